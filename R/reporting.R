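# Run configuration and joined reports: the glue that ties target
# selection, reach estimation, ASO design and assay prediction together
# behind the command-line entry points (inst/cli/dexskip).

#' Assemble and validate a run configuration
#'
#' Thresholds default to the design rules used throughout: duplex Tm >= 48
#' degrees C, soft GC band 40-60%, oligo length 17-23 nt, 50-nt intronic
#' flanks, skip candidates of up to 2 consecutive exons.
#'
#' @param gff,fasta gene annotation and genome sequence paths
#' @param domains domain TSV path (required by [run_find_targets()])
#' @param variants variant TSV/VCF path (optional)
#' @param out_dir report directory
#' @param exons exon indices to design ASOs for
#' @param flank intronic flank (nt) for ASO target regions
#' @param min_len,max_len,tm_min,gc_soft ASO design thresholds
#' @param max_exons maximal exons per skip candidate
#' @param population population constant for reach estimates
#' @param top_n ASOs to report per exon
#' @param fwd_exon,rev_exon RT-PCR primer exons for product prediction
#' @param skip_sets list of exon-index vectors for product prediction
#' @param seed integer seed (mismatch-control placement)
#' @return validated config list of class `run_config`
#' @export
run_config <- function(gff = NULL, fasta = NULL, domains = NULL,
                       variants = NULL, out_dir = tempdir(), exons = NULL,
                       flank = 50L, min_len = 17L, max_len = 23L,
                       tm_min = 48, gc_soft = c(0.40, 0.60),
                       max_exons = 2L, population = 8e9, top_n = 3L,
                       fwd_exon = NULL, rev_exon = NULL, skip_sets = NULL,
                       seed = 1L) {
  stopifnot(flank >= 0L, min_len >= 8L, max_len >= min_len, max_len <= 50L,
            tm_min > 0, length(gc_soft) == 2L, gc_soft[1] < gc_soft[2],
            gc_soft[1] >= 0, gc_soft[2] <= 1, max_exons >= 1L,
            population > 0, top_n >= 1L)
  structure(as.list(environment()), class = "run_config")
}

#' Read a plain-text run configuration
#'
#' `key = value` lines (one per key; `#` comments allowed). List-valued
#' keys (`exons`, `gc_soft`) are comma-separated; `skip_sets` entries are
#' semicolon-separated groups of comma-separated exon indices
#' (`4,5;4,5,6`). Flags given to the CLI override file values.
#'
#' @param path config file
#' @return `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- grep("=", sub("#.*$", "", readLines(path)), value = TRUE)
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p)
    c(trimws(p[1L]), trimws(paste(p[-1L], collapse = "="))))
  vals <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
  args <- list()
  for (key in names(vals)) {
    v <- vals[[key]]
    args[[key]] <- switch(key,
      exons = as.integer(strsplit(v, ",")[[1L]]),
      gc_soft = as.numeric(strsplit(v, ",")[[1L]]),
      skip_sets = lapply(strsplit(v, ";")[[1L]],
                         function(s) as.integer(strsplit(s, ",")[[1L]])),
      flank = , min_len = , max_len = , max_exons = , top_n = ,
      fwd_exon = , rev_exon = , seed = as.integer(v),
      tm_min = , population = as.numeric(v),
      v)
  }
  do.call(run_config, args)
}

config_provenance <- function(config) {
  keep <- !vapply(config, is.null, logical(1))
  c(config[keep], list(package = "dexskip",
                       version = as.character(utils::packageVersion("dexskip"))))
}

load_inputs <- function(config, need_domains = FALSE) {
  if (is.null(config$gff) || is.null(config$fasta))
    stopf("config requires 'gff' and 'fasta' paths")
  gm <- load_gene_model(config$gff, config$fasta)
  tx <- gm$transcripts[[1L]]
  domains <- NULL
  if (!is.null(config$domains)) domains <- load_domains(config$domains, tx)
  else if (need_domains) stopf("config requires a 'domains' file")
  variants <- if (!is.null(config$variants)) load_variants(config$variants, tx)
  list(gm = gm, tx = tx, domains = domains, variants = variants)
}

write_report <- function(tab, config, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, paste0(stem, ".tsv"))
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(list(config = config_provenance(config),
                            results = tab),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  c(tsv = tsv, json = json)
}

#' Find and rank exon skip candidates
#'
#' Loads the gene model, domains and (optionally) variants named in the
#' config, enumerates skip candidates up to `max_exons` consecutive exons,
#' attaches burden/reach, ranks, and writes `candidates.tsv`/`.json` to
#' `out_dir` with the config embedded for provenance.
#'
#' @param config a [run_config()]
#' @return the ranked candidate table, invisibly
#' @export
run_find_targets <- function(config) {
  inp <- load_inputs(config, need_domains = TRUE)
  cand <- enumerate_skip_candidates(inp$tx, inp$domains,
                                    max_exons = config$max_exons)
  if (!is.null(inp$variants))
    cand <- add_variant_metrics(cand, inp$variants,
                                population = config$population)
  ranked <- rank_candidates(cand)
  write_report(ranked, config, config$out_dir, "candidates")
  invisible(ranked)
}

#' Design ASOs for the configured target exons
#'
#' For each exon in `config$exons`: builds the exon +/- flank target
#' region, tiles and scores all windows, applies the hard/soft design
#' criteria, keeps the `top_n` ranked candidates and pairs each with a
#' four-mismatch control. Writes `asos.tsv`/`.json`.
#'
#' @param config a [run_config()]
#' @return the ASO report table, invisibly
#' @export
run_design_asos <- function(config) {
  if (is.null(config$exons)) stopf("config requires 'exons' to design ASOs for")
  inp <- load_inputs(config)
  genome <- Biostrings::readDNAStringSet(config$fasta)
  matrices <- load_ese_matrices()
  crit <- aso_criteria(tm_min = config$tm_min, gc_range = config$gc_soft,
                       len_range = c(config$min_len, config$max_len))
  out <- list()
  for (exi in config$exons) {
    region <- build_target_region(inp$tx, exi, flank_nt = config$flank,
                                  genome = genome)
    cand <- generate_windows(region, config$min_len, config$max_len)
    cand <- score_asos(cand, region, matrices)
    ranked <- filter_and_rank(cand, crit)
    if (nrow(ranked) == 0L) next
    top <- utils::head(ranked, config$top_n)
    top$mismatch_control <- vapply(seq_len(nrow(top)), function(i)
      design_mismatch_control(top$sequence[i],
                              seed = config$seed + i)$sequence, character(1))
    top$chemistry <- "2'-MOE/PS (metadata only)"
    out[[as.character(exi)]] <- top
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  write_report(report, config, config$out_dir, "asos")
  invisible(report)
}

#' Predict RT-PCR products for the configured skip sets
#'
#' Runs [predict_rtpcr()] with the configured primer exons and skip sets
#' and writes the gel-style band table (`bands.tsv`/`.json`).
#'
#' @param config a [run_config()]
#' @return the band table, invisibly
#' @export
run_predict_products <- function(config) {
  if (is.null(config$fwd_exon) || is.null(config$rev_exon))
    stopf("config requires 'fwd_exon' and 'rev_exon'")
  inp <- load_inputs(config)
  preds <- predict_rtpcr(inp$tx, config$fwd_exon, config$rev_exon,
                         skip_sets = if (is.null(config$skip_sets)) list()
                                     else config$skip_sets)
  bands <- band_table(preds)
  write_report(bands, config, config$out_dir, "bands")
  invisible(bands)
}
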