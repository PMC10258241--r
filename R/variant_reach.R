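# Variant intake (LOVD-style TSV or VCF), per-exon loss-of-function burden,
# and a Hardy-Weinberg estimate of how many affected individuals a skip
# candidate could treat given pathogenic allele frequencies.

LOF_CLASSES <- c("nonsense", "frameshift", "canonical_splice")

normalize_consequence <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("stop_gained|nonsense", x)] <- "nonsense"
  out[grepl("frameshift", x)] <- "frameshift"
  out[grepl("splice_acceptor|splice_donor|canonical_splice", x)] <- "canonical_splice"
  out[grepl("missense", x)] <- "missense"
  out
}

# parse the coding position out of a c. description; returns list(pos,
# offset) where offset != 0 marks an intronic position (c.123-5 style)
parse_hgvs_c_pos <- function(hgvs_c) {
  m <- regmatches(hgvs_c, regexec("^c\\.(\\d+)([+-]\\d+)?", hgvs_c))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(pos = as.integer(m[2L]),
       offset = if (m[3L] == "" || is.na(m[3L])) 0L else as.integer(m[3L]))
}

#' Load a variant table and resolve each record to an exon
#'
#' Accepts either a LOVD-style TSV (columns `hgvs_c`, `consequence`,
#' `allele_frequency`, optional `source`) or a VCF 4.x file (genomic
#' records; allele frequency read from `INFO/AF`, consequence class from the
#' first field of `INFO/CSQ` when present). TSV records are placed via their
#' c. position; records with an intronic offset (e.g. `c.100-5A>G`) are
#' flagged intronic (`exon_index = NA`) and never counted in exonic burden.
#' Malformed rows are skipped with a warning naming the count.
#'
#' @param path variant file
#' @param tx a `transcript` used to resolve positions
#' @return data.frame with `hgvs_c`, `exon_index`, `consequence_class`,
#'   `allele_frequency`, `intronic`, `source`
#' @export
load_variants <- function(path, tx) {
  if (!file.exists(path)) stopf("variant file not found: %s", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "vcf") load_variants_vcf(path, tx) else load_variants_tsv(path, tx)
}

empty_variants <- function() {
  data.frame(hgvs_c = character(0), exon_index = integer(0),
             consequence_class = character(0), allele_frequency = numeric(0),
             intronic = logical(0), source = character(0),
             stringsAsFactors = FALSE)
}

load_variants_tsv <- function(path, tx) {
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    warnf("no variant records read from %s", path)
    return(empty_variants())
  }
  need <- c("hgvs_c", "consequence", "allele_frequency")
  if (!all(need %in% names(tab)))
    stopf("variant TSV must have columns: %s", paste(need, collapse = ", "))
  bad <- 0L
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    pos <- parse_hgvs_c_pos(tab$hgvs_c[i])
    af <- suppressWarnings(as.numeric(tab$allele_frequency[i]))
    if (is.null(pos) || is.na(af) || af < 0 || af > 1) return(NULL)
    intronic <- pos$offset != 0L
    ei <- if (intronic) NA_integer_ else exon_of_cds_pos(tx, pos$pos)
    data.frame(hgvs_c = tab$hgvs_c[i],
               exon_index = ei,
               consequence_class = normalize_consequence(tab$consequence[i]),
               allele_frequency = af,
               intronic = intronic || is.na(ei),
               source = if ("source" %in% names(tab)) tab$source[i] else "tsv",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  bad <- sum(!keep)
  if (bad > 0L) warnf("skipped %d malformed variant row(s) in %s", bad, path)
  if (!any(keep)) return(empty_variants())
  do.call(rbind, rows[keep])
}

load_variants_vcf <- function(path, tx) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warnf("no variant records read from %s", path)
    return(empty_variants())
  }
  info <- vcfR::getINFO(v)
  get_info <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s,
                               perl = TRUE))[[1L]]
    if (length(m) == 0L) NA_character_ else m[2L]
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    gpos <- suppressWarnings(as.integer(fix$POS[i])) - 1L   # to 0-based
    if (is.na(gpos)) return(NULL)
    af <- suppressWarnings(as.numeric(get_info(info[i], "AF")))
    if (is.na(af) || af < 0 || af > 1) return(NULL)
    csq <- get_info(info[i], "CSQ")
    cls <- if (is.na(csq)) "other" else
      normalize_consequence(strsplit(csq, "|", fixed = TRUE)[[1L]][1L])
    tpos <- genomic_to_tx(tx, gpos)
    intronic <- is.na(tpos) || tpos < tx$cds_start || tpos >= tx$cds_start + tx$cds_len
    cpos <- if (intronic) NA_integer_ else as.integer(tpos - tx$cds_start + 1L)
    ei <- if (intronic) NA_integer_ else exon_of_cds_pos(tx, cpos)
    hgvs <- if (intronic) sprintf("g.%s%s>%s", fix$POS[i], fix$REF[i], fix$ALT[i])
            else sprintf("c.%d%s>%s", cpos, fix$REF[i], fix$ALT[i])
    data.frame(hgvs_c = hgvs, exon_index = ei, consequence_class = cls,
               allele_frequency = af, intronic = intronic, source = "vcf",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (sum(!keep) > 0L) warnf("skipped %d malformed VCF record(s) in %s", sum(!keep), path)
  if (!any(keep)) return(empty_variants())
  do.call(rbind, rows[keep])
}

#' Loss-of-function variant burden over an exon range
#'
#' Counts unique variant records (by `hgvs_c`) assigned to exons in the
#' range whose consequence class is nonsense, frameshift or canonical
#' splice. Missense and intronic records are excluded by default; widen
#' `classes` to change that.
#'
#' @param variants data.frame from [load_variants()]
#' @param exon_range integer vector of exon indices
#' @param classes consequence classes to count
#' @return integer count
#' @export
lof_burden <- function(variants, exon_range, classes = LOF_CLASSES) {
  sel <- !is.na(variants$exon_index) &
    variants$exon_index %in% exon_range &
    variants$consequence_class %in% classes
  length(unique(variants$hgvs_c[sel]))
}

#' Estimate the number of treatable affected individuals
#'
#' Under Hardy-Weinberg random mating with total pathogenic allele frequency
#' `a_gene` in the gene and `a_target` in the target exons, an individual is
#' affected when both alleles are pathogenic and is eligible for the skip
#' when at least one of the two carries a target-exon mutation (that allele
#' is the one the skipped transcript restores). The expected count is
#'
#'   `population * a_target * (2 * a_gene - a_target)`
#'
#' The stricter count of affected individuals with *both* alleles in the
#' target exons, `population * a_target^2`, is reported alongside.
#'
#' @param a_target summed pathogenic allele frequency in the target exons
#' @param a_gene summed pathogenic allele frequency gene-wide
#' @param population population size (default 8e9, "worldwide")
#' @return list of class `reach_estimate` with `eligible_affected`,
#'   `biallelic_in_target`, the inputs and the formula string
#' @export
estimate_reach <- function(a_target, a_gene, population = 8e9) {
  if (a_target < 0 || a_gene > 1 || a_target > a_gene)
    stopf("need 0 <= a_target <= a_gene <= 1 (got a_target=%g, a_gene=%g)",
          a_target, a_gene)
  structure(list(
    a_target = a_target, a_gene = a_gene, population = population,
    eligible_affected = population * a_target * (2 * a_gene - a_target),
    biallelic_in_target = population * a_target^2,
    formula = "population * a_target * (2*a_gene - a_target)"
  ), class = "reach_estimate")
}

#' @export
print.reach_estimate <- function(x, ...) {
  cat(sprintf(
    "reach: %.0f eligible affected (>=1 target-exon allele; %s)\n       %.0f with both alleles in target exons\n       a_target=%g, a_gene=%g, population=%g\n",
    x$eligible_affected, x$formula, x$biallelic_in_target,
    x$a_target, x$a_gene, x$population))
  invisible(x)
}

#' Convert carrier frequency to allele frequency
#'
#' Under the rare-allele approximation a carrier frequency `f` (heterozygote
#' fraction ~ 2q) corresponds to allele frequency `q = f / 2`.
#'
#' @param carrier_frequency fraction of carriers in the population
#' @export
carrier_to_allele_frequency <- function(carrier_frequency) {
  stopifnot(carrier_frequency >= 0, carrier_frequency <= 1)
  carrier_frequency / 2
}
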