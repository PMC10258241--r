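# Design of splice-modulating antisense oligonucleotides (ASOs) against a
# target exon: tile every 17-23-nt window over the exon and its intronic
# flanks, score each window (GC, nearest-neighbor duplex Tm, ESE footprint,
# hairpin and self-dimer propensity), apply the design rules (hard Tm
# floor, soft GC band), rank deterministically, and build four-mismatch
# non-binding control oligos.

#' Extract a target region: one exon plus flanking intronic sequence
#'
#' The region is reported in transcript (sense) orientation; for
#' minus-strand genes the genomic sequence is reverse-complemented. Flanks
#' shorter than `flank_nt` (exon at a transcript end, or chromosome edge)
#' are truncated with a warning.
#'
#' @param tx a `transcript` (needs genomic coordinates and a genome
#'   sequence) or `NULL` when `pre_mrna` is given
#' @param exon_index exon to target (1-based transcript rank)
#' @param flank_nt intronic flank length on each side (default 50)
#' @param genome named character vector or `DNAStringSet` with the
#'   chromosome sequence (required to recover intronic sequence)
#' @return object of class `target_region` with fields `exon_index`,
#'   `sequence`, `exon_start`/`exon_end` (0-based half-open within the
#'   region), `flank_up`, `flank_down`
#' @export
build_target_region <- function(tx, exon_index, flank_nt = 50L, genome) {
  stopifnot(inherits(tx, "transcript"))
  ex <- tx$exons
  if (!(exon_index %in% ex$index)) stopf("exon %d out of range", exon_index)
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  cseq <- genome[[tx$chrom]]
  if (is.null(cseq)) stopf("sequence '%s' missing from genome", tx$chrom)
  clen <- nchar(cseq)
  gs <- ex$gstart[exon_index]; ge <- ex$gend[exon_index]
  if (tx$strand == "+") {
    up <- min(flank_nt, gs); down <- min(flank_nt, clen - ge)
    seq <- substr(cseq, gs - up + 1L, ge + down)
  } else {
    up <- min(flank_nt, clen - ge); down <- min(flank_nt, gs)
    seq <- revcomp_dna(substr(cseq, gs - down + 1L, ge + up))
  }
  if (up < flank_nt || down < flank_nt)
    warnf("exon %d: flank truncated to %d/%d nt by sequence end",
          exon_index, up, down)
  structure(list(
    exon_index = exon_index,
    sequence = as_dna(seq),
    exon_start = as.integer(up),
    exon_end = as.integer(up + (ge - gs)),
    flank_up = as.integer(up), flank_down = as.integer(down)
  ), class = "target_region")
}

#' Target region from a raw sequence
#'
#' For workflows that start from a pre-mRNA fragment rather than a loaded
#' gene model.
#'
#' @param sequence sense-strand sequence of exon plus flanks
#' @param exon_start,exon_end 0-based half-open exon interval within it
#' @param exon_index label for reporting
#' @export
target_region_from_seq <- function(sequence, exon_start, exon_end,
                                   exon_index = 1L) {
  sequence <- as_dna(sequence)
  stopifnot(exon_start >= 0L, exon_end > exon_start,
            exon_end <= nchar(sequence))
  structure(list(exon_index = as.integer(exon_index), sequence = sequence,
                 exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end),
                 flank_up = as.integer(exon_start),
                 flank_down = as.integer(nchar(sequence) - exon_end)),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region exon %d> %d nt (%d + %d exon + %d)\n",
              x$exon_index, nchar(x$sequence), x$flank_up,
              x$exon_end - x$exon_start, x$flank_down))
  invisible(x)
}

#' Enumerate candidate ASO windows over a target region
#'
#' Every window of each allowed length that overlaps the exon by at least
#' one base yields one candidate. The emitted oligo sequence is the exact
#' reverse complement of the covered sense window, in RNA alphabet,
#' written 5'->3'. Windows straddling an intron-exon boundary are
#' category `boundary`; fully intra-exonic windows are `exonic_ese`.
#'
#' @param region a `target_region`
#' @param min_len,max_len allowed oligo lengths (defaults 17 and 23)
#' @return data.frame of unscored candidates (`id`, `target_exon`,
#'   `start`/`end` 0-based half-open on the region, `length_nt`,
#'   `sense_seq`, `sequence`, `category`)
#' @export
generate_windows <- function(region, min_len = 17L, max_len = 23L) {
  stopifnot(inherits(region, "target_region"), min_len >= 1L,
            max_len >= min_len)
  n <- nchar(region$sequence)
  if (n < min_len) stopf("region shorter than min_len")
  rows <- list()
  for (L in min_len:max_len) {
    if (L > n) break
    for (s in 0L:(n - L)) {
      e <- s + L
      if (e <= region$exon_start || s >= region$exon_end) next  # no exon overlap
      crosses <- (s < region$exon_start && e > region$exon_start) ||
        (s < region$exon_end && e > region$exon_end)
      sense <- substr(region$sequence, s + 1L, e)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("ex%d_%d_%d", region$exon_index, s, L),
        target_exon = region$exon_index,
        start = s, end = e, length_nt = L,
        sense_seq = sense,
        sequence = revcomp_rna(sense),
        category = if (crosses) "boundary" else "exonic_ese",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Score ASO candidates
#'
#' Adds GC fraction, duplex melting temperature, ESE footprint count
#' (number of ESE hits on the sense strand whose footprint overlaps the
#' window within the exon), maximum hairpin pairing and longest self-dimer
#' run for each candidate.
#'
#' @param candidates from [generate_windows()]
#' @param region the `target_region` the candidates tile
#' @param matrices ESE matrices ([load_ese_matrices()]); `NULL` skips the scan
#' @param oligo_conc,na_conc conditions for [melting_temperature()]
#' @return candidates with `gc_fraction`, `tm_c`, `ese_hits`,
#'   `hairpin_pairs`, `self_dimer_run` columns
#' @export
score_asos <- function(candidates, region, matrices = NULL,
                       oligo_conc = 250e-9, na_conc = 0.1) {
  hits <- if (is.null(matrices)) NULL else ese_scan(region, matrices)
  candidates$gc_fraction <- vapply(candidates$sequence, gc_content, numeric(1),
                                   USE.NAMES = FALSE)
  candidates$tm_c <- vapply(candidates$sequence, melting_temperature,
                            numeric(1), oligo_conc = oligo_conc,
                            na_conc = na_conc, USE.NAMES = FALSE)
  candidates$ese_hits <- vapply(seq_len(nrow(candidates)), function(i) {
    if (is.null(hits) || nrow(hits) == 0L) return(0L)
    ws <- candidates$start[i]; we <- candidates$end[i]
    hs <- hits$pos_region - 1L; he <- hs + hits$width   # 0-based half-open
    sum(hs < we & he > ws)
  }, integer(1))
  candidates$hairpin_pairs <- vapply(candidates$sequence, hairpin_score,
                                     integer(1), USE.NAMES = FALSE)
  candidates$self_dimer_run <- vapply(candidates$sequence, self_dimer_run,
                                      integer(1), USE.NAMES = FALSE)
  candidates
}

#' Design criteria for ASO filtering and ranking
#'
#' Hard criteria (candidates failing them are removed): length within
#' `len_range`, duplex Tm at least `tm_min`. The GC band is deliberately a
#' SOFT criterion: published effective oligos sit just outside the 40-60%
#' band (e.g. a 23-mer at 9/23 ~ 39.1% GC), so out-of-band GC is flagged
#' and penalized, never excluded. Structure scores above the caps are
#' penalized likewise. `rank_score = w_boundary * [boundary] +
#' w_ese * ese_hits - w_gc * gc_excess - w_struct * (hairpin_excess +
#' dimer_excess)`.
#'
#' @param tm_min minimum duplex Tm in Celsius (default 48)
#' @param gc_range soft GC band as fractions (default 0.40-0.60)
#' @param len_range allowed oligo lengths (default 17-23)
#' @param hairpin_cap,dimer_cap unpenalized structure score ceilings
#' @param w_boundary,w_ese,w_gc,w_struct ranking weights
#' @export
aso_criteria <- function(tm_min = 48, gc_range = c(0.40, 0.60),
                         len_range = c(17L, 23L), hairpin_cap = 6L,
                         dimer_cap = 6L, w_boundary = 2, w_ese = 0.5,
                         w_gc = 5, w_struct = 0.25) {
  stopifnot(gc_range[1] < gc_range[2], len_range[1] <= len_range[2])
  list(tm_min = tm_min, gc_range = gc_range, len_range = len_range,
       hairpin_cap = hairpin_cap, dimer_cap = dimer_cap,
       w_boundary = w_boundary, w_ese = w_ese, w_gc = w_gc,
       w_struct = w_struct)
}

#' Filter and rank scored ASO candidates
#'
#' Applies the hard filters, computes the documented `rank_score`, flags
#' soft-criterion violations (`gc_in_band`), and orders candidates by
#' score descending with a deterministic positional tie-break (window
#' start, then length).
#'
#' @param candidates scored candidates ([score_asos()])
#' @param criteria from [aso_criteria()]
#' @return ordered data.frame (possibly empty, with a warning)
#' @export
filter_and_rank <- function(candidates, criteria = aso_criteria()) {
  ok <- candidates$length_nt >= criteria$len_range[1] &
    candidates$length_nt <= criteria$len_range[2] &
    candidates$tm_c >= criteria$tm_min
  out <- candidates[ok, , drop = FALSE]
  if (nrow(out) == 0L) {
    warnf("no ASO candidates pass the hard filters")
    return(out)
  }
  gc_excess <- pmax(0, criteria$gc_range[1] - out$gc_fraction,
                    out$gc_fraction - criteria$gc_range[2])
  out$gc_in_band <- gc_excess == 0
  out$rank_score <- criteria$w_boundary * (out$category == "boundary") +
    criteria$w_ese * out$ese_hits -
    criteria$w_gc * gc_excess -
    criteria$w_struct * (pmax(0L, out$hairpin_pairs - criteria$hairpin_cap) +
                           pmax(0L, out$self_dimer_run - criteria$dimer_cap))
  out <- out[order(-out$rank_score, out$start, out$length_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a four-mismatch non-binding control oligo
#'
#' Introduces exactly `n` substitutions at interior positions (never the
#' first three or last two), chosen reproducibly from `seed`. Each
#' substituted base keeps its chemical class (A<->G, C<->U): a
#' purine-purine / pyrimidine-pyrimidine swap maximally disrupts pairing
#' with the target while minimizing the GC change among class-preserving
#' choices.
#'
#' @param aso_seq RNA sequence of the parent ASO
#' @param n number of mismatches (default 4)
#' @param seed integer seed for position choice
#' @return list of class `mismatch_control` with `sequence`,
#'   `mismatch_positions` (1-based), `parent`
#' @export
design_mismatch_control <- function(aso_seq, n = 4L, seed = 1L) {
  aso_seq <- check_rna(aso_seq)
  len <- nchar(aso_seq)
  if (len < 12L) stopf("mismatch control requires parent length >= 12")
  interior <- 4L:(len - 2L)
  if (length(interior) < n)
    stopf("cannot place %d mismatches in %d interior positions", n, length(interior))
  pos <- sort(with_seed(seed, sample(interior, n)))
  swap <- c(A = "G", G = "A", C = "U", U = "C")
  b <- chars(aso_seq)
  b[pos] <- swap[b[pos]]
  structure(list(sequence = paste0(b, collapse = ""),
                 mismatch_positions = pos, parent = aso_seq),
            class = "mismatch_control")
}

#' Validate an ASO / mismatch-control pair
#'
#' Checks the published design convention: equal length, Hamming distance
#' exactly `n`, and every mismatch at an interior position (not within the
#' first three or last two bases).
#'
#' @param aso_seq,control_seq RNA sequences
#' @param n required mismatch count (default 4)
#' @return list with `valid`, `n_mismatch`, `positions`, `interior_ok`,
#'   `length_ok`
#' @export
validate_mismatch_pair <- function(aso_seq, control_seq, n = 4L) {
  aso_seq <- check_rna(aso_seq); control_seq <- check_rna(control_seq)
  length_ok <- nchar(aso_seq) == nchar(control_seq)
  if (!length_ok)
    return(list(valid = FALSE, n_mismatch = NA_integer_,
                positions = integer(0), interior_ok = NA, length_ok = FALSE))
  a <- chars(aso_seq); b <- chars(control_seq)
  pos <- which(a != b)
  len <- length(a)
  interior_ok <- all(pos >= 4L & pos <= len - 2L)
  list(valid = length(pos) == n && interior_ok,
       n_mismatch = length(pos), positions = pos,
       interior_ok = interior_ok, length_ok = TRUE)
}

#' Published lead ASO / mismatch-control sequences for USH2A exons 30-40
#'
#' The five validated lead oligos (and their four-mismatch controls)
#' targeting human USH2A exons 30, 31, 39 and 40, as deposited with the
#' dual exon skipping study this package operationalizes.
#'
#' @return data.frame with `aso_id`, `target_exon`, `sequence`,
#'   `mismatch_control`
#' @export
lead_aso_table <- function() {
  path <- system.file("extdata", "ush2a_lead_asos.tsv", package = "dexskip")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
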