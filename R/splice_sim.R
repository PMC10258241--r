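# In silico twin of the minigene splice assay and endogenous-transcript
# RT-PCR: exact amplicon sizes for each splice isoform (with and without
# the targeted exons), rendered as a gel-style band table.

#' Describe a minigene splice construct
#'
#' The insert exons sit between two heterologous flanking exons (rhodopsin
#' exons in the wet-lab construct); RT-PCR primers sit in the flanking
#' exons so every insert isoform is amplified. Primer positions default to
#' the flanking exon centers; pass explicit positions to mirror a real
#' primer pair.
#'
#' @param upstream_flank_nt,downstream_flank_nt flanking exon lengths
#' @param insert_exon_nt integer vector of insert exon lengths, 5'->3'
#' @param fwd_primer_pos 1-based position of the forward primer 5' end in
#'   the upstream flanking exon (amplicon starts there)
#' @param rev_primer_pos 1-based position in the downstream flanking exon
#'   at which the amplicon ends (the reverse primer 5' end)
#' @return object of class `minigene_construct`
#' @export
minigene_construct <- function(upstream_flank_nt, downstream_flank_nt,
                               insert_exon_nt,
                               fwd_primer_pos = NULL, rev_primer_pos = NULL) {
  stopifnot(upstream_flank_nt >= 1L, downstream_flank_nt >= 1L,
            length(insert_exon_nt) >= 1L, all(insert_exon_nt >= 1L))
  if (is.null(fwd_primer_pos)) fwd_primer_pos <- ceiling(upstream_flank_nt / 2)
  if (is.null(rev_primer_pos)) rev_primer_pos <- ceiling(downstream_flank_nt / 2)
  stopifnot(fwd_primer_pos >= 1L, fwd_primer_pos <= upstream_flank_nt,
            rev_primer_pos >= 1L, rev_primer_pos <= downstream_flank_nt)
  structure(list(upstream_flank_nt = as.integer(upstream_flank_nt),
                 downstream_flank_nt = as.integer(downstream_flank_nt),
                 insert_exon_nt = as.integer(insert_exon_nt),
                 fwd_primer_pos = as.integer(fwd_primer_pos),
                 rev_primer_pos = as.integer(rev_primer_pos)),
            class = "minigene_construct")
}

#' Predict minigene RT-PCR products for a set of skip isoforms
#'
#' One prediction per isoform, the unskipped reference included. A skipped
#' isoform's product is the full product minus the summed lengths of the
#' skipped insert exons. Skip sets refer to insert exons by their 1-based
#' position in the insert; skipping a flanking exon is an error (the
#' primers sit there).
#'
#' @param construct a `minigene_construct`
#' @param skip_sets list of integer vectors of insert exon indices (the
#'   empty vector is the reference and is always included)
#' @return data.frame of class `amplicon_predictions` with `isoform_label`,
#'   `product_nt`, `frame_preserving`
#' @export
predict_minigene_products <- function(construct, skip_sets = list()) {
  stopifnot(inherits(construct, "minigene_construct"))
  ins <- construct$insert_exon_nt
  full <- (construct$upstream_flank_nt - construct$fwd_primer_pos + 1L) +
    sum(ins) + construct$rev_primer_pos
  sets <- unique(c(list(integer(0)), lapply(skip_sets, function(s) sort(unique(as.integer(s))))))
  rows <- lapply(sets, function(s) {
    if (length(s) > 0L && (min(s) < 1L || max(s) > length(ins)))
      stopf("skip set references a flanking or non-existent exon (insert has %d exons)",
            length(ins))
    data.frame(isoform_label = isoform_label(s),
               product_nt = full - sum(ins[s]),
               frame_preserving = sum(ins[s]) %% 3L == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amplicon_predictions", "data.frame")
  out
}

#' Predict endogenous-transcript RT-PCR products for skip isoforms
#'
#' Primers sit in exons strictly outside the skipped range (the wet-lab
#' design places them two exons up- and downstream of the target exons);
#' product sizes are exact transcript distances between the primer ends.
#'
#' @param tx a `transcript`
#' @param fwd_exon,rev_exon exon indices carrying the primers
#' @param skip_sets list of skip event sets (as in [apply_skip()]); the
#'   no-skip reference is always included
#' @param fwd_primer_pos,rev_primer_pos 1-based positions within the primer
#'   exons (defaults: exon centers)
#' @return `amplicon_predictions` data.frame
#' @export
predict_rtpcr <- function(tx, fwd_exon, rev_exon, skip_sets = list(),
                          fwd_primer_pos = NULL, rev_primer_pos = NULL) {
  stopifnot(inherits(tx, "transcript"))
  ex <- tx$exons
  if (!(fwd_exon %in% ex$index) || !(rev_exon %in% ex$index) ||
      fwd_exon >= rev_exon)
    stopf("need valid primer exons with fwd_exon < rev_exon")
  if (is.null(fwd_primer_pos)) fwd_primer_pos <- ceiling(ex$length_nt[fwd_exon] / 2)
  if (is.null(rev_primer_pos)) rev_primer_pos <- ceiling(ex$length_nt[rev_exon] / 2)
  # amplicon on the unskipped transcript: from the fwd primer 5' end to the
  # rev primer 5' end, inclusive
  amp_start <- ex$tx_start[fwd_exon] + fwd_primer_pos - 1L
  amp_end <- ex$tx_start[rev_exon] + rev_primer_pos
  full <- amp_end - amp_start

  sets <- unique(c(list(integer(0)),
                   lapply(skip_sets, function(s) normalize_events(tx, s))))
  rows <- lapply(sets, function(s) {
    if (length(s) > 0L) {
      if (any(s <= fwd_exon) || any(s >= rev_exon))
        stopf("skipped exons must lie strictly between the primer exons (%d..%d)",
              fwd_exon, rev_exon)
    }
    cons <- protein_consequence(tx, s)
    data.frame(isoform_label = isoform_label(s),
               product_nt = full - sum(ex$length_nt[s]),
               frame_preserving = cons$frame_preserving,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amplicon_predictions", "data.frame")
  out
}

#' Gel-style band table
#'
#' Sorts isoforms by product size descending (the order bands appear on a
#' gel); isoforms with identical product sizes are merged into one band
#' with a combined label, mirroring their co-migration.
#'
#' @param predictions an `amplicon_predictions` data.frame
#' @return data.frame of class `band_table` (`band`, `product_nt`,
#'   `isoform_label`, `frame_preserving`)
#' @export
band_table <- function(predictions) {
  stopifnot(nrow(predictions) >= 1L)
  sizes <- sort(unique(predictions$product_nt), decreasing = TRUE)
  rows <- lapply(seq_along(sizes), function(i) {
    sel <- predictions$product_nt == sizes[i]
    data.frame(band = i, product_nt = sizes[i],
               isoform_label = paste(predictions$isoform_label[sel], collapse = "/"),
               frame_preserving = all(predictions$frame_preserving[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("band_table", "data.frame")
  out
}

#' Write / read a band table as TSV
#' @param bands a `band_table`
#' @param path file path
#' @export
write_band_table <- function(bands, path) {
  utils::write.table(bands, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("band_table", "data.frame")
  out
}
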