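# Exonic splicing enhancer (ESE) scanning with position-specific score
# matrices in the ESEfinder style (one matrix per SR protein, fixed width,
# per-base weights, a published score threshold). The packaged matrices are
# synthetic stand-ins with the published widths and thresholds of the
# SRSF1/SRSF2/SRSF5/SRSF6 ESEfinder matrices; drop replacement TSVs into a
# directory and point `load_ese_matrices()` at it to scan with real ones.

#' Load ESE score matrices from a directory of TSV files
#'
#' Each file holds one matrix: comment headers `# factor:`, `# threshold:`,
#' then a table with columns `pos`, `A`, `C`, `G`, `U` (one row per motif
#' position). Weights must be defined for all four bases at every position.
#'
#' @param dir directory of matrix TSVs; defaults to the packaged synthetic
#'   matrices
#' @return named list of `ese_matrix` objects (`factor`, `width`,
#'   `threshold`, `weights`)
#' @export
load_ese_matrices <- function(dir = system.file("extdata", "ese_matrices",
                                                package = "dexskip")) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stopf("no ESE matrix TSVs in %s", dir)
  mats <- lapply(files, read_ese_matrix)
  stats::setNames(mats, vapply(mats, `[[`, character(1), "factor"))
}

read_ese_matrix <- function(path) {
  hdr <- readLines(path, n = 10L)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) stopf("matrix %s lacks '# %s:' header", path, key)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1L]))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pos", "A", "C", "G", "U") %in% names(tab)))
    stopf("matrix %s must have columns pos, A, C, G, U", path)
  tab <- tab[order(tab$pos), ]
  w <- as.matrix(tab[, c("A", "C", "G", "U")])
  if (any(!is.finite(w))) stopf("matrix %s has undefined weights", path)
  structure(list(factor = get("factor"),
                 width = nrow(w),
                 threshold = as.numeric(get("threshold")),
                 weights = w),
            class = "ese_matrix")
}

#' Score one window against an ESE matrix
#' @param seq sequence of exactly the matrix width (DNA or RNA)
#' @param matrix an `ese_matrix`
#' @return numeric score (sum of per-position weights)
#' @export
ese_score <- function(seq, matrix) {
  b <- chars(as_rna(seq))
  if (length(b) != matrix$width)
    stopf("window length %d != matrix width %d", length(b), matrix$width)
  sum(matrix$weights[cbind(seq_along(b), match(b, c("A", "C", "G", "U")))])
}

#' Scan a target region for ESE motif hits
#'
#' Slides each matrix along the sense strand of the exon portion of the
#' region (motifs must lie fully inside the exon) and reports every window
#' scoring at or above the matrix threshold.
#'
#' @param region a `target_region` (see [build_target_region()])
#' @param matrices list from [load_ese_matrices()]
#' @return data.frame with `factor`, `pos_region` (1-based start in the
#'   region), `pos_exon` (1-based start within the exon), `width`, `score`
#' @export
ese_scan <- function(region, matrices) {
  stopifnot(inherits(region, "target_region"))
  exon_seq <- substr(region$sequence, region$exon_start + 1L, region$exon_end)
  rows <- list()
  for (m in matrices) {
    w <- m$width
    n <- nchar(exon_seq)
    if (n < w) next
    for (s in seq_len(n - w + 1L)) {
      sc <- ese_score(substr(exon_seq, s, s + w - 1L), m)
      if (sc >= m$threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = m$factor, pos_region = region$exon_start + s,
          pos_exon = s, width = w, score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = character(0), pos_region = integer(0),
               pos_exon = integer(0), width = integer(0), score = numeric(0),
               stringsAsFactors = FALSE)
}

#' Highest-scoring (consensus) sequence of an ESE matrix
#' @param matrix an `ese_matrix`
#' @return RNA string of the per-position argmax bases
#' @export
ese_consensus <- function(matrix) {
  paste0(c("A", "C", "G", "U")[apply(matrix$weights, 1L, which.max)],
         collapse = "")
}
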