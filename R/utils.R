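# Small sequence helpers shared across modules. Internal coordinates are
# 0-based half-open throughout; anything user-facing (HGVS, reports) is
# 1-based inclusive.

as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_dna(x))))
}

revcomp_rna <- function(x) as_rna(revcomp_dna(x))

#' Translate a coding DNA sequence
#'
#' @param cds coding sequence (character, length divisible by 3)
#' @return amino-acid string, stop codons rendered as `*`
#' @keywords internal
translate_cds <- function(cds) {
  cds <- as_dna(cds)
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "X"
  ))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards so package calls never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}
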