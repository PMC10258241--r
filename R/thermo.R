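# Nearest-neighbor duplex melting temperature for RNA:RNA duplexes
# (Xia/Turner 1998 Watson-Crick parameter set) and dependency-free
# secondary-structure scores: Nussinov-style maximum base pairing for
# hairpin propensity and the longest ungapped self-complementary run for
# dimerization propensity.

# Stack parameters keyed by the 5'->3' dinucleotide of the given strand
# paired with its perfect complement. dH in kcal/mol, dS in cal/(mol K).
# The ten unique stacks are expanded to all sixteen dinucleotides by
# duplex symmetry (XY equals the reverse complement of XY read from the
# other end, e.g. UU == AA, AG == CU).
RNA_NN_DH <- c(
  AA = -6.82, UU = -6.82,
  AU = -9.38,
  UA = -7.69,
  CU = -10.48, AG = -10.48,
  CA = -10.44, UG = -10.44,
  GU = -11.40, AC = -11.40,
  GA = -12.44, UC = -12.44,
  CG = -10.64,
  GG = -13.39, CC = -13.39,
  GC = -14.88
)
RNA_NN_DS <- c(
  AA = -19.0, UU = -19.0,
  AU = -26.7,
  UA = -20.5,
  CU = -27.1, AG = -27.1,
  CA = -26.9, UG = -26.9,
  GU = -29.5, AC = -29.5,
  GA = -32.5, UC = -32.5,
  CG = -26.7,
  GG = -32.7, CC = -32.7,
  GC = -36.9
)
RNA_NN_INIT_DH <- 3.61; RNA_NN_INIT_DS <- -1.5
RNA_NN_TERM_AU_DH <- 3.72; RNA_NN_TERM_AU_DS <- 10.5
GAS_CONSTANT <- 1.9872      # cal/(mol K)

check_rna <- function(seq) {
  seq <- toupper(seq)
  if (!grepl("^[ACGU]+$", seq))
    stopf("sequence must be RNA over the ACGU alphabet: %s", seq)
  seq
}

#' GC fraction of a sequence
#'
#' @param seq DNA or RNA string (unambiguous ACGT/ACGU)
#' @return (G + C) / length
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stopf("empty sequence")
  if (!grepl("^[ACGTU]+$", seq))
    stopf("ambiguous or non-nucleotide characters in sequence: %s", seq)
  b <- chars(seq)
  sum(b %in% c("G", "C")) / length(b)
}

#' Nearest-neighbor melting temperature of an oligo:target RNA duplex
#'
#' Computes the two-state melting temperature of the duplex formed by `seq`
#' and its perfect RNA complement under the Watson-Crick RNA:RNA
#' nearest-neighbor parameter set (duplex initiation and per-end terminal
#' A-U penalties included), at the given total strand concentration, with
#' the classic `16.6 * log10([Na+])` monovalent-salt adjustment relative to
#' 1 M. Defaults: 250 nM oligo, 100 mM monovalent salt. Absolute values for
#' chemically modified oligos (2'-MOE, phosphorothioate) are approximate;
#' the threshold applied downstream is configurable.
#'
#' @param seq RNA string, length >= 8
#' @param oligo_conc total strand concentration in mol/L
#' @param na_conc monovalent cation concentration in mol/L
#' @return melting temperature in degrees Celsius
#' @export
melting_temperature <- function(seq, oligo_conc = 250e-9, na_conc = 0.1) {
  seq <- check_rna(seq)
  n <- nchar(seq)
  if (n < 8L) stopf("melting temperature requires length >= 8 (got %d)", n)
  b <- chars(seq)
  stacks <- paste0(b[-n], b[-1L])
  dH <- RNA_NN_INIT_DH + sum(RNA_NN_DH[stacks])
  dS <- RNA_NN_INIT_DS + sum(RNA_NN_DS[stacks])
  for (end in c(b[1L], b[n])) {
    if (end %in% c("A", "U")) {
      dH <- dH + RNA_NN_TERM_AU_DH
      dS <- dS + RNA_NN_TERM_AU_DS
    }
  }
  x <- if (identical(seq, revcomp_rna(seq))) 1 else 4
  tm_k <- dH * 1000 / (dS + GAS_CONSTANT * log(oligo_conc / x))
  tm_k - 273.15 + 16.6 * log10(na_conc)
}

PAIRABLE <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")

can_pair <- function(a, b) b %in% PAIRABLE[[a]]

#' Maximum intramolecular base pairing (hairpin propensity)
#'
#' Nussinov-style dynamic program returning the maximum number of nested
#' Watson-Crick + G:U wobble pairs with a minimum hairpin loop of
#' `min_loop` unpaired bases. A pure counting model, not an energy model:
#' it is deterministic and adequate for ranking candidate oligos by
#' structure propensity.
#'
#' @param seq RNA string, length >= 4
#' @param min_loop minimum loop size (default 3)
#' @return integer: maximum number of base pairs
#' @export
hairpin_score <- function(seq, min_loop = 3L) {
  seq <- check_rna(seq)
  n <- nchar(seq)
  if (n < 4L) stopf("hairpin score requires length >= 4")
  b <- chars(seq)
  M <- matrix(0L, n, n)
  if (n < min_loop + 2L) return(0L)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]                       # i unpaired
      for (k in (i + min_loop + 1L):j) {         # i paired with k
        if (can_pair(b[i], b[k])) {
          left <- if (k - i - 1L >= 2L) M[i + 1L, k - 1L] else 0L
          right <- if (k < j) M[k + 1L, j] else 0L
          best <- max(best, 1L + left + right)
        }
      }
      M[i, j] <- best
    }
  }
  M[1L, n]
}

#' Longest self-complementary run (dimerization propensity)
#'
#' Slides the sequence against itself in antiparallel orientation at every
#' ungapped offset and returns the length of the longest contiguous run of
#' Watson-Crick pairs. A palindromic (self-complementary) sequence scores
#' its full length.
#'
#' @param seq RNA string, length >= 4
#' @return integer run length
#' @export
self_dimer_run <- function(seq) {
  seq <- check_rna(seq)
  n <- nchar(seq)
  if (n < 4L) stopf("self-dimer score requires length >= 4")
  b <- chars(seq)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  best <- 0L
  # antiparallel pairing: position i on one copy against position j on the
  # other with i + j = c; runs are contiguous in i
  for (csum in 2L:(2L * n)) {
    run <- 0L
    for (i in max(1L, csum - n):min(n, csum - 1L)) {
      j <- csum - i
      if (wc[b[i]] == b[j]) { run <- run + 1L; best <- max(best, run) }
      else run <- 0L
    }
  }
  best
}
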