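# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, sharing no code with the implementation.

# exon phases by cumulative CDS length
oracle_phases <- function(tx) {
  cds <- tx$exons$cds_nt
  cum <- 0L
  out <- data.frame(start_phase = integer(length(cds)),
                    end_phase = integer(length(cds)))
  for (i in seq_along(cds)) {
    if (cds[i] == 0L) {
      out$start_phase[i] <- -1L; out$end_phase[i] <- -1L
    } else {
      out$start_phase[i] <- cum %% 3L
      out$end_phase[i] <- (cum + cds[i]) %% 3L
    }
    cum <- cum + cds[i]
  }
  out
}

# frame preservation by direct summation
oracle_frame <- function(tx, idx) sum(tx$exons$cds_nt[idx]) %% 3L == 0L

# removed amino-acid set by counting, per codon, how many of its three
# nucleotides fall inside the skipped CDS block (removed when >= 2)
oracle_removed_aa <- function(tx, idx) {
  cum <- cumsum(c(0L, tx$exons$cds_nt))
  skipped <- unlist(lapply(idx, function(i) {
    if (tx$exons$cds_nt[i] == 0L) integer(0)
    else seq.int(cum[i], cum[i + 1L] - 1L)   # 0-based CDS positions
  }))
  n_aa <- nchar(tx$protein_seq)
  removed <- logical(n_aa)
  for (c0 in seq_len(n_aa) - 1L) {
    removed[c0 + 1L] <- sum((3L * c0):(3L * c0 + 2L) %in% skipped) >= 2L
  }
  which(removed)
}

# domain impact by residue-set membership
oracle_impact <- function(tx, idx, domains) {
  if (!oracle_frame(tx, idx)) return("frameshift")
  removed <- oracle_removed_aa(tx, idx)
  if (length(removed) == 0L || nrow(domains) == 0L) return("no_domain_removed")
  inside <- partial <- 0L
  for (d in seq_len(nrow(domains))) {
    res <- seq.int(domains$aa_start[d], domains$aa_end[d])
    hit <- res %in% removed
    if (all(hit)) inside <- inside + 1L
    else if (any(hit)) partial <- partial + 1L
  }
  if (partial > 0L) "partial_domain_disruption"
  else if (inside == 1L) "clean_single_domain"
  else if (inside >= 2L) "clean_multi_domain"
  else "no_domain_removed"
}

# exhaustive maximum nested pairing (no DP): recursion over all structures
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(seq), "")[[1]]
  ok <- function(x, y) paste0(x, y) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(b[i], b[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(b) < 2L) return(0L)
  rec(1L, length(b))
}

# spreadsheet-style nearest-neighbor Tm: parameters re-entered by hand from
# the RNA:RNA Watson-Crick tables and summed positionally; the duplex is
# read from the complement side to keep the summation independent
ORACLE_NN <- data.frame(
  stack = c("AA", "AU", "UA", "CU", "CA", "GU", "GA", "CG", "GG", "GC"),
  dh = c(-6.82, -9.38, -7.69, -10.48, -10.44, -11.40, -12.44, -10.64,
         -13.39, -14.88),
  ds = c(-19.0, -26.7, -20.5, -27.1, -26.9, -29.5, -32.5, -26.7, -32.7,
         -36.9),
  stringsAsFactors = FALSE
)

oracle_tm <- function(seq, ct = 250e-9, na = 0.1) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  dh <- 3.61; ds <- -1.5
  for (i in seq_len(n - 1L)) {
    top <- paste0(b[i], b[i + 1L])
    # each duplex stack can be read from either strand; the table holds one
    # orientation, the other is the reverse complement read backwards
    alt <- paste0(comp[b[i + 1L]], comp[b[i]])
    row <- match(top, ORACLE_NN$stack)
    if (is.na(row)) row <- match(alt, ORACLE_NN$stack)
    dh <- dh + ORACLE_NN$dh[row]
    ds <- ds + ORACLE_NN$ds[row]
  }
  if (b[1] %in% c("A", "U")) { dh <- dh + 3.72; ds <- ds + 10.5 }
  if (b[n] %in% c("A", "U")) { dh <- dh + 3.72; ds <- ds + 10.5 }
  self_comp <- identical(paste(b, collapse = ""),
                         paste(rev(unname(comp[b])), collapse = ""))
  x <- if (self_comp) 1 else 4
  dh * 1000 / (ds + 1.9872 * log(ct / x)) - 273.15 + 16.6 * log10(na)
}

# per-position PSSM scores by explicit double loop
oracle_pssm_scores <- function(seq, weights) {
  b <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  w <- nrow(weights)
  base_col <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  n <- length(b) - w + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (s in seq_len(n)) {
    acc <- 0
    for (p in seq_len(w)) acc <- acc + weights[p, base_col[b[s + p - 1L]]]
    out[s] <- acc
  }
  out
}
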