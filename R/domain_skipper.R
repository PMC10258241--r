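# Enumeration and classification of contiguous exon skip candidates by
# their protein-domain impact, plus the ranking used to pick therapeutic
# targets: in-frame combinations that cleanly remove exactly one repetitive
# domain (e.g. one FN3 repeat of usherin) score highest, refined by
# loss-of-function variant burden and estimated population reach.

IMPACT_LEVELS <- c("clean_single_domain", "clean_multi_domain",
                   "no_domain_removed", "partial_domain_disruption",
                   "frameshift")

#' Load protein domain annotations
#'
#' @param path TSV with columns `name`, `ordinal`, `aa_start`, `aa_end`
#'   (1-based inclusive amino-acid coordinates on the translated product)
#' @param tx optional `transcript` to validate the intervals against
#' @return data.frame of domains sorted by `aa_start`
#' @export
load_domains <- function(path, tx = NULL) {
  if (!file.exists(path)) stopf("domain file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "ordinal", "aa_start", "aa_end")
  if (!all(need %in% names(d)))
    stopf("domain TSV must have columns: %s", paste(need, collapse = ", "))
  validate_domains(d, tx)
}

validate_domains <- function(d, tx = NULL) {
  d <- d[order(d$aa_start), , drop = FALSE]
  if (any(d$aa_start < 1L) || any(d$aa_end < d$aa_start))
    stopf("domain intervals must satisfy 1 <= aa_start <= aa_end")
  if (nrow(d) > 1L && any(d$aa_start[-1L] <= d$aa_end[-nrow(d)]))
    stopf("domain intervals may not overlap")
  if (!is.null(tx) && any(d$aa_end > nchar(tx$protein_seq)))
    stopf("domain extends beyond the %d-aa protein", nchar(tx$protein_seq))
  rownames(d) <- NULL
  d
}

#' Map a protein domain onto the exons that encode it
#'
#' Returns the minimal contiguous exon run whose CDS covers every codon of
#' the domain, and whether the domain boundaries coincide exactly with exon
#' boundaries (the precondition for a skip that removes the domain and
#' nothing else).
#'
#' @param domain one-row data.frame (or list) with `aa_start`, `aa_end`
#' @param tx a `transcript`
#' @return list with `exon_start`, `exon_end`, `start_coincides`,
#'   `end_coincides`
#' @export
map_domain_to_exons <- function(domain, tx) {
  stopifnot(inherits(tx, "transcript"))
  s <- as.integer(domain$aa_start); e <- as.integer(domain$aa_end)
  if (s < 1L || e > nchar(tx$protein_seq)) stopf("domain outside protein")
  cds_a <- (s - 1L) * 3L          # 0-based CDS interval of the domain codons
  cds_b <- e * 3L
  ex <- tx$exons
  cum <- cumsum(c(0L, ex$cds_nt))  # CDS offset at the start of each exon
  covers <- which(ex$cds_nt > 0L & cum[-length(cum)] < cds_b & cum[-1L] > cds_a)
  list(
    exon_start = covers[1L],
    exon_end = covers[length(covers)],
    start_coincides = cum[covers[1L]] == cds_a,
    end_coincides = cum[covers[length(covers)] + 1L] == cds_b
  )
}

# whole-codon removed amino-acid interval for a contiguous skip, NULL when
# frame-disrupting or non-coding (see protein_consequence for the rule)
removed_interval <- function(cons) {
  if (!cons$frame_preserving || is.na(cons$removed_aa_start)) return(NULL)
  c(cons$removed_aa_start, cons$removed_aa_end)
}

#' Classify the domain impact of a skip candidate
#'
#' A skip is `clean_single_domain` when exactly one annotated domain lies
#' entirely inside the removed amino-acid interval and no domain is cut by
#' its boundaries; `clean_multi_domain` when two or more do. Linker residues
#' between domains are unassigned and never veto a clean call. Any domain
#' partially overlapped by the removal is `partial_domain_disruption`;
#' frame-disrupting skips are `frameshift` regardless of domains.
#'
#' @param cons a `protein_consequence`
#' @param domains domain data.frame (see [load_domains()])
#' @return list with `impact_class` and `removed_domains` (row subset)
#' @export
classify_skip <- function(cons, domains) {
  if (!cons$frame_preserving)
    return(list(impact_class = "frameshift", removed_domains = domains[0, , drop = FALSE]))
  ri <- removed_interval(cons)
  if (is.null(ri) || nrow(domains) == 0L)
    return(list(impact_class = "no_domain_removed", removed_domains = domains[0, , drop = FALSE]))
  inside <- domains$aa_start >= ri[1L] & domains$aa_end <= ri[2L]
  overlaps <- domains$aa_start <= ri[2L] & domains$aa_end >= ri[1L]
  partial <- overlaps & !inside
  cls <- if (any(partial)) "partial_domain_disruption"
         else if (sum(inside) == 1L) "clean_single_domain"
         else if (sum(inside) >= 2L) "clean_multi_domain"
         else "no_domain_removed"
  list(impact_class = cls, removed_domains = domains[inside, , drop = FALSE])
}

#' Enumerate contiguous exon skip candidates
#'
#' One candidate per contiguous run of internal coding exons of length up to
#' `max_exons`. The first and last coding exons are never candidates (their
#' loss removes the start or stop codon). Each candidate carries its frame
#' status, protein consequence and domain-impact class; variant burden and
#' reach are zero until [add_variant_metrics()] fills them in.
#'
#' @param tx a `transcript`
#' @param domains domain data.frame (may be empty)
#' @param max_exons maximum number of consecutive exons per candidate
#'   (default 2, the dual-skip scope)
#' @return data.frame of class `skip_candidates`, one row per candidate
#' @export
enumerate_skip_candidates <- function(tx, domains = NULL, max_exons = 2L) {
  stopifnot(inherits(tx, "transcript"), max_exons >= 1L)
  if (is.null(domains)) {
    domains <- data.frame(name = character(0), ordinal = integer(0),
                          aa_start = integer(0), aa_end = integer(0))
  } else domains <- validate_domains(domains, tx)
  coding <- which(tx$exons$cds_nt > 0L)
  internal <- coding[-c(1L, length(coding))]
  rows <- list()
  for (i in internal) {
    for (k in seq_len(max_exons)) {
      j <- i + k - 1L
      if (!(j %in% internal)) break
      cons <- protein_consequence(tx, i:j)
      cls <- classify_skip(cons, domains)
      rows[[length(rows) + 1L]] <- data.frame(
        exon_start = i, exon_end = j, n_exons = k,
        skipped_cds_nt = cons$skipped_cds_nt,
        frame_preserving = cons$frame_preserving,
        impact_class = cls$impact_class,
        removed_domains = paste(
          sprintf("%s(%s)", cls$removed_domains$name, cls$removed_domains$ordinal),
          collapse = ","),
        n_removed_domains = nrow(cls$removed_domains),
        removed_aa_start = cons$removed_aa_start,
        removed_aa_end = cons$removed_aa_end,
        junction_residue = cons$junction_residue,
        hgvs_p = cons$hgvs_p,
        burden = 0L, a_target = 0, reach = 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exon_start = integer(0))
  class(out) <- c("skip_candidates", "data.frame")
  out
}

#' Attach variant burden and population reach to skip candidates
#'
#' @param candidates output of [enumerate_skip_candidates()]
#' @param variants variant table from [load_variants()]
#' @param population population size for the reach estimate (default 8e9)
#' @param lof_classes consequence classes counted as loss of function
#' @return candidates with `burden`, `a_target` and `reach` filled in
#' @export
add_variant_metrics <- function(candidates, variants,
                                population = 8e9,
                                lof_classes = c("nonsense", "frameshift",
                                                "canonical_splice")) {
  lof <- variants[!is.na(variants$exon_index) &
                    variants$consequence_class %in% lof_classes, , drop = FALSE]
  lof <- lof[!duplicated(lof$hgvs_c), , drop = FALSE]
  a_gene <- sum(lof$allele_frequency)
  for (r in seq_len(nrow(candidates))) {
    rng <- candidates$exon_start[r]:candidates$exon_end[r]
    sel <- lof$exon_index %in% rng
    candidates$burden[r] <- sum(sel)
    a_t <- sum(lof$allele_frequency[sel])
    candidates$a_target[r] <- a_t
    candidates$reach[r] <- estimate_reach(a_t, a_gene, population)$eligible_affected
  }
  candidates
}

#' Rank skip candidates
#'
#' Total order: impact class first (`clean_single_domain`,
#' `clean_multi_domain`, `no_domain_removed`, `partial_domain_disruption`,
#' `frameshift`), then reach descending, burden descending, fewer exons, and
#' finally the exon range itself as a deterministic tie-break.
#'
#' @param candidates data.frame from [enumerate_skip_candidates()]
#' @return the same rows, ordered best-first, with a `rank` column
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  cls <- match(candidates$impact_class, IMPACT_LEVELS)
  ord <- order(cls, -candidates$reach, -candidates$burden,
               candidates$n_exons, candidates$exon_start, candidates$exon_end)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
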