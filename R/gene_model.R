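# Gene/transcript model: exact coordinate arithmetic between genomic,
# transcript, coding (c.) and protein (p.) spaces, plus application of
# exon-skip events and protein-level consequence calling.
#
# Conventions:
#   * exon index = 1-based 5'->3' rank within the transcript (the numbering
#     clinicians use, e.g. "exons 30-31");
#   * genomic intervals are 0-based half-open on the + strand of the
#     reference, regardless of transcript strand;
#   * transcript (tx) and CDS intervals are 0-based half-open;
#   * all emitted HGVS-style text is 1-based inclusive.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a transcript from exon sequences
#'
#' Low-level constructor used by [load_gene_model()], the synthetic fixture
#' generator and tests. Exon sequences must already be in transcript (sense)
#' orientation and 5'->3' order; for minus-strand genes the genomic
#' intervals therefore descend along the chromosome.
#'
#' @param tx_id,gene_id,chrom,strand identifiers; `strand` is `"+"` or `"-"`
#' @param exon_seqs character vector of exon sequences, 5'->3' transcript order
#' @param cds_start 0-based transcript offset of the first CDS base (the A of
#'   the ATG)
#' @param cds_len CDS length in nt, terminal stop codon included
#' @param gstarts,gends optional 0-based half-open genomic intervals per exon
#'   (+ strand). When omitted, synthetic coordinates with 100-nt introns are
#'   assigned.
#' @param validate enforce invariants (CDS divisible by 3, stop-terminated,
#'   no internal stop, non-overlapping exons). Edited transcripts produced by
#'   [apply_skip()] relax this.
#' @return an object of class `transcript`
#' @export
new_transcript <- function(tx_id, exon_seqs, cds_start, cds_len,
                           gene_id = tx_id, chrom = "chr_toy", strand = "+",
                           gstarts = NULL, gends = NULL, validate = TRUE) {
  exon_seqs <- vapply(exon_seqs, as_dna, character(1), USE.NAMES = FALSE)
  n <- length(exon_seqs)
  if (n < 1L) stopf("transcript %s has no exons", tx_id)
  lens <- nchar(exon_seqs)
  tx_end <- cumsum(lens)
  tx_start <- tx_end - lens

  if (is.null(gstarts) || is.null(gends)) {
    intron <- 100L
    gs <- integer(n); ge <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      gs[i] <- pos; ge[i] <- pos + lens[i]; pos <- ge[i] + intron
    }
    if (strand == "-") {
      # exon i (tx order) sits at descending genomic coordinates
      total <- pos - intron
      pos <- total
      for (i in seq_len(n)) { ge[i] <- pos; gs[i] <- pos - lens[i]; pos <- gs[i] - intron }
    }
    gstarts <- gs; gends <- ge
  }
  if (length(gstarts) != n || length(gends) != n)
    stopf("transcript %s: genomic intervals do not match exon count", tx_id)
  if (any(gends - gstarts != lens))
    stopf("transcript %s: genomic interval widths disagree with exon sequence lengths", tx_id)

  spliced <- paste0(exon_seqs, collapse = "")
  tx_len <- nchar(spliced)
  if (cds_start < 0L || cds_start + cds_len > tx_len)
    stopf("transcript %s: CDS [%d, %d) outside transcript of length %d",
          tx_id, cds_start, cds_start + cds_len, tx_len)

  cds_seq <- substr(spliced, cds_start + 1L, cds_start + cds_len)
  aa_full <- translate_cds(cds_seq)

  if (validate) {
    if (cds_len %% 3L != 0L)
      stopf("transcript %s: CDS length %d is not divisible by 3", tx_id, cds_len)
    ord <- order(gstarts)
    if (any(gstarts[ord][-1L] < gends[ord][-n]))
      stopf("transcript %s: overlapping exons", tx_id)
    body <- substr(aa_full, 1L, nchar(aa_full) - 1L)
    if (grepl("*", body, fixed = TRUE))
      stopf("transcript %s: internal stop codon in CDS", tx_id)
    if (substr(aa_full, nchar(aa_full), nchar(aa_full)) != "*")
      stopf("transcript %s: CDS does not end in a stop codon", tx_id)
  }
  protein <- sub("\\*$", "", aa_full)

  # per-exon CDS overlap and phase chain
  cds_nt <- mapply(function(s, e) interval_overlap(s, e, cds_start, cds_start + cds_len),
                   tx_start, tx_end)
  cum_before <- cumsum(c(0L, cds_nt))[seq_len(n)]
  start_phase <- ifelse(cds_nt > 0L, cum_before %% 3L, -1L)
  end_phase <- ifelse(cds_nt > 0L, (cum_before + cds_nt) %% 3L, -1L)

  exons <- data.frame(
    index = seq_len(n),
    gstart = as.integer(gstarts), gend = as.integer(gends),
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    length_nt = as.integer(lens),
    cds_nt = as.integer(cds_nt),
    start_phase = as.integer(start_phase), end_phase = as.integer(end_phase),
    seq = exon_seqs,
    stringsAsFactors = FALSE
  )

  structure(list(
    tx_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, spliced_seq = spliced,
    cds_start = as.integer(cds_start), cds_len = as.integer(cds_len),
    cds_seq = cds_seq, protein_seq = protein
  ), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %s:%s, %d exons, %d nt spliced, CDS %d nt, %d aa\n",
              x$tx_id, x$chrom, x$strand, nrow(x$exons), nchar(x$spliced_seq),
              x$cds_len, nchar(x$protein_seq)))
  invisible(x)
}

#' Per-exon reading-frame phases
#'
#' Returns the codon phase at which each exon starts and ends (0/1/2;
#' -1 for exons without CDS overlap). The chain property
#' `end_phase(k) = (start_phase(k) + cds_nt(k)) mod 3` and
#' `start_phase(k+1) = end_phase(k)` for consecutive coding exons holds by
#' construction.
#'
#' @param tx a `transcript`
#' @return data.frame with columns `index`, `cds_nt`, `start_phase`, `end_phase`
#' @export
exon_phases <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  tx$exons[, c("index", "cds_nt", "start_phase", "end_phase")]
}

# ---- coordinate maps --------------------------------------------------------

#' Map transcript positions to genomic positions
#'
#' @param tx a `transcript`
#' @param pos 0-based transcript positions
#' @return 0-based genomic positions on the + strand
#' @export
tx_to_genomic <- function(tx, pos) {
  ex <- tx$exons
  vapply(pos, function(p) {
    i <- which(p >= ex$tx_start & p < ex$tx_end)
    if (length(i) != 1L) stopf("transcript position %d out of range", p)
    off <- p - ex$tx_start[i]
    if (tx$strand == "+") ex$gstart[i] + off else ex$gend[i] - 1L - off
  }, numeric(1))
}

#' Map genomic positions to transcript positions
#'
#' @param tx a `transcript`
#' @param gpos 0-based genomic positions (+ strand)
#' @return 0-based transcript positions; `NA` for intronic/intergenic input
#' @export
genomic_to_tx <- function(tx, gpos) {
  ex <- tx$exons
  vapply(gpos, function(g) {
    i <- which(g >= ex$gstart & g < ex$gend)
    if (length(i) != 1L) return(NA_real_)
    if (tx$strand == "+") ex$tx_start[i] + (g - ex$gstart[i])
    else ex$tx_start[i] + (ex$gend[i] - 1L - g)
  }, numeric(1))
}

# exon index containing a 1-based coding (c.) position, NA if outside CDS
exon_of_cds_pos <- function(tx, cpos) {
  tpos <- tx$cds_start + cpos - 1L
  ex <- tx$exons
  i <- which(tpos >= ex$tx_start & tpos < ex$tx_end)
  if (length(i) != 1L || cpos < 1L || cpos > tx$cds_len) NA_integer_ else i
}

# ---- loading ----------------------------------------------------------------

#' Load a gene model from GFF3 (or exon TSV) plus FASTA
#'
#' GFF3 input follows the usual gene/mRNA/exon/CDS layout with `ID`/`Parent`
#' attributes (one CDS chain per transcript). The TSV dialect has columns
#' `tx_id, exon_index, chrom, start, end, strand, cds_start, cds_end` with
#' 1-based inclusive coordinates and `NA` CDS columns for non-coding exons.
#' Minus-strand features are reverse-complemented into transcript
#' orientation. The CDS must be stop-terminated; annotations that exclude
#' the stop codon are accepted when the next in-frame codon in the
#' transcript is a stop (it is then folded into the CDS).
#'
#' @param annotation_path GFF3 (`.gff`/`.gff3`) or TSV file
#' @param sequence_path FASTA with the chromosome/contig sequences
#' @return a `gene_model` object (list of `transcript`s)
#' @export
load_gene_model <- function(annotation_path, sequence_path) {
  if (!file.exists(annotation_path)) stopf("annotation file not found: %s", annotation_path)
  if (!file.exists(sequence_path)) stopf("sequence file not found: %s", sequence_path)
  genome <- Biostrings::readDNAStringSet(sequence_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ext <- tolower(tools::file_ext(annotation_path))
  if (ext %in% c("gff", "gff3")) {
    load_gene_model_gff3(annotation_path, genome)
  } else {
    load_gene_model_tsv(annotation_path, genome)
  }
}

chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stopf("sequence '%s' referenced by the annotation is missing from the FASTA", chrom)
  as.character(genome[[chrom]])
}

build_tx_from_intervals <- function(tx_id, gene_id, chrom, strand,
                                    ex_start, ex_end, cds_gstart, cds_gend,
                                    genome) {
  # ex_* : 0-based half-open genomic exon intervals (+ strand, any order)
  # cds_gstart/cds_gend: per-exon CDS genomic intervals (NA where non-coding)
  ord <- if (strand == "+") order(ex_start) else order(-ex_start)
  ex_start <- ex_start[ord]; ex_end <- ex_end[ord]
  cds_gstart <- cds_gstart[ord]; cds_gend <- cds_gend[ord]
  cseq <- chrom_seq(genome, chrom)
  seqs <- substring(cseq, ex_start + 1L, ex_end)
  if (strand == "-") seqs <- vapply(seqs, revcomp_dna, character(1), USE.NAMES = FALSE)

  lens <- ex_end - ex_start
  tx_end <- cumsum(lens); tx_start <- tx_end - lens

  coding <- which(!is.na(cds_gstart))
  if (length(coding) == 0L) stopf("transcript %s has no CDS", tx_id)
  # transcript offset of the translation start: first coding exon in tx order
  i1 <- coding[1L]; ilast <- coding[length(coding)]
  if (strand == "+") {
    cds_start <- tx_start[i1] + (cds_gstart[i1] - ex_start[i1])
    cds_end_tx <- tx_start[ilast] + (cds_gend[ilast] - ex_start[ilast])
  } else {
    cds_start <- tx_start[i1] + (ex_end[i1] - cds_gend[i1])
    cds_end_tx <- tx_start[ilast] + (ex_end[ilast] - cds_gstart[ilast])
  }
  cds_len <- as.integer(cds_end_tx - cds_start)
  spliced <- paste0(seqs, collapse = "")

  if (cds_len %% 3L != 0L)
    stopf("transcript %s: CDS length %d is not divisible by 3", tx_id, cds_len)
  # tolerate stop-codon-excluded CDS annotations
  last_codon <- substr(spliced, cds_start + cds_len - 2L, cds_start + cds_len)
  if (!(last_codon %in% STOP_CODONS)) {
    nxt <- substr(spliced, cds_start + cds_len + 1L, cds_start + cds_len + 3L)
    if (nxt %in% STOP_CODONS) cds_len <- cds_len + 3L
    else stopf("transcript %s: CDS does not end in a stop codon", tx_id)
  }
  new_transcript(tx_id, seqs, cds_start, cds_len, gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 gstarts = ex_start, gends = ex_end)
}

load_gene_model_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  get_parent <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }
  parents <- vapply(seq_along(gr), get_parent, character(1))
  ids <- if ("ID" %in% colnames(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))

  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  if (length(mrna_idx) == 0L) stopf("no mRNA/transcript features in %s", path)

  txs <- list()
  for (mi in mrna_idx) {
    tx_id <- ids[mi]
    gene_id <- if (is.na(parents[mi])) tx_id else parents[mi]
    kids <- which(parents == tx_id)
    exi <- kids[type[kids] == "exon"]
    cdsi <- kids[type[kids] == "CDS"]
    if (length(exi) == 0L) stopf("transcript %s has no exon features", tx_id)
    if (length(cdsi) == 0L) stopf("transcript %s has no CDS features", tx_id)
    strand <- as.character(BiocGenerics::strand(gr[mi]))
    chrom <- as.character(GenomicRanges::seqnames(gr[mi]))
    ex_start <- BiocGenerics::start(gr[exi]) - 1L  # to 0-based half-open
    ex_end <- BiocGenerics::end(gr[exi])
    cs <- BiocGenerics::start(gr[cdsi]) - 1L
    ce <- BiocGenerics::end(gr[cdsi])
    # assign each CDS piece to its exon
    cds_gstart <- rep(NA_integer_, length(exi)); cds_gend <- rep(NA_integer_, length(exi))
    for (k in seq_along(cs)) {
      j <- which(cs[k] >= ex_start & ce[k] <= ex_end)
      if (length(j) != 1L)
        stopf("transcript %s: CDS segment [%d,%d) not contained in a single exon",
              tx_id, cs[k], ce[k])
      if (!is.na(cds_gstart[j]))
        stopf("transcript %s: more than one CDS segment in exon at [%d,%d)",
              tx_id, ex_start[j], ex_end[j])
      cds_gstart[j] <- cs[k]; cds_gend[j] <- ce[k]
    }
    txs[[tx_id]] <- build_tx_from_intervals(tx_id, gene_id, chrom, strand,
                                            ex_start, ex_end, cds_gstart, cds_gend,
                                            genome)
  }
  new_gene_model(txs)
}

load_gene_model_tsv <- function(path, genome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tx_id", "exon_index", "chrom", "start", "end", "strand",
            "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stopf("exon TSV must have columns: %s", paste(need, collapse = ", "))
  txs <- list()
  for (id in unique(tab$tx_id)) {
    t1 <- tab[tab$tx_id == id, ]
    t1 <- t1[order(t1$exon_index), ]
    strand <- t1$strand[1L]
    txs[[id]] <- build_tx_from_intervals(
      id, id, t1$chrom[1L], strand,
      as.integer(t1$start) - 1L, as.integer(t1$end),
      ifelse(is.na(t1$cds_start), NA_integer_, as.integer(t1$cds_start) - 1L),
      ifelse(is.na(t1$cds_end), NA_integer_, as.integer(t1$cds_end)),
      genome)
  }
  new_gene_model(txs)
}

new_gene_model <- function(txs) {
  stopifnot(length(txs) >= 1L)
  strands <- unique(vapply(txs, `[[`, character(1), "strand"))
  if (length(strands) != 1L) stopf("all transcripts of a gene model must share a strand")
  structure(list(
    gene_id = txs[[1L]]$gene_id,
    chromosome = txs[[1L]]$chrom,
    strand = strands,
    transcripts = txs
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s:%s, %d transcript(s)\n",
              x$gene_id, x$chromosome, x$strand, length(x$transcripts)))
  for (tx in x$transcripts) print(tx)
  invisible(x)
}

# ---- skip events ------------------------------------------------------------

# normalize events (an integer vector or a list of contiguous ranges) into a
# sorted vector of unique exon indices; each event must be contiguous
normalize_events <- function(tx, events) {
  if (!is.list(events)) events <- list(events)
  idx <- integer(0)
  for (ev in events) {
    ev <- sort(unique(as.integer(ev)))
    if (length(ev) == 0L) next
    if (any(diff(ev) != 1L)) stopf("a skip event must be a contiguous exon range")
    if (ev[1L] < 1L || ev[length(ev)] > nrow(tx$exons))
      stopf("skip event references exon outside 1..%d", nrow(tx$exons))
    if (any(ev %in% idx)) stopf("skip events overlap")
    idx <- c(idx, ev)
  }
  sort(idx)
}

#' Apply exon-skip events to a transcript
#'
#' Removes the given exons and rebuilds the spliced transcript. The edited
#' CDS start is shifted by any removed 5'-UTR nucleotides; for
#' frame-disrupting skips the edited protein is translated from the original
#' start codon to the first stop encountered.
#'
#' @param tx a `transcript`
#' @param events an integer vector of exon indices forming a contiguous run,
#'   or a list of such runs (e.g. an intended skip plus a co-skip)
#' @return the edited `transcript` (unvalidated; attribute `"skipped"` holds
#'   the removed exon indices)
#' @export
apply_skip <- function(tx, events) {
  stopifnot(inherits(tx, "transcript"))
  skipped <- normalize_events(tx, events)
  if (length(skipped) == 0L) return(tx)
  keep <- setdiff(seq_len(nrow(tx$exons)), skipped)
  if (sum(tx$exons$cds_nt[keep]) == 0L)
    stopf("skip of %s would remove every coding exon", paste(range(skipped), collapse = ".."))

  ex <- tx$exons
  removed_before_cds <- sum(pmax(0L, pmin(ex$tx_end[skipped], tx$cds_start) - ex$tx_start[skipped]))
  removed_cds <- sum(ex$cds_nt[skipped])
  new_cds_start <- tx$cds_start - removed_before_cds
  nominal_cds_len <- tx$cds_len - removed_cds

  edited <- new_transcript(
    tx_id = paste0(tx$tx_id, "_", skip_label(skipped)),
    exon_seqs = ex$seq[keep],
    cds_start = new_cds_start,
    cds_len = nominal_cds_len,
    gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
    gstarts = ex$gstart[keep], gends = ex$gend[keep],
    validate = FALSE
  )
  if (removed_cds %% 3L != 0L) {
    # frameshift: re-derive protein by scanning for the first in-frame stop
    spliced <- edited$spliced_seq
    orf <- substr(spliced, new_cds_start + 1L, nchar(spliced))
    aa <- translate_cds(orf)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    edited$protein_seq <- if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa
    edited$cds_seq <- orf
  }
  attr(edited, "skipped") <- skipped
  edited
}

skip_label <- function(skipped) paste0("dex", paste(skipped, collapse = "_"))

#' Isoform label for a skip event set ("Dex30Dex31" style uses Greek delta)
#' @keywords internal
isoform_label <- function(skipped) {
  if (length(skipped) == 0L) return("full")
  paste0(sprintf("Δex%d", skipped), collapse = "")
}

# ---- protein consequence ----------------------------------------------------

AA1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

#' Protein-level consequence of a skip event set
#'
#' For frame-preserving skips the removed amino-acid interval is computed on
#' whole codons: a codon split by the skip boundary counts as removed only
#' when at least two of its three nucleotides are removed, matching the
#' observed persistence of hybrid junction codons as a (possibly novel)
#' residue. When the skip starts mid-codon (start phase != 0) the hybrid
#' codon formed by the retained 5' leftover and the first retained 3' bases
#' is translated: if it recreates a reference residue a plain `del` is
#' emitted, otherwise `delins<X>`. Frame-disrupting skips are reported with
#' `frame_preserving = FALSE` and no deletion interval.
#'
#' @param tx a `transcript`
#' @param events as in [apply_skip()]
#' @return list of class `protein_consequence` with fields
#'   `removed_aa_start`, `removed_aa_end`, `junction_residue`,
#'   `frame_preserving`, `skipped_cds_nt`, `hgvs_p`
#' @export
protein_consequence <- function(tx, events) {
  stopifnot(inherits(tx, "transcript"))
  skipped <- normalize_events(tx, events)
  ex <- tx$exons
  res <- list(removed_aa_start = NA_integer_, removed_aa_end = NA_integer_,
              junction_residue = NA_character_, frame_preserving = TRUE,
              skipped_cds_nt = 0L, hgvs_p = NA_character_)
  class(res) <- "protein_consequence"
  if (length(skipped) == 0L) {
    res$hgvs_p <- "p.(=)"
    return(res)
  }
  removed_cds <- sum(ex$cds_nt[skipped])
  res$skipped_cds_nt <- as.integer(removed_cds)
  if (removed_cds == 0L) { res$hgvs_p <- "p.(=)"; return(res) }
  if (removed_cds %% 3L != 0L) {
    res$frame_preserving <- FALSE
    return(res)
  }
  if (any(diff(skipped) != 1L)) {
    # non-contiguous removal: frame logic above still applies, but a single
    # deletion interval does not; callers get per-block consequences instead
    blocks <- split(skipped, cumsum(c(1L, diff(skipped) != 1L)))
    res$blocks <- lapply(blocks, function(b) protein_consequence(tx, b))
    return(res)
  }

  # contiguous block: CDS interval [a, b) removed (0-based within CDS)
  coding <- skipped[ex$cds_nt[skipped] > 0L]
  first <- coding[1L]
  cum_before <- cumsum(c(0L, ex$cds_nt))[first]
  a <- cum_before
  b <- a + removed_cds
  p <- a %% 3L
  m <- removed_cds %/% 3L
  k <- a %/% 3L                       # 0-based index of codon containing a
  prot <- tx$protein_seq
  aa_at <- function(i) substr(prot, i, i)

  if (p == 0L) {
    rs <- k + 1L; re <- k + m
    res$removed_aa_start <- rs; res$removed_aa_end <- re
    res$hgvs_p <- hgvs_del(aa_at(rs), rs, aa_at(re), re)
    return(res)
  }
  # hybrid codon: retained 5' leftover + first retained 3' bases
  cds <- tx$cds_seq
  left <- substr(cds, 3L * k + 1L, 3L * k + p)
  right <- substr(cds, b + 1L, b + (3L - p))
  if (nchar(right) < 3L - p) {
    # skip runs into the stop codon region; treat as plain C-terminal del
    rs <- k + 1L; re <- k + m
    res$removed_aa_start <- rs; res$removed_aa_end <- re
    res$hgvs_p <- hgvs_del(aa_at(rs), rs, aa_at(re), re)
    return(res)
  }
  hybrid <- translate_cds(paste0(left, right))
  res$junction_residue <- hybrid
  # affected reference residues: codon k .. codon k+m (m+1 residues -> 1)
  first_aa <- k + 1L; last_aa <- k + m + 1L
  if (identical(hybrid, aa_at(first_aa))) {
    rs <- first_aa + 1L; re <- last_aa
    res$removed_aa_start <- rs; res$removed_aa_end <- re
    res$junction_residue <- NA_character_
    res$hgvs_p <- hgvs_del(aa_at(rs), rs, aa_at(re), re)
  } else if (identical(hybrid, aa_at(last_aa))) {
    rs <- first_aa; re <- last_aa - 1L
    res$removed_aa_start <- rs; res$removed_aa_end <- re
    res$junction_residue <- NA_character_
    res$hgvs_p <- hgvs_del(aa_at(rs), rs, aa_at(re), re)
  } else {
    # m+1 residues replaced by the hybrid one; net loss is m residues.
    # The whole-codon removed interval (codons losing >=2 nt) spans m codons:
    if (p == 1L) { res$removed_aa_start <- first_aa; res$removed_aa_end <- last_aa - 1L }
    else { res$removed_aa_start <- first_aa + 1L; res$removed_aa_end <- last_aa }
    res$hgvs_p <- sprintf("p.%s%d_%s%ddelins%s",
                          aa_at(first_aa), first_aa, aa_at(last_aa), last_aa, hybrid)
  }
  res
}

hgvs_del <- function(aa1, p1, aa2, p2) {
  if (p1 == p2) sprintf("p.%s%ddel", aa1, p1)
  else sprintf("p.%s%d_%s%ddel", aa1, p1, aa2, p2)
}

#' @export
print.protein_consequence <- function(x, ...) {
  if (!x$frame_preserving) {
    cat(sprintf("frameshift (skipped CDS %d nt, not divisible by 3)\n", x$skipped_cds_nt))
  } else {
    cat(sprintf("%s (removed aa %s..%s, skipped CDS %d nt)\n",
                x$hgvs_p, x$removed_aa_start, x$removed_aa_end, x$skipped_cds_nt))
  }
  invisible(x)
}

# ---- reference fact reporting ----------------------------------------------

#' Summary facts of a transcript annotation
#'
#' Convenience report used to sanity-check a loaded annotation against
#' externally published facts about a transcript (exon count, per-exon CDS
#' lengths, conceptual translation length): e.g. for human USH2A isoform B
#' one expects 72 exons, a 5,202-aa translation, and CDS sums of 306 nt over
#' exons 30-31 and 294 nt over exons 39-40.
#'
#' @param tx a `transcript`
#' @return list with `n_exons`, `protein_aa`, `cds_nt`, `exon_cds_nt`
#' @export
transcript_fact_report <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  list(
    tx_id = tx$tx_id,
    n_exons = nrow(tx$exons),
    protein_aa = nchar(tx$protein_seq),
    cds_nt = tx$cds_len,
    exon_cds_nt = stats::setNames(tx$exons$cds_nt, tx$exons$index)
  )
}

#' Count single exons skippable without disturbing the reading frame
#'
#' Reported under two definitions, since published counts rarely state
#' which is meant: (a) internal coding exons whose CDS length is divisible
#' by three (the pure frame rule), and (b) those that additionally do not
#' create a premature stop codon at the new exon junction. Both index sets
#' are returned.
#'
#' @param tx a `transcript`
#' @return list with `n_frame`, `n_frame_stop_free`, `frame_exons`,
#'   `stop_free_exons`
#' @export
count_inframe_exons <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  coding <- which(tx$exons$cds_nt > 0L)
  internal <- coding[-c(1L, length(coding))]
  frame_ok <- internal[tx$exons$cds_nt[internal] %% 3L == 0L]
  stop_free <- frame_ok[vapply(frame_ok, function(i) {
    aa <- translate_cds(apply_skip(tx, i)$cds_seq)
    !grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)
  }, logical(1))]
  list(n_frame = length(frame_ok), n_frame_stop_free = length(stop_free),
       frame_exons = frame_ok, stop_free_exons = stop_free)
}

#' Summed CDS nucleotides over an exon range
#' @param tx a `transcript`
#' @param exon_range integer vector of exon indices
#' @export
exon_cds_sum <- function(tx, exon_range) {
  stopifnot(inherits(tx, "transcript"))
  sum(tx$exons$cds_nt[tx$exons$index %in% exon_range])
}
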