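# Deterministic synthetic genes with a repetitive domain architecture
# (a chain of identical-size FN3-like repeats, as in usherin) so every
# operation in the package is testable without annotation downloads. A
# designated two-exon pair encodes exactly one domain; its summed CDS
# length defaults to 306 nt (a 102-aa repeat), the size of the exemplar
# dual-skip target.

CODON_POOL <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0)), c("A", "C", "G", "T"), paste0)),
  c(STOP_CODONS, "ATG"))

#' Specification for a synthetic toy gene
#'
#' @param n_domains number of repeated domains (default 13, the FN3 count
#'   of the usherin mid-section)
#' @param domain_aa residues per domain (default 102, i.e. 306 nt per
#'   two-exon pair)
#' @param exons_per_domain 1 or 2 exons encoding each domain
#' @param linker_aa residues of unassigned linker before each domain,
#'   encoded by a dedicated in-frame exon when > 0
#' @param leader_aa,trailer_aa residues before the first / after the last
#'   domain (kept in the first/last coding exons)
#' @param utr5_nt,utr3_nt untranslated leaders on the terminal exons
#' @param intron_nt intron length (also the genomic flank length); must
#'   comfortably exceed the 50-nt ASO design flank
#' @param pair_phases recycled per domain: the exon phase at the internal
#'   junction of each two-exon pair (1 or 2 gives split codons)
#' @param strand `"+"` or `"-"`
#' @param seed integer; generation is bit-for-bit reproducible per seed
#' @export
fixture_spec <- function(n_domains = 13L, domain_aa = 102L,
                         exons_per_domain = 2L, linker_aa = 0L,
                         leader_aa = 10L, trailer_aa = 8L,
                         utr5_nt = 30L, utr3_nt = 40L, intron_nt = 150L,
                         pair_phases = c(1L, 2L), strand = "+", seed = 1L,
                         gene_id = "TOYG", tx_id = "TOYG-201",
                         chrom = "chr_toy") {
  stopifnot(n_domains >= 1L, domain_aa >= 2L, exons_per_domain %in% c(1L, 2L),
            linker_aa >= 0L, leader_aa >= 1L, trailer_aa >= 1L,
            utr5_nt >= 0L, utr3_nt >= 0L, intron_nt >= 20L,
            strand %in% c("+", "-"))
  if (any(!pair_phases %in% 0:2))
    stopf("pair_phases must be codon phases (0, 1 or 2)")
  if (exons_per_domain == 2L) {
    first <- 3L * (domain_aa %/% 2L) + pair_phases
    second <- 3L * domain_aa - first
    if (any(first < 6L | second < 6L))   # no micro-exons
      stopf("impossible phase pattern for domain of %d aa", domain_aa)
  }
  as.list(environment())
}

random_nt <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_codons <- function(n_aa) paste0(sample(CODON_POOL, n_aa, replace = TRUE),
                                       collapse = "")

#' Generate a toy gene fixture
#'
#' Builds the gene deterministically from a [fixture_spec()]: GFF3 text,
#' chromosome FASTA text, a domain annotation table, and the already
#' assembled `transcript`. The designated pair (`designated_exons`) is the
#' two-exon pair encoding the middle domain; skipping it removes exactly
#' that domain in frame.
#'
#' @param spec a [fixture_spec()]
#' @return list of class `toy_gene`: `spec`, `gff3`, `fasta`, `domains`,
#'   `tx`, `designated_exons`, `designated_domain`
#' @export
make_toy_gene <- function(spec) {
  with_seed(spec$seed, {
    e_per <- spec$exons_per_domain
    has_linker <- spec$linker_aa > 0L
    # protein layout (aa counts, stop excluded)
    n_aa <- 1L + spec$leader_aa +
      spec$n_domains * (spec$linker_aa + spec$domain_aa) + spec$trailer_aa
    cds_nt <- 3L * (n_aa + 1L)

    # exon CDS lengths in transcript order
    cds_lens <- 3L * (1L + spec$leader_aa)
    for (d in seq_len(spec$n_domains)) {
      if (has_linker) cds_lens <- c(cds_lens, 3L * spec$linker_aa)
      dom_nt <- 3L * spec$domain_aa
      if (e_per == 2L) {
        phase <- spec$pair_phases[(d - 1L) %% length(spec$pair_phases) + 1L]
        first <- 3L * (spec$domain_aa %/% 2L) + phase
        cds_lens <- c(cds_lens, first, dom_nt - first)
      } else {
        cds_lens <- c(cds_lens, dom_nt)
      }
    }
    cds_lens <- c(cds_lens, 3L * spec$trailer_aa + 3L)
    stopifnot(sum(cds_lens) == cds_nt)

    # sequence: ATG + body codons + stop, with UTRs on the terminal exons
    cds_seq <- paste0("ATG", random_codons(n_aa - 1L), "TAA")
    utr5 <- if (spec$utr5_nt > 0L) random_nt(spec$utr5_nt) else ""
    utr3 <- if (spec$utr3_nt > 0L) random_nt(spec$utr3_nt) else ""
    mrna <- paste0(utr5, cds_seq, utr3)

    exon_lens <- cds_lens
    exon_lens[1L] <- exon_lens[1L] + spec$utr5_nt
    exon_lens[length(exon_lens)] <- exon_lens[length(exon_lens)] + spec$utr3_nt
    ends <- cumsum(exon_lens)
    exon_seqs <- substring(mrna, c(1L, ends[-length(ends)] + 1L), ends)

    # genome assembly on the + strand
    n_ex <- length(exon_lens)
    introns <- vapply(seq_len(n_ex - 1L), function(i)
      paste0("GT", random_nt(spec$intron_nt - 4L), "AG"), character(1))
    flank5 <- random_nt(spec$intron_nt)
    flank3 <- random_nt(spec$intron_nt)
    pieces <- character(2L * n_ex + 1L)
    pieces[1L] <- flank5
    pieces[seq_len(n_ex) * 2L] <- exon_seqs
    if (n_ex > 1L) pieces[seq_len(n_ex - 1L) * 2L + 1L] <- introns
    pieces[2L * n_ex + 1L] <- flank3
    chrom_plus <- paste0(pieces, collapse = "")

    gstarts <- integer(n_ex); gends <- integer(n_ex)
    pos <- spec$intron_nt
    for (i in seq_len(n_ex)) {
      gstarts[i] <- pos; gends[i] <- pos + exon_lens[i]
      pos <- gends[i] + spec$intron_nt
    }
    if (spec$strand == "-") {
      chrom_seq <- revcomp_dna(chrom_plus)
      L <- nchar(chrom_seq)
      tmp <- L - gends
      gends <- L - gstarts
      gstarts <- tmp
    } else {
      chrom_seq <- chrom_plus
    }

    tx <- new_transcript(spec$tx_id, exon_seqs,
                         cds_start = spec$utr5_nt, cds_len = cds_nt,
                         gene_id = spec$gene_id, chrom = spec$chrom,
                         strand = spec$strand,
                         gstarts = gstarts, gends = gends)

    # domain annotation
    aa_starts <- 1L + spec$leader_aa +
      (seq_len(spec$n_domains) - 1L) * (spec$linker_aa + spec$domain_aa) +
      spec$linker_aa + 1L
    domains <- data.frame(
      name = "FN3", ordinal = seq_len(spec$n_domains),
      aa_start = aa_starts, aa_end = aa_starts + spec$domain_aa - 1L,
      stringsAsFactors = FALSE)

    mid <- (spec$n_domains + 1L) %/% 2L
    first_exon_of_domain <- 1L + (mid - 1L) * (e_per + has_linker) +
      has_linker + 1L
    designated <- first_exon_of_domain:(first_exon_of_domain + e_per - 1L)

    structure(list(
      spec = spec,
      gff3 = toy_gff3(spec, tx),
      fasta = paste0(">", spec$chrom, "\n", wrap_fasta(chrom_seq)),
      domains = domains,
      tx = tx,
      designated_exons = designated,
      designated_domain = mid
    ), class = "toy_gene")
  })
}

wrap_fasta <- function(seq, width = 70L) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = width)
  paste0(paste0(substring(seq, starts, pmin(starts + width - 1L, n)),
                collapse = "\n"), "\n")
}

toy_gff3 <- function(spec, tx) {
  # 1-based inclusive GFF3 on the chromosome; exon rows in genomic order
  ex <- tx$exons
  ord <- order(ex$gstart)
  lines <- c("##gff-version 3")
  gene_s <- min(ex$gstart) + 1L; gene_e <- max(ex$gend)
  f <- function(type, s, e, phase, attrs)
    paste(spec$chrom, "dexskip", type, s, e, ".", spec$strand, phase, attrs,
          sep = "\t")
  lines <- c(lines,
             f("gene", gene_s, gene_e, ".", sprintf("ID=%s", spec$gene_id)),
             f("mRNA", gene_s, gene_e, ".",
               sprintf("ID=%s;Parent=%s", spec$tx_id, spec$gene_id)))
  for (i in ord) {
    lines <- c(lines, f("exon", ex$gstart[i] + 1L, ex$gend[i], ".",
                        sprintf("ID=%s.exon%d;Parent=%s", spec$tx_id,
                                ex$index[i], spec$tx_id)))
    if (ex$cds_nt[i] > 0L) {
      # CDS genomic sub-interval of the exon
      utr_head <- max(0L, tx$cds_start - ex$tx_start[i])
      utr_tail <- max(0L, ex$tx_end[i] - (tx$cds_start + tx$cds_len))
      if (spec$strand == "+") {
        cs <- ex$gstart[i] + utr_head; ce <- ex$gend[i] - utr_tail
      } else {
        cs <- ex$gstart[i] + utr_tail; ce <- ex$gend[i] - utr_head
      }
      gff_phase <- (3L - ex$start_phase[i]) %% 3L
      lines <- c(lines, f("CDS", cs + 1L, ce, gff_phase,
                          sprintf("ID=%s.cds;Parent=%s", spec$tx_id, spec$tx_id)))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a toy gene fixture to disk
#'
#' @param gene a `toy_gene`
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths (`gff3`, `fasta`,
#'   `domains`)
#' @export
write_fixture <- function(gene, dir) {
  stopifnot(inherits(gene, "toy_gene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff3 = file.path(dir, "gene.gff3"),
             fasta = file.path(dir, "genome.fa"),
             domains = file.path(dir, "domains.tsv"))
  writeLines(sub("\n$", "", gene$gff3), paths["gff3"])
  writeLines(sub("\n$", "", gene$fasta), paths["fasta"])
  utils::write.table(gene$domains, paths["domains"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Generate a synthetic variant table
#'
#' Emits exactly the requested number of unique nonsense (loss-of-function)
#' variants per exon, with allele frequencies drawn uniformly from
#' `freq_range`; deterministic given `seed`.
#'
#' @param tx a `transcript`
#' @param per_exon_lof_counts named integer vector: names are exon indices,
#'   values the number of unique LoF variants to place there
#' @param freq_range allele-frequency range
#' @param seed integer
#' @return data.frame with `hgvs_c`, `consequence`, `allele_frequency`,
#'   `source` (writeable as the variant TSV dialect)
#' @export
make_variant_table <- function(tx, per_exon_lof_counts,
                               freq_range = c(1e-6, 1e-4), seed = 1L) {
  stopifnot(inherits(tx, "transcript"))
  exon_idx <- as.integer(names(per_exon_lof_counts))
  if (any(is.na(exon_idx)) || any(!exon_idx %in% tx$exons$index))
    stopf("per_exon_lof_counts names must be exon indices")
  cum <- cumsum(c(0L, tx$exons$cds_nt))
  with_seed(seed, {
    rows <- list()
    for (k in seq_along(exon_idx)) {
      i <- exon_idx[k]; cnt <- per_exon_lof_counts[[k]]
      if (tx$exons$cds_nt[i] < cnt)
        stopf("exon %d has only %d CDS nt for %d variants", i,
              tx$exons$cds_nt[i], cnt)
      cpos <- sort(sample(seq.int(cum[i] + 1L, cum[i + 1L]), cnt))
      rows[[k]] <- data.frame(
        hgvs_c = sprintf("c.%dG>T", cpos),
        consequence = "nonsense",
        allele_frequency = stats::runif(cnt, freq_range[1], freq_range[2]),
        source = "synthetic", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Plant a maximal-score ESE motif into a target region
#'
#' Overwrites the sense strand at the given exon offset with the matrix
#' consensus so a subsequent [ese_scan()] reports a hit of maximal score
#' exactly there. The motif must lie fully inside the exon.
#'
#' @param region a `target_region`
#' @param matrix an `ese_matrix`
#' @param offset 1-based start position within the exon
#' @return the modified `target_region`
#' @export
plant_ese <- function(region, matrix, offset) {
  stopifnot(inherits(region, "target_region"), inherits(matrix, "ese_matrix"))
  exon_len <- region$exon_end - region$exon_start
  if (offset < 1L || offset + matrix$width - 1L > exon_len)
    stopf("motif of width %d at exon offset %d falls outside the %d-nt exon",
          matrix$width, offset, exon_len)
  motif <- as_dna(ese_consensus(matrix))
  s <- region$exon_start + offset   # 1-based region position of motif start
  seq <- region$sequence
  substr(seq, s, s + matrix$width - 1L) <- motif
  region$sequence <- seq
  region
}
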