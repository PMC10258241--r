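test_that("a toy 3-exon gene yields the expected translation and phases", {
  tx <- tiny_tx()
  expect_equal(nchar(tx$protein_seq), 99)           # 300/3 - 1
  expect_equal(tx$exons$cds_nt, c(90L, 60L, 150L))
  ph <- exon_phases(tx)
  expect_equal(ph$start_phase, c(0L, 0L, 0L))
  expect_equal(ph$end_phase, c(0L, 0L, 0L))
})

test_that("minus-strand construction is strand symmetric", {
  plus <- tiny_tx("+")
  minus <- tiny_tx("-")
  expect_identical(minus$spliced_seq, plus$spliced_seq)
  expect_identical(minus$protein_seq, plus$protein_seq)
  # genomic coordinates descend along the chromosome in transcript order
  expect_true(all(diff(minus$exons$gstart) < 0))
})

test_that("invalid CDS annotations are fatal and name the transcript", {
  expect_error(
    new_transcript("BAD-301", c("ATGGCTGCT", paste0(strrep("GCA", 97), "TAAG")),
                   cds_start = 0, cds_len = 301),
    "BAD-301.*301.*not divisible by 3")
  expect_error(
    new_transcript("NOSTOP", c("ATGGCTGCTGCA"), cds_start = 0, cds_len = 12),
    "NOSTOP.*stop codon")
  expect_error(
    new_transcript("OVL", c("ATGGCT", "GCATAA"), cds_start = 0, cds_len = 12,
                   gstarts = c(0, 3), gends = c(6, 9)),
    "overlapping exons")
})

test_that("phase chain matches the cumulative-sum oracle on toy genes", {
  for (seed in 1:5) {
    g <- toy_gene_cached(seed)
    ph <- exon_phases(g$tx)
    orc <- oracle_phases(g$tx)
    expect_equal(ph$start_phase, orc$start_phase)
    expect_equal(ph$end_phase, orc$end_phase)
    # chain property: end phase feeds the next coding exon
    coding <- which(g$tx$exons$cds_nt > 0)
    expect_equal(ph$end_phase[coding[-length(coding)]],
                 ph$start_phase[coding[-1]])
  }
})

test_that("an exon's end phase is start phase plus CDS length mod 3", {
  g <- toy_gene_cached(3)
  ph <- exon_phases(g$tx)
  coding <- ph$cds_nt > 0
  expect_equal(ph$end_phase[coding],
               (ph$start_phase[coding] + ph$cds_nt[coding]) %% 3L)
})

test_that("genomic/transcript coordinate maps are mutually inverse", {
  for (seed in c(1, 2)) {
    for (strand in c("+", "-")) {
      g <- toy_gene_cached(seed, strand = strand, n_domains = 4L)
      tx <- g$tx
      pos <- seq(0, nchar(tx$spliced_seq) - 1L)
      expect_equal(genomic_to_tx(tx, tx_to_genomic(tx, pos)), pos)
    }
  }
})

test_that("apply_skip conserves length and handles the identity case", {
  g <- toy_gene_cached(1)
  tx <- g$tx
  ed <- apply_skip(tx, 4:5)
  expect_equal(nchar(tx$spliced_seq) - nchar(ed$spliced_seq),
               sum(tx$exons$length_nt[4:5]))
  expect_identical(apply_skip(tx, integer(0)), tx)
  expect_error(apply_skip(tx, seq_len(nrow(tx$exons))), "every coding exon")
})

test_that("skipping a 306-nt in-frame pair shortens the protein by 102 aa", {
  g <- toy_gene_cached(1)
  tx <- g$tx
  pair <- g$designated_exons
  expect_equal(exon_cds_sum(tx, pair), 306)
  ed <- apply_skip(tx, pair)
  expect_equal(nchar(tx$protein_seq) - nchar(ed$protein_seq), 102)
  cons <- protein_consequence(tx, pair)
  expect_true(cons$frame_preserving)
  expect_true(is.na(cons$junction_residue))    # phase-0 boundary
  expect_equal(cons$removed_aa_end - cons$removed_aa_start + 1L, 102L)
  expect_match(cons$hgvs_p, "^p\\.[A-Z]\\d+_[A-Z]\\d+del$")
})

test_that("a phase-split skip emits a delins with the hybrid junction residue", {
  tx <- delins_tx()
  expect_equal(exon_phases(tx)$start_phase, c(0L, 1L, 1L))
  cons <- protein_consequence(tx, 2L)
  expect_true(cons$frame_preserving)
  expect_identical(cons$junction_residue, "G")
  expect_identical(cons$hgvs_p, "p.A4_R8delinsG")
  # the edited transcript really contains the glycine junction
  ed <- apply_skip(tx, 2L)
  expect_identical(ed$protein_seq, "MAAGAE")
})

test_that("skips whose CDS length is not divisible by 3 are frameshifts", {
  # 151-nt coding exon in the middle
  cds <- paste0("ATG", strrep("GCA", 120), "TAA")
  tx <- new_transcript("FS-1",
                       c(substr(cds, 1, 100), substr(cds, 101, 251),
                         substr(cds, 252, 366)),
                       cds_start = 0, cds_len = 366)
  expect_equal(tx$exons$cds_nt[2], 151L)
  cons <- protein_consequence(tx, 2L)
  expect_false(cons$frame_preserving)
  expect_true(is.na(cons$hgvs_p))
  expect_true(is.na(cons$removed_aa_start))
})

test_that("frame preservation equals the mod-3 rule under brute-force translation", {
  g <- toy_gene_cached(2)
  tx <- g$tx
  internal <- 2:(nrow(tx$exons) - 1L)
  for (i in internal[seq(1, length(internal), by = 3)]) {
    for (j in i:min(i + 2L, max(internal))) {
      cons <- protein_consequence(tx, i:j)
      expect_identical(cons$frame_preserving, oracle_frame(tx, i:j))
      if (cons$frame_preserving) {
        ed <- apply_skip(tx, i:j)
        # stop-free fixture: frame-preserving edit translates cleanly with
        # the expected length
        expect_equal(nchar(ed$protein_seq),
                     nchar(tx$protein_seq) - cons$skipped_cds_nt / 3)
      }
    }
  }
})

test_that("loader round-trips fixtures through GFF3 + FASTA on both strands", {
  for (strand in c("+", "-")) {
    g <- toy_gene_cached(5, strand = strand, n_domains = 3L)
    paths <- write_fixture(g, tempfile())
    gm <- load_gene_model(paths["gff3"], paths["fasta"])
    tx <- gm$transcripts[[1]]
    expect_identical(tx$spliced_seq, g$tx$spliced_seq)
    expect_identical(tx$protein_seq, g$tx$protein_seq)
    expect_equal(tx$exons$cds_nt, g$tx$exons$cds_nt)
  }
})

test_that("the exon TSV dialect loads equivalently to GFF3", {
  g <- toy_gene_cached(4, n_domains = 3L)
  paths <- write_fixture(g, tempfile())
  ex <- g$tx$exons
  # per-exon CDS genomic sub-intervals (fully coding except terminal exons)
  utr_head <- pmax(0L, g$tx$cds_start - ex$tx_start)
  utr_tail <- pmax(0L, ex$tx_end - (g$tx$cds_start + g$tx$cds_len))
  tsv <- data.frame(tx_id = g$tx$tx_id, exon_index = ex$index,
                    chrom = g$tx$chrom, start = ex$gstart + 1L, end = ex$gend,
                    strand = g$tx$strand,
                    cds_start = ex$gstart + utr_head + 1L,
                    cds_end = ex$gend - utr_tail)
  path <- write_tsv(tsv, tempfile(fileext = ".tsv"))
  gm <- load_gene_model(path, paths["fasta"])
  expect_identical(gm$transcripts[[1]]$protein_seq, g$tx$protein_seq)
  expect_equal(gm$transcripts[[1]]$cds_len, g$tx$cds_len)
})

test_that("in-frame exon counting reports both definitions", {
  g <- toy_gene_cached(1)
  cnt <- count_inframe_exons(g$tx)
  # pair splits have phases 1/2, so no internal exon is individually
  # divisible by 3 except none; with linkers every linker exon qualifies
  expect_equal(cnt$n_frame, sum(g$tx$exons$cds_nt[2:27] %% 3 == 0))
  expect_lte(cnt$n_frame_stop_free, cnt$n_frame)
  gl <- toy_gene_cached(2, linker_aa = 3L)
  cl <- count_inframe_exons(gl$tx)
  expect_gte(cl$n_frame, 13L)   # one linker exon per domain, all in frame
  expect_true(all(cl$stop_free_exons %in% cl$frame_exons))
})

test_that("missing FASTA sequences are fatal", {
  g <- toy_gene_cached(4, n_domains = 3L)
  paths <- write_fixture(g, tempfile())
  other <- tempfile(fileext = ".fa")
  writeLines(c(">other_chrom", "ACGT"), other)
  expect_error(load_gene_model(paths["gff3"], other), "missing from the FASTA")
})
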