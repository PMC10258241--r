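region_for <- function(g, which_exon = 1L, flank = 50L) {
  # rebuild the genome from the fixture FASTA text (line-wrapped)
  lines <- strsplit(g$fasta, "\n")[[1]]
  genome <- stats::setNames(paste(lines[-1], collapse = ""), g$tx$chrom)
  build_target_region(g$tx, g$designated_exons[which_exon], flank, genome)
}

revcomp_sense <- function(rna) {
  chartr("U", "T", as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(rna))))
}

test_that("target regions carry the exon plus symmetric flanks", {
  g <- toy_gene_cached(1)
  exi <- g$designated_exons[1]
  r <- region_for(g, 1L, 50L)
  exon_len <- g$tx$exons$length_nt[exi]
  expect_equal(nchar(r$sequence), exon_len + 100L)
  expect_equal(c(r$exon_start, r$exon_end), c(50L, 50L + exon_len))
  # the exon portion is exactly the transcript exon sequence
  expect_identical(substr(r$sequence, 51, 50 + exon_len),
                   g$tx$exons$seq[exi])
})

test_that("short flanks are truncated with a warning", {
  # first exon of a gene with only 20 nt of chromosome upstream
  g <- toy_gene_cached(2, n_domains = 3L, intron_nt = 20L)
  lines <- strsplit(g$fasta, "\n")[[1]]
  genome <- stats::setNames(paste(lines[-1], collapse = ""), g$tx$chrom)
  expect_warning(r <- build_target_region(g$tx, 1L, 50L, genome), "truncated")
  expect_equal(r$flank_up, 20L)
})

test_that("minus-strand regions equal their plus-strand twin", {
  gp <- toy_gene_cached(3, n_domains = 3L, strand = "+")
  gm <- toy_gene_cached(3, n_domains = 3L, strand = "-")
  rp <- region_for(gp); rm_ <- region_for(gm)
  expect_identical(rm_$sequence, rp$sequence)
  expect_equal(rm_$exon_start, rp$exon_start)
})

test_that("window enumeration matches the exhaustive oracle", {
  r <- target_region_from_seq(random_rna(220, seed = 5), 50L, 170L)
  w <- generate_windows(r, 17L, 23L)
  # brute force: every (start, length) pair intersecting the exon
  expected <- 0L
  for (L in 17:23) for (s in 0:(220 - L)) {
    if (s + L > 50 && s < 170) expected <- expected + 1L
  }
  expect_equal(nrow(w), expected)
  expect_true(all(w$end > 50 & w$start < 170))
  # category: crosses an exon edge <=> boundary
  crosses <- (w$start < 50 & w$end > 50) | (w$start < 170 & w$end > 170)
  expect_identical(w$category, ifelse(crosses, "boundary", "exonic_ese"))
  # antisense correctness: every emitted oligo reverse-complements back to
  # a verbatim substring of the region
  for (i in seq_len(nrow(w))) {
    back <- chartr("Uu", "Tt", as.character(
      Biostrings::reverseComplement(Biostrings::RNAString(w$sequence[i]))))
    expect_identical(back, substr(chartr("U", "T", r$sequence),
                                  w$start[i] + 1L, w$end[i]))
  }
})

test_that("GC content matches hand counts, including the published leads", {
  expect_equal(gc_content("CUGGAGUUGGUAUCUGGGA"), 10 / 19)       # ASO_39D
  expect_equal(gc_content("UAGCUUAACGAUGCAGAAGGAUU"), 9 / 23)    # ASO_40A
  expect_equal(gc_content("GGCC"), 1.0)
  expect_error(gc_content("GGNC"), "ambiguous")
  expect_error(gc_content(""), "empty")
})

test_that("duplex Tm is symmetric under reversal of the duplex", {
  for (seed in 1:6) {
    s <- random_rna(18, seed = seed)
    # reading the duplex from the other end: reverse complement strand
    s_rev <- paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]),
                   collapse = "")
    expect_equal(melting_temperature(s), melting_temperature(s_rev),
                 tolerance = 1e-12)
  }
})

test_that("Tm equals the hand-summed nearest-neighbor oracle", {
  duplexes <- c("GGCCAUCGAC", "AUAUAUAUAU", "CUGGAGUUGG",
                vapply(1:7, function(i) random_rna(10, seed = 100 + i),
                       character(1)))
  for (s in duplexes) {
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-9)
  }
  # conditions feed through: dilution lowers Tm, salt raises it
  expect_lt(melting_temperature("GGCCAUCGACGG", oligo_conc = 25e-9),
            melting_temperature("GGCCAUCGACGG", oligo_conc = 250e-9))
  expect_gt(melting_temperature("GGCCAUCGACGG", na_conc = 1),
            melting_temperature("GGCCAUCGACGG", na_conc = 0.1))
  expect_error(melting_temperature("ACGTACGTT"), "RNA")
  expect_error(melting_temperature("ACGU"), "length")
})

test_that("appending GC-rich stacks never lowers the Tm", {
  for (seed in 1:20) {
    s <- random_rna(12, seed = 300 + seed)
    expect_gte(melting_temperature(paste0(s, "GGCC")),
               melting_temperature(s))
  }
})

test_that("hairpin scoring equals exhaustive enumeration up to 12 nt", {
  expect_equal(hairpin_score("AAAAAAAAAA"), 0L)
  expect_equal(hairpin_score("GGGGAAAACCCC"), 4L)
  for (seed in 1:200) {
    n <- with_seed_local(1000 + seed, sample(4:12, 1))
    s <- random_rna(n, seed = 2000 + seed)
    expect_equal(hairpin_score(s), oracle_max_pairs(s),
                 label = sprintf("hairpin(%s)", s))
  }
})

test_that("self-dimer run finds full palindromes and ignores non-complements", {
  expect_equal(self_dimer_run("GGGGCCCC"), 8L)
  expect_equal(self_dimer_run("AAAAAAAAAA"), 0L)
  expect_equal(self_dimer_run("GGGGUUUU"), 0L)   # G:U not counted for dimers
  s <- "ACGUACGAUGGCAU"
  expect_lte(self_dimer_run(s), nchar(s))
})

test_that("hairpin scores respect the structural upper bound", {
  for (seed in 1:20) {
    n <- with_seed_local(3000 + seed, sample(8:23, 1))
    s <- random_rna(n, seed = 4000 + seed)
    expect_lte(hairpin_score(s), (n - 3) %/% 2)
    g <- gc_content(s)
    expect_gte(g, 0); expect_lte(g, 1)
  }
})

test_that("ESE scanning equals brute-force matrix sums", {
  mats <- load_ese_matrices()
  expect_setequal(names(mats), c("SRSF1", "SRSF2", "SRSF5", "SRSF6"))
  # 30-nt exon, no flanks, fully scanned
  seq30 <- chartr("U", "T", random_rna(30, seed = 42))
  r <- target_region_from_seq(seq30, 0L, 30L)
  hits <- ese_scan(r, mats)
  for (m in mats) {
    sc <- oracle_pssm_scores(seq30, m$weights)
    want <- which(sc >= m$threshold)
    got <- hits$pos_exon[hits$factor == m$factor]
    expect_equal(sort(got), sort(want))
    if (length(want)) {
      expect_equal(hits$score[hits$factor == m$factor][order(got)],
                   sc[sort(want)])
    }
  }
})

test_that("planted consensus motifs are recovered exactly and are fragile", {
  mats <- load_ese_matrices()
  m <- mats$SRSF1
  # poly-A exon background scores far below threshold everywhere
  r <- target_region_from_seq(strrep("A", 140), 20L, 120L)
  expect_equal(nrow(ese_scan(r, mats["SRSF1"])), 0L)
  planted <- plant_ese(r, m, offset = 10L)
  hits <- ese_scan(planted, mats["SRSF1"])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos_exon, 10L)
  expect_equal(hits$score, max(oracle_pssm_scores(
    substr(planted$sequence, 21, 120 + 20), m$weights)))
  # mutating one consensus base to the worst base kills the hit
  worst <- c("A", "C", "G", "U")[which.min(m$weights[1L, ])]
  seq <- planted$sequence
  substr(seq, 30L, 30L) <- chartr("U", "T", worst)   # motif start in region
  mut <- target_region_from_seq(seq, 20L, 120L)
  expect_equal(nrow(ese_scan(mut, mats["SRSF1"])), 0L)
  # two plants at disjoint offsets give two hits
  two <- plant_ese(plant_ese(r, m, 10L), m, 60L)
  expect_equal(nrow(ese_scan(two, mats["SRSF1"])), 2L)
  expect_error(plant_ese(r, m, 99L), "outside")
})

test_that("hard Tm filter and soft criteria order candidates as documented", {
  r <- target_region_from_seq(random_rna(160, seed = 9), 40L, 120L)
  w <- generate_windows(r)
  s <- score_asos(w, r, load_ese_matrices())
  ranked <- filter_and_rank(s, aso_criteria())
  expect_true(all(ranked$tm_c >= 48))
  # independent recomputation of the documented score formula
  crit <- aso_criteria()
  gc_ex <- pmax(0, crit$gc_range[1] - ranked$gc_fraction,
                ranked$gc_fraction - crit$gc_range[2])
  want <- crit$w_boundary * (ranked$category == "boundary") +
    crit$w_ese * ranked$ese_hits - crit$w_gc * gc_ex -
    crit$w_struct * (pmax(0, ranked$hairpin_pairs - crit$hairpin_cap) +
                       pmax(0, ranked$self_dimer_run - crit$dimer_cap))
  expect_equal(ranked$rank_score, want)
  expect_true(all(diff(ranked$rank_score) <= 0))
  # Tm below the floor is excluded outright
  fake <- s[1:2, ]; fake$tm_c <- c(47.9, 60)
  kept <- filter_and_rank(fake, aso_criteria())
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$tm_c, 60)
})

test_that("more ESE hits win between otherwise identical exonic candidates", {
  base <- data.frame(id = c("a", "b"), target_exon = 1L, start = c(10L, 10L),
                     end = c(29L, 29L), length_nt = 19L,
                     sense_seq = "x", sequence = "x",
                     category = "exonic_ese", gc_fraction = 0.5,
                     tm_c = 60, ese_hits = c(3L, 0L), hairpin_pairs = 0L,
                     self_dimer_run = 0L, stringsAsFactors = FALSE)
  ranked <- filter_and_rank(base, aso_criteria())
  expect_equal(ranked$id, c("a", "b"))
})

test_that("the GC band is a soft criterion: ASO_40A is flagged, not rejected", {
  lead <- lead_aso_table()
  aso40a <- lead$sequence[lead$aso_id == "ASO_40A"]
  expect_equal(gc_content(aso40a), 9 / 23)           # 39.1%, below the floor
  cand <- data.frame(
    id = "ASO_40A", target_exon = 40L, start = 0L, end = nchar(aso40a),
    length_nt = nchar(aso40a), sense_seq = revcomp_sense(aso40a),
    sequence = aso40a, category = "boundary",
    gc_fraction = gc_content(aso40a),
    tm_c = melting_temperature(aso40a),
    ese_hits = 0L, hairpin_pairs = hairpin_score(aso40a),
    self_dimer_run = self_dimer_run(aso40a), stringsAsFactors = FALSE)
  ranked <- filter_and_rank(cand, aso_criteria())
  expect_equal(nrow(ranked), 1L)                      # retained
  expect_false(ranked$gc_in_band)                     # but flagged
  expect_lt(ranked$rank_score, 2)                     # and penalized
})

test_that("mismatch controls have exactly four interior mismatches, reproducibly", {
  for (seed in 1:10) {
    s <- random_rna(with_seed_local(seed, sample(17:23, 1)), seed = 500 + seed)
    mc <- design_mismatch_control(s, seed = seed)
    v <- validate_mismatch_pair(s, mc$sequence)
    expect_true(v$valid)
    expect_equal(v$n_mismatch, 4L)
    expect_true(all(v$positions >= 4 & v$positions <= nchar(s) - 2))
    # purine<->purine / pyrimidine<->pyrimidine swaps only
    a <- strsplit(s, "")[[1]][v$positions]
    b <- strsplit(mc$sequence, "")[[1]][v$positions]
    expect_true(all((a %in% c("A", "G")) == (b %in% c("A", "G"))))
    # same seed, same control
    expect_identical(mc$sequence,
                     design_mismatch_control(s, seed = seed)$sequence)
  }
  expect_error(design_mismatch_control("ACGUACGUACG", seed = 1), "length >= 12")
})

test_that("all five published lead ASO/control pairs pass the validator", {
  lead <- lead_aso_table()
  expect_equal(nrow(lead), 5L)
  for (i in seq_len(nrow(lead))) {
    v <- validate_mismatch_pair(lead$sequence[i], lead$mismatch_control[i])
    expect_true(v$valid, label = lead$aso_id[i])
    expect_equal(v$n_mismatch, 4L)
  }
  # the 39D pair differs exactly at positions 4, 6, 10 and 17
  v39 <- validate_mismatch_pair(lead$sequence[lead$aso_id == "ASO_39D"],
                                lead$mismatch_control[lead$aso_id == "ASO_39D"])
  expect_equal(v39$positions, c(4L, 6L, 10L, 17L))
  # adjacent mismatches occur in the published set and are accepted
  v30 <- validate_mismatch_pair(lead$sequence[lead$aso_id == "ASO_30"],
                                lead$mismatch_control[lead$aso_id == "ASO_30"])
  expect_true(all(c(10L, 11L) %in% v30$positions))
})
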