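# Shared fixtures, built in code. Everything is deterministic per seed.

.toy_cache <- new.env(parent = emptyenv())

toy_gene_cached <- function(seed = 1L, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!exists(key, .toy_cache)) {
    assign(key, make_toy_gene(fixture_spec(seed = seed, ...)), .toy_cache)
  }
  get(key, .toy_cache)
}

# hand-built 3-exon gene: CDS 90 + 60 + 150 = 300 nt (stop included),
# fully coding exons, phase chain 0/0 -> 0/0 -> 0/0
tiny_tx <- function(strand = "+") {
  body <- paste(rep(c("GCT", "GAA", "TTC", "GGA"), length.out = 98), collapse = "")
  cds <- paste0("ATG", body, "TAA")
  stopifnot(nchar(cds) == 300)
  new_transcript("TINY-1",
                 exon_seqs = c(substr(cds, 1, 90), substr(cds, 91, 150),
                               substr(cds, 151, 300)),
                 cds_start = 0, cds_len = 300, strand = strand)
}

# 3-exon gene engineered so skipping exon 2 (start phase 1, 12 CDS nt)
# forms a hybrid GGA junction codon: p.A4_R8delinsG
delins_tx <- function() {
  new_transcript("DELINS-1",
                 exon_seqs = c("ATGGCTGCTG", "CTAGAGAATTCA", "GAGCTGAATAA"),
                 cds_start = 0, cds_len = 33)
}

# random small gene spec for property tests
random_fixture_spec <- function(seed) {
  with_seed_local(seed, fixture_spec(
    n_domains = sample(3:6, 1),
    domain_aa = sample(c(30L, 40L, 51L, 60L), 1),
    exons_per_domain = sample(1:2, 1),
    linker_aa = sample(0:4, 1),
    leader_aa = sample(4:12, 1),
    trailer_aa = sample(3:9, 1),
    pair_phases = sample(0:2, 2, replace = TRUE),
    strand = sample(c("+", "-"), 1),
    intron_nt = 60L,
    seed = seed))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_rna <- function(n, seed = NULL) {
  draw <- function() paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                            collapse = "")
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
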