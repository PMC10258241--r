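---
title: "Domain-oriented exon skipping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-oriented exon skipping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexskip)
```

`dexskip` plans therapeutic exon skipping around whole protein domains.
This vignette explains the models behind each step, the parameters that
matter, the numerical conventions, and what the synthetic test bed does
and does not demonstrate about real genes.

## Reading-frame arithmetic and skip consequences

A transcript is represented with 0-based half-open coordinates in three
linked spaces (genomic, spliced transcript, CDS); everything user-facing
(HGVS c./p. output, exon numbers) is 1-based inclusive, following
community convention. Exon *k* carries a start and end phase — the codon
offset at its CDS boundaries — with the chain invariant
`end_phase(k) = (start_phase(k) + cds_nt(k)) mod 3` and
`start_phase(k+1) = end_phase(k)` for consecutive coding exons.

A contiguous skip of exons *i..j* removes `L = Σ cds_nt` coding bases and
preserves the reading frame iff `L ≡ 0 (mod 3)`. The frame rule is
evaluated on **CDS-overlap nucleotides**, not full exon lengths, so exons
carrying UTR are handled correctly; for fully coding exons the two
coincide. The first and last coding exons are never candidates — their
loss removes the start or stop codon.

When a frame-preserving skip starts mid-codon (start phase `p ≠ 0`), the
retained 5' leftover of `p` bases joins the first `3 − p` retained 3'
bases into a **hybrid junction codon**. We translate it: if it recreates
a reference residue the consequence is a plain deletion
(`p.X###_Y###del`); otherwise a `delins` with the novel junction residue
(`p.X###_Y###delins<Z>`), exactly the form observed in engineered
in-frame deletions. The removed amino-acid interval is computed on whole
codons: a codon split by the skip boundary counts as removed only when at
least two of its three nucleotides are gone — consistent with the
junction codon persisting as one (possibly novel) residue, and the basis
for domain classification below. Frame-disrupting skips report
`frame_preserving = FALSE` and no deletion interval; the edited protein
is obtained by translating from the original start codon to the first
stop.

Skips spanning several events (an intended pair plus an adjacent co-skip)
are merged; a non-contiguous union still gets a correct frame call but
per-block consequences instead of a single deletion interval.

## Domain impact classification and ranking

Domains are 1-based amino-acid intervals that may not overlap; residues
between domains (linkers) are deliberately **unassigned** and never veto
a clean call — the structural concern is cutting into a folded domain,
not trimming a linker. A candidate is

* `clean_single_domain` — exactly one domain lies entirely inside the
  removed interval, none is cut;
* `clean_multi_domain` — two or more lie entirely inside, none cut;
* `no_domain_removed` / `partial_domain_disruption` / `frameshift`
  otherwise.

Ranking is a strict total order: impact class first (clean single-domain
targets are the point of the strategy; frameshifts always sink to the
bottom), then estimated reach descending, then loss-of-function burden
descending, then fewer exons, and finally the exon range itself so equal
candidates order deterministically. `max_exons` defaults to 2 — the
dual-skip scope in which the strategy was validated — and is
configurable.

## Variant burden and population reach

Loss-of-function burden counts **unique** records (by c. description)
with nonsense, frameshift or canonical-splice consequences; missense is
excluded by default because the therapeutic rationale applies to
truncating alleles, and the class set is widenable. Records with intronic
offsets (`c.100-5A>G`) are flagged and never counted in exonic burden.

Published reach figures rarely print their formula, so ours is explicit
and embedded in every report. Under Hardy–Weinberg random mating with
summed pathogenic allele frequencies `a_t` (target exons) and `a_g`
(gene-wide), an affected individual is eligible when at least one of the
two pathogenic alleles lies in the target exons — the skipped transcript
restores that allele, matching the precedent of single-exon skipping
therapies:

$$E = N \cdot a_t \cdot (2 a_g - a_t)$$

The limits `a_t = 0 → 0` and `a_t = a_g = q → N q²` hold by algebra, and
`E` is monotone in both frequencies. Because whether published counts
mean "≥ 1 target allele" or "both alleles in the target exons" is usually
unstated, the stricter `N·a_t²` is always reported alongside. The
population constant defaults to 8 × 10⁹ ("worldwide") and is
configurable; a helper converts carrier frequencies to allele frequencies
under the rare-allele approximation (`q ≈ f/2`).

## ASO design model

For a target exon we tile every antisense window of 17–23 nt over the
exon plus 50 nt of intronic flank on each side (both defaults are the
published design range for this oligo chemistry; the flank is genomic
sequence, truncated only at a sequence end, with a warning). Windows
crossing an intron–exon boundary are category `boundary` (splice-site
masking); fully exonic windows are `exonic_ese` (enhancer masking).

Scores per candidate:

* **GC fraction** — plain `(G+C)/length`.
* **Duplex Tm** — two-state nearest-neighbor model for the oligo:target
  RNA duplex with the Watson–Crick RNA:RNA parameter set (initiation and
  terminal A–U penalties included), at 250 nM strand concentration (the
  screening dose) and 100 mM monovalent salt via the classic
  `16.6·log10[Na⁺]` adjustment. The chemistry actually used in the clinic
  (2′-MOE ribose, phosphorothioate backbone) shifts absolute Tm, which no
  published parameter set covers; we therefore treat the model as a
  consistent comparator, keep the threshold configurable, and print the
  conditions in reports. Whether the published "Tm ≥ 48 °C" refers to the
  duplex or self-melting is unstated; we treat it as duplex Tm.
* **ESE footprint** — position-specific score matrices in the ESEfinder
  style, scanned on the sense strand with motifs fully inside the exon;
  a candidate's `ese_hits` counts hit footprints overlapping its window.
  The packaged matrices are *synthetic* (widths 7/8/7/6 and thresholds
  1.956/2.383/2.67/2.676 matching the published SRSF1/SRSF2/SRSF5/SRSF6
  matrices, weights invented) because the original weight tables are not
  redistributable offline; they are plain TSVs, so real matrices drop in
  via `load_ese_matrices(dir)`.
* **Structure** — a Nussinov-style maximum-pairing recursion (minimum
  loop 3, G:U allowed) for hairpin propensity, and the longest ungapped
  antiparallel Watson–Crick run of the sequence against itself for dimer
  propensity. These are counting models, not energy models: exact,
  deterministic, dependency-free, and adequate for *ranking*; an external
  folding engine can replace them where absolute free energies matter.

Filtering: length and Tm are **hard**; GC 40–60 % is deliberately
**soft** — a validated 23-mer lead computes to 9/23 ≈ 39.1 % GC, so a
hard floor would reject a proven oligo. Out-of-band GC and
structure-score excess over configurable caps enter as penalties in the
documented linear `rank_score`; ties break by window position then
length, so output order is reproducible.

Mismatch controls place exactly four substitutions at interior positions
(never the first three or last two bases), sampled reproducibly from the
run seed; each substitution swaps within its chemical class (A↔G, C↔U),
which maximally disrupts pairing while minimizing the GC change. No
spacing constraint is imposed beyond interior placement — published
control oligos include adjacent mismatches. A validator checks any
ASO/control pair against the same convention.

## Splice-assay prediction

Minigene constructs put the insert exons between two heterologous
flanking exons, with primers in the flanks; endogenous RT-PCR uses
primers in exons strictly outside the skipped range. Product sizes are
exact transcript distances; a skipped isoform's product is the full
product minus the summed skipped exon lengths. Primer positions default
to exon centers (the real flanking-exon primer coordinates are not
published) and are configurable; the insert flank sizes likewise vary per
construct and are parameters, not constants. The band table sorts by size
descending and merges co-migrating isoforms, since a gel cannot separate
them.

## The synthetic test bed

`make_toy_gene()` emulates the features the algorithms depend on: a chain
of identical-size FN3-like repeats, each encoded by one or two exons with
controllable junction phases; optional linker residues (as dedicated
in-frame exons) between repeats; UTRs on terminal exons; `GT..AG`
introns; a designated two-exon pair whose 306-nt default mirrors the
exemplar dual-skip target (294 nt via `domain_aa = 98`). Codons are drawn
from a stop-free alphabet, so every generated CDS is valid for any seed,
and generation is byte-identical per seed.

It does **not** mimic real splice-site strength, intron length
distributions, sequence composition, or alternative splicing — so passing
tests demonstrate the correctness of the arithmetic, classification,
scanning and scoring, not the biological efficacy of any designed oligo.
Test problem sizes (50 random genes for the classifier oracles, 200
short sequences for exhaustive structure enumeration, exhaustive window
enumeration per region) were chosen so the whole suite exercises every
code path in about a minute on one core.

## Degenerate inputs and edge rules

* Loading fails fast with the offending transcript named: CDS not
  divisible by 3, missing stop, internal stop, overlapping exons, missing
  FASTA sequence. Annotations whose CDS excludes the stop codon are
  accepted when the next in-frame codon is a stop (then folded in).
* Skipping every coding exon is an error; an empty skip set is the
  identity.
* A skip running into the stop-codon region falls back to a plain
  C-terminal deletion call.
* Variant rows that fail to parse are skipped with a counted warning —
  one bad row never kills an intake of thousands.
* Intronic breakpoints in input c. descriptions are accepted; only the
  exonic consequence is modeled.
* "How many exons are individually skippable in frame" is reported under
  two definitions (`count_inframe_exons()`): CDS length divisible by
  three, and additionally stop-free at the new junction — published
  counts rarely say which is meant, so we refuse to guess.

## Known limitations

No off-target transcriptome screening, no chemistry-aware
thermodynamics, no de-novo domain prediction, no 3D structural
assessment of the shortened protein, no modeling of skip efficiency or
dose response — these need external tools or experiments. Reach
estimates inherit every bias of the input allele frequencies and assume
random mating with full penetrance of biallelic genotypes.
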