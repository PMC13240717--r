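---
title: "Mining secreted amylases and amylase-inhibitor gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining secreted amylases and amylase-inhibitor gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylatlas)
```

## The biological question

Streptomycetes degrade starch with secreted amylases, and some of them
simultaneously produce amylase *inhibitors* — pseudooligosaccharides such as
acarbose, acarviostatin and trestatin (whose biosynthetic gene clusters, BGCs,
share a core set of C7N-aminocyclitol genes) and small proteinaceous
inhibitors of the tendamistat family. A producer that poisons the
extracellular amylase pool needs its own starch-degrading machinery to keep
working, which predicts three genome-scale signatures:

1. genomes carrying inhibitor BGCs should encode *more* amylases than genomes
   without them, with amylase genes clustered in the BGC neighborhood;
2. particular inhibitor classes should co-occur with particular amylase
   clades; and
3. amylases associated with inhibitor BGCs should carry inhibitor-resistance
   substitutions — canonically a catalytic-pocket histidine replaced by
   asparagine (or alanine) in pullulanase-domain amylases, visible as
   group-specific enrichment at individual alignment columns.

`amylatlas` implements the full desk-side analysis: reducing raw annotation
calls to a clade-typed secreted amylase set, detecting inhibitor BGCs in
ordered gene tables, and testing the cohort-level and residue-level
associations — together with a seeded synthetic-cohort generator that plants
all three signatures with known parameters, so every stage has a
parameter-recovery test that runs in seconds without downloading a genome.

## Pipeline stages and their rules

**Secretome filter** (`filter_secreted_amylases()`). Amylases sit in the
CAZyme family GH13, which also contains cytoplasmic enzymes (trehalose and
glycogen metabolism), so family membership alone is not enough. The filter
applies three rules in order:

1. *GH13 recommended*: GH13 must be among the annotation's recommended
   families, after collapsing subfamilies (`GH13_32` counts as `GH13`) and
   accepting multi-family recommendations (`GH13;CBM20` counts).
2. *Secreted*: the protein must carry a secretion-signal call. This check
   runs before the domain check; the two drop lists
   (`dropped_no_signal`, `dropped_no_domain`) therefore partition failures by
   the first criterion violated. Running the checks in the opposite order
   would move doubly-failing proteins between the audit lists without
   changing the kept set; the order here mirrors the narrative order of the
   secretome-reduction protocol this filter implements.
3. *Amylase domain*: at least one amylase-type or pullulanase-type conserved
   domain must be present.

Clade typing uses the conserved-domain vocabulary
(`default_domain_vocabulary()`), with precedence pullulanase > CMD-like >
alpha-1,4: clade-1 architectures carry an amylase catalytic domain *next to*
their pullulanase domains, so the pullulanase domain is the discriminating
signal. The vocabulary is an editable data frame, not a hard-coded rule.

**Clade tools.** Trees arrive with branch lengths and opaque support labels
(stored verbatim, never parsed as numbers). `midpoint_root()` places the root
at the midpoint of the longest leaf-to-leaf path. `extract_clades()` cuts the
rooted tree into `k` groups (default 3) by greedily removing, at each step,
the edge that minimizes the maximum within-clade root-to-leaf span, measuring
each fragment from the deepest common ancestor of its leaves; ties break by
edge order in the tree's edge matrix. This cut rule is an explicit design
choice — practitioners usually delimit major clades by eye — and is *not*
claimed to reproduce any particular published clade membership; what it
guarantees is determinism, connected subtrees, and recovery of planted clades
whose separating branches dominate the within-clade spans.
`select_representative()` implements consensus-nearest selection: per-column
majority consensus (gaps ignored by default; ties to the lexicographically
smallest residue), then the member with the highest fraction of identical
columns over the positions where neither member nor consensus is gapped, ties
to the first member in input order.

**BGC neighborhoods.** `find_bgc_loci()` is a deliberately simplified
required/optional-gene cluster search: maximal runs of role-matching genes
separated by at most `max_gene_gap = 5` non-matching genes, kept when they
cover `required_fraction = 1` of the required set (for acarbose-like
clusters, the 15 gac aminocyclitol core genes). Windows are counted in
*genes*, not base pairs, and strand is ignored — the synthetic gene model is
ordinal, and none of the downstream statistics use strand or physical
distance. `count_flanking_amylases()` counts amylase genes within the locus
span or `flank_genes = 10` positions of either end, clipped at contig edges;
loci within `max_gene_gap` of a contig end are flagged as potentially
truncated. Tendamistat presence is a per-genome flag from HMM hits at
E-value <= 1e-10 (the cutoff is inclusive).

**Statistics** (`stats_core` functions). All cohort statistics are exact or
classical:

* `fisher_exact()` — hypergeometric enumeration over the table's support;
  the two-sided p-value uses probability ordering with a 1e-12 relative
  tolerance guarding floating-point ties. The reported odds ratio is the
  sample odds ratio `ad/bc` (`Inf` with an empty discordant cell), not the
  conditional MLE.
* `mann_whitney_u()` — midrank U; exact p when the data are tie-free and
  `choose(n1+n2, n1) <= 200,000`, otherwise a normal approximation with
  tie-corrected variance and continuity correction. The default effect size
  is the rank-biserial correlation `r = 2U/(n1*n2) - 1`, signed so that a
  positive value means the first sample (the flagged genomes in
  `count_association()`) is larger; `z/sqrt(N)` is available as an
  alternative definition since published effect sizes do not always state
  which convention they use. Counts are compared with this test
  unconditionally — no normality pre-test — because per-genome amylase
  counts are small discrete values for which a rank test is the defensible
  default.
* `chi_square_2x2()` — Pearson chi-square without continuity correction by
  default (switchable), with `phi = sign(ad-bc) * sqrt(chi2/n)`.
* `benjamini_hochberg()` / `bonferroni()` — step-up FDR and family-wise
  corrections.

**Enrichment scan** (`column_enrichment_scan()`). For every (column, residue)
pair with at least `min_count = 3` total observations, a two-sided Fisher
test compares residue carriage between BGC-associated (group A) and other
(group B) sequences; BH and Bonferroni corrections are computed over *all*
tested pairs of the scan as one family. Sequences gapped at a column are
excluded from both margins by default (`gap_policy = "exclude"`); counting
them as "without residue" is available but conflates alignment holes with
substitutions. Fold enrichment is `(a/nA)/(c/nB)`; only when the group-B
count is zero a Haldane–Anscombe 0.5 pseudocount enters all four cells, so
finite folds are reported for perfectly group-A-specific residues without
perturbing ordinary tables. `min_count = 3` exists to skip degenerate one- or
two-observation tables that can never reach significance but inflate the
correction family. Results carry reference coordinates (gap-aware ungapped
position in a chosen reference sequence) and substitution labels such as
`H235G`. `substitution_census()` answers the narrower question for one known
site, at sequence level or de-duplicated genome level — the two differ
exactly when a genome carries two or more variant sequences, which is why
both are exposed.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws, per genome: inhibitor-BGC carriage
(`p_bgc = 0.05`, about 15 of 295 genomes), a secreted-amylase count from a
base distribution on {0,1,2,3} (probabilities 0.10/0.35/0.35/0.20) shifted by
`+3` in BGC carriers, a clade split (pullulanase 0.45 / alpha-1,4 0.45 /
CMD-like 0.10), tendamistat presence (marginal 0.13) with a planted
phi = 0.16 association to CMD-like amylase presence, and a genome size of
8.5 ± 0.4 Mb. The defaults are the study conditions: a 295-genome
genus-wide cohort whose per-genome amylase counts range 0–6, in which about
one genome in twenty carries an inhibitor BGC, inhibitor carriers sit at the
top of the count range, and tendamistat co-occurs weakly with the CMD-like
clade. The base distribution is confined to {0..3} so that the +3 shift
lands inside the observed 0–6 range without clamping distortion — clamping
exists (counts are capped at 6) but under the defaults it never engages, and
with clamping disabled an out-of-range shift is an error rather than a
silent truncation. The per-genome gene layout places the 15-gene gac run
away from contig edges, a planted 1–4 amylases immediately adjacent to it,
and all remaining amylases far enough away that the default 10-gene flank
cannot reach them; the planted flank counts are therefore exactly
recoverable, which is what the neighborhood tests assert.

`generate_msa()` plants group-specific column substitutions: at a planted
column, group A carries `residue_a` with frequency `freq_a` (default 0.6),
group B carries `residue_b` with `freq_b` (default 0.04), and the fallback
background at that column excludes both planted residues — so
`freq_a = 1, freq_b = 0` yields perfect group separation and the planted
frequencies hold exactly (planted columns also receive no gaps). This
models the situation where the resistance variant is essentially absent
outside the BGC-associated group; a variant that also circulates at
appreciable frequency in the background group is a much harder detection
problem that the bundled simulations deliberately do not claim to cover.

What the generator does *not* emulate: phylogenetic correlation between
sequences (sites are i.i.d. given the group), indels (template-derived
sequences differ only by substitutions, so "alignment" is exact), linkage
between amylase clade and BGC adjacency, base-pair distances, and any
realistic population structure across genomes. Passing the recovery tests
therefore shows the *rules and statistics* are implemented correctly under
their stated model — it does not show that real cohorts satisfy that model.
Real-data headline numbers (prevalences, specific effect sizes, specific
fold enrichments) depend on the external annotation tools and genome set and
are out of scope here.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (residues, MSA columns);
  gene indices are 0-based and must be consecutive within a contig.
* Fisher tables with a zero margin return p = 1 (degenerate, not an error);
  chi-square likewise returns chi2 = 0, phi = 0, p = 1.
* A Mann–Whitney comparison in which every observation is identical returns
  p = 1 and r = 0 rather than dividing by a zero variance.
* Consensus ties are lexicographic; representative ties follow input order;
  clade-cut ties follow edge-matrix order — every tie-break is deterministic
  and documented next to the code that applies it.
* Newick round-trips write 15 significant digits so branch lengths and path
  sums survive re-reading to well below 1e-9.
* All generators take a single integer seed, restore the session RNG state
  afterwards, and produce byte-identical output for equal seeds.
  `make_fixtures()` additionally walks deterministic sub-seeds
  (seed, seed+1000, ...) until the sampled cohort has at least two BGC
  carriers, two non-carriers and two tendamistat-positive genomes, so the
  fixture exercises every stage for any seed.

## Problem sizes used by the test suite

The bundled tests run the cohort statistics at the study scale (295 genomes;
200 replicate cohorts each for null calibration and for power of the planted
+3 shift), the enrichment scan on 50 seeded alignments of 300 sequences by
400 columns with 5 planted columns, Fisher's exact test against exhaustive
enumeration on every 2x2 table with all margins at most 12, Mann–Whitney
against full rank-arrangement enumeration for all sample sizes up to 7 per
group, midpoint rooting on 500 random trees, and representative selection
against a brute-force oracle on 100 random alignments. End-to-end pipeline
runs use a 40–60 genome fixture, which exercises every stage while keeping a
full suite run within a few minutes on one CPU.

## Known limitations

* The clade-cut rule and the consensus-similarity metric are fixed,
  documented choices among several defensible ones; neither is claimed to
  reproduce published clade boundaries or representative accessions.
* The BGC search is a gene-window approximation of homology-aware cluster
  detection: role labels are taken as given, so it cannot discover clusters
  whose genes were not labelled upstream, and it does not discriminate
  acarbose from acarviostatin or trestatin chemistry.
* The enrichment scan treats sequences as exchangeable within groups;
  phylogenetic pseudo-replication (many near-identical sequences from
  related genomes) will inflate significance on real data and should be
  addressed by genome-level de-duplication (`substitution_census()` at
  genome level) or by subsampling before scanning.
* `fisher_exact()` reports the sample odds ratio, which is infinite for
  tables with an empty discordant cell; the fold-enrichment pseudocount
  applies only to the scan's fold column, never to p-values.
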