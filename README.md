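# amylatlas

Comparative mining of secreted amylases and amylase-inhibitor biosynthetic
gene clusters (BGCs) across bacterial genome cohorts, modelled on the
*Streptomyces* genus.

Streptomycetes that secrete amylase inhibitors — pseudooligosaccharides such
as acarbose (built on a shared core of C7N-aminocyclitol *gac* genes) and
tendamistat-family peptides — are expected to (i) encode more amylases than
non-producers, clustered around the inhibitor BGC, (ii) show co-occurrence
between inhibitor classes and particular amylase clades, and (iii) carry
inhibitor-resistance substitutions in BGC-associated amylases, canonically a
catalytic histidine→asparagine change in pullulanase-domain enzymes. This
package turns that analysis into a tested, reusable pipeline for anyone
working from standard annotation outputs (CAZyme calls, secretion-signal
calls, conserved-domain hits, ordered gene tables, alignments, trees).

## What it computes

* **Secretome filter** — GH13-recommended ∧ secreted ∧ amylase/pullulanase
  domain, with subfamily collapse (`GH13_32` → `GH13`), multi-family
  recommendations (`GH13;CBM20`) accepted, and domain-based clade typing
  (pullulanase / alpha-1,4 / CMD-like).
* **Clade tools** — midpoint rooting, deterministic k-clade tree cuts,
  per-clade consensus sequences and consensus-nearest representatives.
* **BGC neighborhoods** — required/optional-gene cluster search over gene
  tables (acarbose-like query: 15 *gac* core genes), flanking-amylase
  counts, tendamistat flags at an E-value cutoff of 1e-10.
* **Association statistics** — Mann–Whitney U with rank-biserial effect size
  *r* = 2U/(n₁n₂) − 1 for count–flag associations; chi-square with
  φ = sign(ad−bc)·√(χ²/n) for flag–flag associations; exact
  (probability-ordering) two-sided Fisher tests; Benjamini–Hochberg and
  Bonferroni corrections.
* **Residue-enrichment scan** — per (column, residue) Fisher tests across a
  grouped alignment with joint multiple-testing correction,
  reference-coordinate mapping and substitution labels (`H235G`), plus a
  sequence- or genome-level census of a single substitution site.
* **Synthetic cohorts** — a seeded generator that plants every signature
  above (count shift in BGC carriers, clade/tendamistat φ, adjacent-amylase
  counts, group-specific alignment columns) with known parameters, so each
  stage has a parameter-recovery test that needs no downloads.

## Worked example

```r
library(amylatlas)

ind <- file.path(tempdir(), "fixture")   # synthetic 60-genome cohort
make_fixtures(ind, seed = 42, n_genomes = 60)

out <- file.path(tempdir(), "report")
res <- run_pipeline(analysis_config(ind, out, seed = 1))
cat(res$log, sep = "\n")
#> mine: 299 proteins annotated
#> mine: 239 GH13-recommended
#> mine: 60 dropped (no secretion signal)
#> mine: 60 dropped (no amylase/pullulanase domain)
#> mine: 119 secreted amylases kept
#> clades: 119 leaves cut into 3 clades (sizes 33/48/38)
#> bgc: 6 loci detected across 6 genomes
#> bgc: 9 genomes with tendamistat-like hits at E <= 1e-10
#> associate: 5 tests run, 0 structured failure(s)
#> scan: 191 (column, residue) pairs tested, 2 significant at BH < 0.05
```

The association table shows the planted signal being recovered: genomes
carrying the acarbose-like BGC have far more amylases than the rest
(rank-biserial r = 0.97, p = 6.3e-05 on this fixture), while genome size —
planted with no association — stays non-significant (p = 0.12):

```r
subset(res$association_stats, select = -c(effect_type, status))
#>                             test         type statistic  p_value effect n_true n_false
#> 1 amylase_count~has_acarbose_bgc mann_whitney    318.50 6.31e-05 0.9660      6      54
#> 2   genome_size~has_acarbose_bgc mann_whitney    225.00 1.24e-01 0.3889      6      54
#> 3  amylase_count~has_tendamistat mann_whitney    237.00 8.80e-01 0.0327      9      51
#> 4    genome_size~has_tendamistat mann_whitney    263.00 4.94e-01 0.1460      9      51
#> 5   cmd_presence~has_tendamistat   chi_square      2.12 1.46e-01 0.1879     10      50
```

The report directory additionally contains `amylases.tsv` (the filtered
secretome), `clades.tsv` / `representatives.tsv`, `bgc_loci.tsv` with
flanking-amylase counts, `genome_summaries.tsv`, `enrichment.tsv` (the
column scan, with BH/Bonferroni-corrected p-values and substitution
labels) and a `manifest.json` recording the configuration and seed; reruns
with the same inputs and configuration are byte-identical.

A thin command-line front end over the same functions is installed with the
package (`inst/scripts/amylatlas`):

```sh
amylatlas fixtures --out fixture/ --seed 42
amylatlas run --in fixture/ --out report/ --seed 1
```

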