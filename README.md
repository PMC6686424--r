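# varbatch

Detection and quantification of sequencing-center batch effects in
multi-cohort germline variant call sets.

## The problem

When a cohort pools samples sequenced at different centers, and sample
groups (e.g. cancer types) are confounded with centers, technical
differences between centers masquerade as biology. In germline whole-exome
variant calls this shows up at several levels at once:

* **per-sample variant totals** — one center's pipelines call up to tens of
  percent more variants per sample than another's;
* **substitution spectrum** — per-sample transition–transversion (TiTv)
  ratios differ systematically by center;
* **where variants fall among genes** — per-gene variant densities carry a
  center signature visible in the sample–sample correlation structure;
* **where variants fall within genes** — the positional distribution of
  called variants along a transcript differs by center for many genes,
  including prominent cancer predisposition genes.

`varbatch` is an audit pipeline for this situation. It ingests per-caller
VCFs, metadata and gene models, quantifies each of the four levels above,
ranks genes by their sensitivity to the batch effect, and contrasts the
survival of carriers of mutations in batch-sensitive versus batch-resistant
gene sets. Because the cohorts where this matters are access-controlled, the
package ships a fully synthetic multi-center cohort generator with
injectable batch structure, so every stage is testable end to end without
any external data.

## The core statistic

For a gene *g*, collect the gene-exomic coordinates (0-based positions in
the concatenated exons) of all called variants across all samples of each
group *t* into a multiset *L*<sub>*g,t*</sub>; duplicates are kept, so a
variant seen in two individuals contributes its position twice. For every
unordered pair of groups (*t*, *s*), a two-sided two-sample
Kolmogorov–Smirnov test on the empirical CDFs of the multisets gives
*p*<sub>*g*,(*t,s*)</sub>; six groups give 15 pairs per gene.

Group pairs sequenced at the **same** center should differ only
biologically; pairs from **different** centers add the batch effect. The
per-gene batch-sensitivity ratio is

> *r*<sub>*g*</sub> = *p*<sub>*g*,min</sub> / *p*<sub>*g*,max</sub>

where *p*<sub>*g*,min</sub> is the *minimum* KS p-value over the designated
within-center pairs and *p*<sub>*g*,max</sub> the *maximum* over the
designated between-center pairs. A gene is declared possibly batch-affected
when *r*<sub>*g*</sub> > 1 — a deliberately conservative rule: it requires
*every* between-center p-value to fall below *every* within-center p-value.
`r_g` is a ranking score, not a calibrated test; no multiple-testing
correction applies.

## Worked example

Simulate a three-center cohort (six groups of 40 samples, two callers with
5% error rates, 30% count inflation and TiTv 2.73 vs 2.57 by center, 20 of
100 genes with a strong positional shift), then audit it:

```r
library(varbatch)

cfg <- cohort_config(
  n_genes = 100L, affected_frac = 0.2, shift = 0.8,
  count_mean = c(BI = 300, WUGSC = 390, BCM = 390),
  titv = c(BI = 2.73, WUGSC = 2.57, BCM = 2.57),
  n_callers = 2L, fp_rate = 0.05, fn_rate = 0.05, seed = 7L)
cfg$groups$n_samples <- 40L
cohort <- generate_cohort(cfg)
dir <- tempfile("cohort"); write_cohort(cohort, dir)

models <- read_gene_models(file.path(dir, "genes.bed"))
meta   <- read_metadata(file.path(dir, "metadata.tsv"))
calls  <- ingest_cohort(dir, models, mode = "consensus", min_callers = 2L)

s  <- summarize_samples(calls, all_samples = meta$sample_id)
gs <- group_summary(s, meta, by = "center")
```

```
  center   n mean_n_variants sd_n_variants mean_titv sd_titv titv_pooled
1    BCM  40           359.1         60.26     2.617  0.2959       2.596
2     BI 120           278.6         44.95     2.767  0.3577       2.743
3  WUGSC  80           344.1         50.81     2.592  0.3490       2.550
counts ANOVA: F = 61.6, log10 p = -21.5
TiTv   ANOVA: F = 7.0,  log10 p = -2.9
```

The consensus-merged counts recover the injected structure: non-reference
centers sit ~25–30% above the reference center and the TiTv split survives
merging, both with decisive one-way ANOVAs (reported as log10 p to dodge
underflow). Now the within-gene stage:

```r
coll   <- build_location_collections(calls, meta)
ks_tbl <- pairwise_ks(coll, groups = sort(unique(meta$group)), min_k = 3L)
design <- pair_design(unique(meta[, c("group", "center")]),
                      type = "reference", reference = "BI",
                      contrast = "WUGSC")
sens   <- batch_ratio(ks_tbl, design)
parts  <- rank_and_partition(sens[sens$evaluable, ], decile = 0.10)
head(parts$ranked, 5)
```

```
evaluable genes: 100; flagged affected (r_g > 1): 21 (21%)
true affected among flagged: 20 of 21
  gene_id  p_min    p_max     r_g affected
1 G0085   0.0740 6.91e-79 1.07e77 TRUE
2 G0046   0.0733 9.05e-58 8.10e55 TRUE
3 G0049   0.135  7.38e-31 1.83e29 TRUE
4 G0054   0.345  1.07e-26 3.23e25 TRUE
5 G0033   0.0158 2.26e-25 6.96e22 TRUE
```

All 20 genes simulated with a shifted positional law are flagged (plus one
false positive), and the ranking's top decile is available for the survival
contrast via `gene_set_contrast()`. The whole chain — plus density
correlation heatmaps, bi-clustered log-p matrices, per-pair violin
summaries and the survival contrast — runs in one call with
`run_full_audit(audit_config(...))`, which writes every table as TSV, every
figure as PNG, and a JSON summary. A thin command-line front end is in
`inst/cli/audit.R` (`simulate` and `full-audit` subcommands).

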