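# famvar

Family-based rare-variant analysis for multiplex pedigrees sequenced by
whole-exome sequencing (WES).

Extended families with a high density of psychiatric illness (four or more
affected relatives) offer a route to rare risk variants that case-control
designs miss: a rare allele shared identical-by-descent by several affected
relatives is a far stronger signal than the same allele seen once in a
case. `famvar` implements the full analysis such a study needs, for
researchers working with multi-sample VCFs and pedigree files:

- **Variant annotation** — rarity against any number of population panels
  (MAF < 1% in *every* panel), worst-consequence ranking across overlapping
  gene models, a combined PolyPhen-2/SIFT pathogenicity score with a 0.99
  candidacy cut, the likely gene-disruptive (LGD) class (nonsense,
  frameshift indel, canonical splice, start-lost), and a brain-expression
  flag (mean RPKM > 1).
- **Sharing classification** — per family, a *potentially etiologic variant*
  (PEV) is a candidate carried by ≥ 3 affected and ≤ 1 unaffected relatives;
  a *likely neutral variant* (LNV) is carried by 1–3 unaffected and ≤ 1
  affected relatives and serves as the comparator pool. Compound
  heterozygotes are phased by parental transmission.
- **Matched-null enrichment** — are PEV genes overrepresented in a gene set
  (postsynaptic density, FMRP targets, ...)? The null draws R random gene
  sets matched to the query on coding-sequence length and missense
  constraint z-score (quantile-bin stratification) from genes with > 10×
  coverage; `p = (1 + #{null ≥ O}) / (1 + R)`, Bonferroni-corrected, with a
  log-gamma hypergeometric tail as the unmatched comparator.
- **Burden and onset** — per-subject counts of distinct rare LGD sites
  (total and brain-expressed), an affected-vs-unaffected Mann–Whitney U
  comparison (exact enumeration for small groups, tie-corrected normal
  approximation otherwise), and Spearman correlation of the brain-expressed
  burden with age of onset in 15–50-year typical-onset cases.
- **De novo detection** — trio Mendelian errors with two homozygous-reference
  parents, gated on read depth (> 20 in all trio members), offspring and
  parental alternate-read counts, and carriage by additional relatives.
- **Deletion inference** — runs of ≥ 3 consecutive hemizygosity-consistent
  Mendelian inconsistencies (opposite homozygotes in a parent-offspring
  pair) become CNV deletion calls; carriers are extended across the pedigree
  by constraint propagation, and array-style filters (MAF < 0.05, ≥ 25 kb,
  ≥ 25 probes) apply to external calls.
- **Relatedness checks** — PLINK-style method-of-moments identity-by-descent
  estimates (Z0, Z1, Z2, π̂) from common markers.
- **A gene-dropping simulator** — multiplex three-generation pedigrees,
  rare founder variants dropped through the pedigree, spiked etiologic
  variants, Poisson de novo events (0.97/offspring), hemizygous deletions
  over marker runs, 112× depth with genotype error, and ages of onset
  optionally coupled to disruptive burden. Every analysis above is validated
  against this generator's ground truth.

All user-facing functions take a data frame first and return tibbles, so
pipelines compose with the pipe.

## Worked example

```r
library(famvar)
library(dplyr)

study <- simulate_study(sim_config(n_families = 15, seed = 42))

ann     <- annotate_variants(study$variant_calls, study$features)
sharing <- classify_sharing(filter(ann, path_candidate), study$pedigree)
count(sharing, label)
#> # A tibble: 3 × 2
#>   label       n
#>   <chr>   <int>
#> 1 LNV        28
#> 2 PEV        16
#> 3 neither  1336

sites <- variant_sites(ann)
pev_genes <- sharing |>
  filter(label == "PEV") |>
  left_join(sites, by = "variant_id") |>
  pull(gene) |> unique()

spec <- null_spec(n_draws = 10000, seed = 7)
bg   <- build_background(study$features, spec)
enrich_gene_sets(pev_genes, study$gene_sets, bg, spec, m = 12)
#>        set_name set_size observed expected empirical_p corrected_p hypergeom_p
#> 1           PSD      150        9   1.5993      0.0001      0.0012    2.02e-06
#> 2  FMRP_targets       84        2   1.1728      0.3347      1.0000    2.50e-01
#> 3    DeNovo_PSY      160        0   1.7111      1.0000      1.0000    1.00e+00
#> 4         NMDAR       12        0   0.0398      1.0000      1.0000    1.00e+00
#> 5           ARC        8        0   0.0952      1.0000      1.0000    1.00e+00
#> 6 Mitochondrial      110        1   0.8970      0.6118      1.0000    7.27e-01
```

Sixteen family-level PEV calls emerge from ~1,400 classified candidate
sharing events; their 15 genes overlap the (spiked) PSD-like target set 9
times against a matched-null expectation of 1.6, an empirical `p` of 1e-4
(the floor is 1/(R+1)), which survives a 12-test Bonferroni correction —
while the decoy sets stay null. The rank statistics print the same way:

```r
mann_whitney_u(c(13, 14, 12, 15), c(14, 13, 16))
#> Mann-Whitney U = 4 (n = 4 vs 3), two-tailed p = 0.6 [exact enumeration]
```

The end-to-end pipeline over files (VCF + PED + feature TSV + GMT) is
`run_all(run_config(...))`, which writes one TSV per stage and a
`manifest.json`; two runs with the same config and seed are byte-identical.
A thin command-line wrapper lives at `inst/cli/famvar.R` (subcommands
`simulate` and `run-all`).

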