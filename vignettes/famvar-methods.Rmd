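---
title: "Methods: family-based rare-variant analysis in famvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant analysis in famvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical procedures `famvar` implements, the
assumptions behind them, the parameters that matter, and the design choices
made where more than one reasonable implementation existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The study design the package serves

The package analyses whole-exome variant calls from extended, multiplex
pedigrees ascertained for a high density of psychiatric illness — at least
four relatives affected with bipolar disorder type I or II or
schizoaffective disorder-manic type. Two affection schemes are built in:
**strict** (affected = BD-I, BD-II, SZMA; mirrors ascertainment) and
**broad** (adds recurrent unipolar depression; used for the onset-burden
analysis). Individuals whose phenotype falls outside both sides of a scheme
(`unknown`, and `RUD` under strict) are excluded from carrier counts on both
sides rather than lumped into either — the missing-data convention used
throughout: *a missing observation is never silently converted into a
negative one*. The same rule governs genotypes (a `missing` call is neither
carrier nor non-carrier) and brain expression (a gene absent from the
feature table is `NA`, not "not expressed").

## Variant-level annotation

**Rarity.** A variant is rare when its allele frequency is strictly below
`maf_max` (default 0.01) in *every* supplied population panel; a panel
without an entry contributes 0. Novel variants are therefore rare by
definition, matching how protein-truncating candidates absent from
reference panels are treated in practice.

**Worst consequence.** When transcript models disagree, the most damaging
class wins under the fixed severity order nonsense > frameshift indel >
canonical splice > start-lost > missense > synonymous > other. The first
four classes form the likely gene-disruptive (LGD) set; LGD status is a
class, never a score — a missense variant with a perfect pathogenicity
score is not LGD.

**Combined pathogenicity (CAROL-style).** PolyPhen-2 (damaging-is-high) and
SIFT (damaging-is-low, so reversed) are combined by the weighted-Z method:
with $d_1 = \mathrm{clip}(\mathrm{PP2}, \varepsilon, 1-\varepsilon)$ and
$d_2 = \mathrm{clip}(1-\mathrm{SIFT}, \varepsilon, 1-\varepsilon)$,

$$Z = \frac{w_1\Phi^{-1}(d_1) + w_2\Phi^{-1}(d_2)}{\sqrt{w_1^2+w_2^2}},
\qquad \mathrm{score} = \Phi(Z).$$

The original publication's trained weights are not recoverable from a
methods description, so the default is equal weights with `weights`
exposed; this preserves the threshold semantics (score in $[0,1]$, candidacy
at $\ge 0.99$). When exactly one predictor is available, the other's weight
is set to zero, which degenerates to the single transformed score — better
than discarding a scoreable variant. The clip constant $\varepsilon = 10^{-8}$
keeps $\Phi^{-1}$ finite at degenerate scores of exactly 0 or 1; the
monotonicity tests in the suite cover the full $[0,1]^2$ grid, where results
are insensitive to $\varepsilon$ below $10^{-6}$.

**Candidacy.** The potentially pathogenic pool is: rare **and** (LGD, or
missense with combined score $\ge$ 0.99). Rare LGDs are candidates without a
score gate — the disruptive classes are treated as damaging per se, with
scores gating only missense.

## Sharing classification

Carriers (genotype `het` or `hom_alt`) are counted per family among
sequenced, scheme-classified members; the same variant in two families
yields two independent calls, since sharing within a pedigree is the unit
of evidence. With affected carrier count $a$ and unaffected count $u$:

* **PEV** iff $a \ge 3$ and $u \le 1$;
* **LNV** iff $1 \le u \le 3$ and $a \le 1$, and not PEV;
* otherwise neither.

PEV takes precedence at the single boundary overlap. Married-in unaffected
parents count toward the unaffected maximum (the literal reading of
"unaffected relative"); this is configurable. LNV status requires the
identical allele shared, not merely any variant in the same gene.

Compound heterozygotes are flagged per subject and gene; phase is resolved
by parental origin where both parents are genotyped and Mendelian logic is
decisive (trans when the two alternate alleles trace to different parents),
otherwise `unknown` — never guessed.

## Matched-null enrichment

The question is whether genes carrying PEVs are overrepresented in a
candidate gene set against what matched random gene sets would show. The
background pool is genes with mean coverage strictly above 10×. "Approximate
matching" is realized as quantile-bin stratification — 10 coding-length
bins × 5 constraint z-score bins by default — rather than nearest-neighbour
matching: it is deterministic, simple to reason about, and faithful to
*approximate*. Each null replicate draws, for every query gene, one gene
uniformly from the query gene's stratum, without replacement within the
replicate (a gene set is a set); query genes themselves remain eligible. A
stratum holding fewer genes than the query requires falls back to the
nearest stratum by covariate centroid, and the event is signalled.

Because strata are disjoint and draws within a stratum are uniform without
replacement, the overlap of one replicate with a gene set is exactly a sum
of independent hypergeometric counts across strata. The implementation
samples null overlaps directly from that law (`rhyper` per stratum), which
is algebraically the same Monte Carlo at a fraction of the cost; explicit
gene identities are materialized by `draw_matched_set()`, which the
matching-fidelity tests exercise. With matching disabled the null collapses
to a single stratum and the empirical p-value converges on the analytic
hypergeometric tail — the oracle-equivalence test in the suite.

The empirical p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge O\})/(1 + R)$ with $R = 10{,}000$ draws by
default, so $p$ is never exactly zero and the floor is $1/(R+1)$. Bonferroni
correction defaults to $m = 12$ (six sets × two query pools — the PEV pool
and the LNV comparator); $m$ is always explicit in output so adding sets
cannot silently miscorrect. The unmatched hypergeometric tail is computed
via log-gamma sums for stability and reported alongside.

Coverage acts as eligibility only, not as a third matching covariate: the
coverage clause describes which genes can enter the pool at all, and
treating it as eligibility keeps strata well-populated.

## Burden and age of onset

Per subject, burden is the number of **distinct rare LGD sites carried** —
site counting, not allele counting (a homozygous carrier counts once),
the conservative reading of counting "variants". The brain-restricted
subcount keeps only genes with mean RPKM > 1; genes with unknown expression
are excluded rather than imputed.

The affected-vs-unaffected comparison is a self-contained Mann–Whitney U:
average ranks for ties; exact enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments when both groups have at most 8
members; otherwise a normal approximation with tie-corrected variance and a
0.5 continuity correction. $U_x + U_y = n_1 n_2$ is an invariant under both
paths. The onset analysis restricts to broad-scheme affected subjects with
onset inside the 15–50-year typical-onset window and computes Spearman's
$r_s$ (Pearson on average ranks) between onset and brain-expressed burden,
with $p$ from $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ df. At $|r_s| = 1$
the $t$ statistic degenerates and the exact permutation tail $2/n!$ is
reported instead. Constant input is an error, not a zero: the correlation is
undefined and silence would hide a filtering bug upstream. A mixed-model
variant of the burden comparison is deliberately out of scope; the rank-sum
test is the primary inference.

## De novo detection

A candidate requires a Mendelian error with both parents homozygous
reference. "Adequate read depth (AD > 20)" is read as **total depth above
20 in all three trio members** — the permissive interpretation of an
ambiguous phrase — with `gate_on = "alt"` one flag away. Two further gates
stand in for manual read review, which is not automatable: offspring
alternate reads $\ge 5$ and parental alternate reads $\le 1$. A candidate
carried by any additional relative is disqualified (the allele is then
inherited or a site-level artifact); configurable. Every failing site is
retained with its first failing gate recorded, so filter attrition is
auditable. Rate comparisons between affected and unaffected offspring reuse
the rank-sum test on per-offspring candidate counts; the simulator emits
coding sites only, so the coding restriction is a pass-through flag.

## Deletion inference and relatedness

A hemizygous deletion makes a carrier appear homozygous for the surviving
allele, producing a characteristic duo inconsistency: **opposite
homozygotes in a parent-offspring pair**. The detector scans each family's
sites in position order, marks sites where any genotyped pair shows that
signature, and merges successive supporting sites with inter-site gaps of
at most `max_gap_bp` (default 1 Mb); a run of at least `min_run = 3`
supporting sites becomes a deletion call spanning the first to last
supporting site. The source description gives no run-length or gap
thresholds for the genotype-based path, so these defaults are declared
package choices, tuned to exonic variant density rather than to array probe
density; the 25 kb / 25-probe / MAF < 0.05 filters apply to array-sourced
calls, and duplications are accepted from arrays only (the genotype
signature modeled here is specific to deletions).

Initial carriers are the members of inconsistent pairs that are never
heterozygous across the run; segregation across the rest of the pedigree
uses constraint propagation within the interval: heterozygous anywhere in
the interval ⇒ definite non-carrier; hemizygosity evidence ⇒ carrier;
otherwise unknown. On clean data this never promotes a true non-carrier to
carrier (only carrier→unknown and non-carrier→unknown errors are possible),
and contradictory carrier evidence aborts segregation with a conflict flag.
A flanking-haplotype approach was considered and rejected: the simulator
models no linkage outside the deleted interval (and carriers have no phase
inside it), so flanking haplotypes carry no signal under the generator's
own assumptions.

Pairwise relatedness uses PLINK-style method-of-moments identity-by-descent:
observed identity-by-state counts are compared with frequency-based
expectations to solve for $(Z_0, Z_1, Z_2)$ sequentially, the estimate is
projected onto the probability simplex (Euclidean projection), and
$\hat\pi = Z_1/2 + Z_2$. Sites are greedily pruned to a minimum pairwise
distance of 100 kb as an independence proxy, and monomorphic sites are
dropped; at least ~200 informative markers are recommended (a warning below
that).

## The synthetic-data generator

`simulate_study()` produces the study the analyses assume: by default 15
three-generation families (founder couple, four children, three married-in
spouses, two to three grandchildren per couple), rejection-sampled until at
least four members are strict-scheme affected, mirroring ascertainment.
Descendants are affected with probability 0.45 (BD-I 55%, BD-II 20%, SZMA
15%, RUD 10%); married-in parents are unaffected.

The site map mixes **rare exonic variants** (founder MAF 0.0005–0.005,
consequence classes at realistic exome proportions) with **common markers**
(MAF 0.35–0.5) laid out as one contiguous block per chromosome. The block
layout and high MAF emulate the clustered, high-heterozygosity
haplotype-informative marker panels that genotype-based CNV segregation
relies on in practice; deletions are spiked onto marker runs because only
polymorphic sites can expose hemizygosity. Gene dropping draws founder
haplotypes Bernoulli(MAF) and transmits one parental haplotype per site
independently — no linkage, except inside a spiked deletion interval, which
is re-dropped as a fully linked block with descent tracked exactly.

Spiked signals define ground truth: etiologic variants (founder-origin,
resampled until carried by ≥ 3 affected and ≤ 1 unaffected — no unaffected
at penetrance 1 — landing in a designated target gene set with probability
0.8), Poisson(0.97) de novo events per trio offspring (each a new site, het
in one offspring, untransmitted, so each event has exactly one
Mendelian-error signature), and hemizygous deletions over `span = 10`
consecutive markers with at least one informative transmission. Depth is
Poisson around 112× with binomial allele-depth splits (per-read miscall
0.001); genotype error perturbs a call to an adjacent state with probability
$\varepsilon$ (default 0). Ages of onset are uniform in 15–50 years, or
`beta0 - beta1 * burden + N(0, sigma)` clipped to that window under the
burden-coupled model (defaults `beta0 = 45` years, `beta1 = 1.5` years per
variant, `sigma = 5` years); the window matches the onset analysis filter
by construction.

**What the generator does not emulate — and what passing tests therefore do
not show.** Sites are far sparser than a real exome (hundreds, not tens of
thousands), so per-subject LGD burdens are of order 0–2 rather than ~13;
the pipeline's own burden and onset outputs on simulated data are
correspondingly weak or dominated by the spiked disruptive variants (which
concentrate in affected relatives by construction — the scaled-down study
can show a case-control burden difference even though the analysis's null
behaviour is what the calibration tests establish). The
parameter-recovery checks for the onset model therefore use the stated
design directly (n = 58, Poisson(8) brain-expressed burden — the
brain-expressed share of a realistic ~13-variant LGD burden — with the
default onset parameters). There is no linkage disequilibrium outside
deletion intervals, no X-linked inheritance (all sites autosomal), no
sequence-level read simulation, and recombination is free at every site.
Power and recovery results on this generator say nothing about annotation
quality or variant calling on real data — they validate the inference
machinery downstream of a call set.

**Test problem sizes.** The suite runs the deletion-recovery check over 200
families, null calibrations at 1,000 replicates with 999 draws each, the
onset power study at 1,000 replicates of n = 58, and identity-by-descent
recovery at 10,000 markers; the enrichment null-calibration configuration
(pool 4,000, set 1,000, query 200) was chosen — before the tests were
frozen — so that the discrete overlap distribution is fine-grained enough
for the empirical p to be near-uniform; with much smaller pools the
rejection rate at $\alpha = 0.05$ sits visibly below 0.05 because of tail
granularity, which is a property of discrete permutation tests, not an
implementation artifact.

## Reproducibility

Every random stage takes an explicit seed; functions seed a local RNG scope
and leave the caller's stream untouched. `run_all()` derives per-stage seeds
deterministically from the config seed, writes no timestamps, and is
byte-identical across reruns — a tested invariant. Coordinates are 1-based
inclusive everywhere except BED export (0-based half-open).

## Known limitations

The deletion detector requires polymorphic markers in the deleted interval;
a deletion spanning only monomorphic or rare sites is invisible to the
genotype signature, and detection power at the default `min_run = 3` decays
rapidly below ~8 informative sites. Segregation inference resolves only
members with decisive genotype evidence and leaves the rest unknown rather
than imputing. The method-of-moments IBD estimator assumes known allele
frequencies and unlinked markers; with estimated frequencies on small
samples it inherits the usual bias. The enrichment test conditions on the
observed query size and treats genes as exchangeable within strata; gene
sets that correlate with covariates not matched on (e.g. GC content) can
still confound.
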