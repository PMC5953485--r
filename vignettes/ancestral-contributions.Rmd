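---
title: "Marginal ancestral contributions in case-control pedigrees: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal ancestral contributions in case-control pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcontrib)
```

# The problem

Some heritable conditions in managed breeding populations — the motivating
example is atrial fibrillation in Standardbred racehorses, a condition with
modest liability-scale heritability (about 0.15) and no evident simple mode
of inheritance — appear concentrated in particular bloodlines. When the trait
is binary, case numbers are small and genotypes are unavailable, a pedigree
can still be interrogated: *which ancestors account for a larger share of the
gene pool of affected animals than of their healthy contemporaries?*
`pedcontrib` implements that analysis end to end: probabilities of gene
origin per birth cohort, a paired comparison of ancestral contributions
between affected and control cohorts with false-discovery-rate control,
descriptive pedigree statistics, and appearance profiles of implicated
ancestors in case pedigrees.

# Pedigree model and classical statistics

A pedigree is a directed acyclic parent graph: one record per animal with
sire, dam (either possibly unknown), birth year, sex and annotations. All
computations run in a topological order (every parent before its offspring),
and unknown ancestors are treated as unrelated founders throughout.

* **Kinship / inbreeding.** Kinship f(i,j) follows the standard recursion
  (f(a,a) = (1 + F_a)/2, f(a,b) = [f(a, sire(b)) + f(a, dam(b))]/2 with b the
  younger); F(x) is the kinship of x's parents, zero for founders or when a
  parent is unknown. The implementation builds the kinship matrix by the
  tabular method, in compiled code, on the *ancestor closure* of the animals
  of interest. This is dense (O(n^2) memory), which is the right trade-off at
  the registry-cohort scale this package targets (closures of a few thousand
  animals); the test suite verifies it against an independent memoized
  recursive implementation to 1e-12 on random pedigrees.
* **Average relationship** of a cohort is the mean additive relationship
  a_ij = 2 f(i,j) over unordered pairs i != j, self-pairs excluded — the
  conventional "average relatedness among members" reading; whether published
  cohort descriptives include self-pairs is usually unstated, and excluding
  them is the interpretation adopted here.
* **Pedigree completeness (PCI).** For each parental line, C_line is the mean
  over generations i = 1..5 of the proportion of the 2^(i-1) ancestor slots
  of that line that are filled; the index is the harmonic mean
  2 C_pat C_mat / (C_pat + C_mat). The harmonic mean is deliberate: it is 1
  only for a fully known five-generation pedigree, 0 as soon as either parent
  is unknown, and penalises one-sided pedigrees — a completely known dam line
  cannot compensate for a sire recorded without parents (that case gives
  2 * (1/5) * 1 / (6/5) = 1/3). Monotonicity (filling in an unknown ancestor
  never decreases the index) is covered by a property test.

# Probabilities of gene origin

The raw contribution of ancestor k to a reference cohort is
q_k = mean_j c(k -> j), where c halves along each parent link, terminates at
k, and is zero through unknown parents. Two compiled kernels make this cheap:
a backward (cohort-upward) accumulation gives q for *all* candidates in one
O(n) pass, and a forward pass gives the contributions of the selected
ancestors to every individual.

Marginal contributions are computed by greedy orthogonal decomposition:

1. Candidates are all individuals with at least one cohort descendant in the
   *current pruned* pedigree, excluding cohort members themselves and
   previously selected ancestors. (Ancestors need not be founders. A founder
   that is itself a cohort member is consequently not attributable; its share
   of the pool simply stays unexplained.)
2. Each candidate's raw q_k (current pedigree) is adjusted for the n-1
   already selected ancestors: p_k = q_k (1 - sum a_i), with a_i the raw
   contribution of selected ancestor i to individual k in the pedigree state
   of the current round.
3. The candidate with the largest p_k is selected and made a
   **pseudo-founder** (its parent links are deleted), so its own ancestry
   can never be double counted later.

Ties on p_k (within 1e-12) go to the earlier birth year, then the
lexicographically smaller id, making the decomposition deterministic and
invariant to input record order. Selection stops at a cumulative explained
share (default 0.99, matching the common practice of reporting the ancestors
behind 99% of a cohort's genetic variability), at a requested ancestor count,
at candidate exhaustion, or when no remaining candidate has a positive
marginal. With every founder known the marginals sum to 1 (tested at 1e-9);
with unknown parents in the pedigree the sum is below 1, which is why
coverage is reported at 99% rather than 100%. Raw contributions are verified
against a gene-dropping Monte Carlo oracle (100,000 allele drops, agreement
within 3 standard errors) in the acceptance tests.

Per-cohort decompositions are assembled into an ancestor x cohort
**contribution matrix**. A cell is *missing* when the ancestor was never
selected for that cohort — distinct from a selected ancestor whose marginal
rounds to zero — and row averages are taken over non-missing cells only, as
in published contribution tables.

# Cohorts and controls

Cases and controls are split into three-year birth windows sliding by one
year (1993-95 through 2005-07 in the motivating design: 13 windows, 26
cohorts), so an animal belongs to up to three consecutive windows.
"Contemporary" control matching is implemented as same birth year: it is the
reproducible reading of racing contemporaneity and respects the window
boundaries. Five controls are drawn per case without replacement and never
reused across cases (reuse would manufacture pseudo-replication); a case
without five same-year candidates is an error rather than a silent
relaxation. Animals lacking a birth year are excluded from cohorts but kept
as ancestors.

# The testing stage

Ancestors are tested when, in either group's matrix, their average
non-missing marginal contribution is at least 0.5% *and* they were selected
in two or more cohorts whose windows are pairwise disjoint (93/95 and 96/98
qualify; 93/95 and 94/96 do not — overlapping windows share animals and are
not independent evidence of persistence).

The per-ancestor test is a paired two-tailed t-test across windows on
d_w = affected_w - control_w with t = mean(d) / (sd(d)/sqrt(n)) and
df = n - 1. The pairing convention is **union with zero-fill**: a window
contributes a pair when either side is non-missing, and a missing side counts
as zero contribution. This convention is not arbitrary — an ancestor absent
from a cohort's decomposition explains none of that cohort's gene pool, so
zero is its contribution, and this is the unique convention that reproduces
the published degrees of freedom for 40 of the 41 tested ancestors in the
packaged tables (the single exception, where six usable windows imply df = 5
against a printed 4, is treated as a typo and excluded from exact-df
assertions). Positive t is reported as affected-direction. Exact two-sided
p-values come from the t distribution; published tables print only bounds, so
anchor comparisons in the tests allow for the 3-decimal rounding the packaged
tables carry (about 0.1-1.5% relative error on t). Ancestors whose
differences are constant across windows (zero variance) are reported as
degenerate and left unclassified. Benjamini-Hochberg step-up flags are
attached at 5% and 10% FDR over the tested set, via `stats::p.adjust`;
a brute-force step-up oracle cross-checks them in the tests.

# Appearance profiles

For each implicated ancestor, its occurrences in the five-generation pedigree
of every case are counted as *slots*: path-distinct positions, split by
whether the path's first step is the case's sire or dam link. Aggregates per
ancestor report how many cases carry it once vs multiple times, through the
sire only, the dam only, or both, and the percentage of cases with at least
one occurrence.

# The synthetic-data generator

Real registry pedigrees behind such studies are typically not deposited, so
the package ships a generator that reproduces the *statistical structure* the
analysis assumes:

* **Pedigree.** Founders (default 200) with staggered birth years over the 12
  years up to `years[1]`; one foal crop per year thereafter (default 150
  matings/year over 1979-2007, about 4,700 animals — the scale of the
  motivating study's cohort pedigrees). Dams are drawn uniformly among
  breeding-age mares (3-20 years, one foal per year); sires are drawn from
  breeding-age stallions (3-22 years) ranked by a fixed latent popularity,
  with truncated-geometric probabilities (`sire_skew`, default 0.15) — the
  popular-sire structure that makes a handful of stallions dominate a breed.
  Larger skew provably concentrates progeny on the top stallion (tested as a
  rank property over seeds).
* **Disease.** Liability l = u + e on a unit-variance scale: breeding values
  follow the pedigree (Mendelian sampling variance 0.5 h2 (1 - (F_s+F_d)/2)),
  h2 defaults to 0.15, and cases are animals born in the case window whose
  liability exceeds qnorm(1 - prevalence). A liability-threshold model is the
  appropriate stand-in for a moderately heritable binary condition with no
  established mode of inheritance; no Mendelian-locus simulator is included.
  Optionally a flat liability shift (`sire_family_effect`) is planted on
  every descendant of a designated "risk sire", creating the
  concentrated-sire-family signal the analysis is meant to detect.
* **What it does not emulate:** real mate selection (assortative mating,
  culling, imported outside blood), sex- or gait-specific disease expression,
  age structure in diagnosis, or registry data errors. Passing tests on
  synthetic data therefore validate the *machinery and its statistical
  behaviour*, not the historical claims of any particular real-data analysis.

All stochastic steps are reproducible from the configuration seed (pedigree,
phenotypes and control sampling use fixed offsets of it) and never disturb
the caller's RNG state.

# Simulation studies: calibration and power

The test suite runs two designed simulation studies. Problem sizes were
chosen once, desk-scale: 60 founders, one 60-80 foal crop per year over
1980-2003, cases born 1993-2003 (nine overlapping windows, 18 cohorts),
prevalence 4% (null) or 2% (power), 5 controls per case, 200 null replicates
and 40 power replicates.

**Null calibration — a deliberate negative control.** With h2 = 0 and no
family effect, case status is independent of the pedigree, so one would hope
the pipeline rejects each tested ancestor at about the nominal 5%. It does
not: at the study's own design the observed per-ancestor rejection rate is
about an order of magnitude higher, with rejections overwhelmingly in the
control direction. Two design features cause this, and each can be isolated:

* **Cohort-size asymmetry.** Affected cohorts are one fifth the size of
  control cohorts. A small cohort's decomposition reaches any cumulative
  threshold with fewer, larger marginals, so minor ancestors are
  systematically *missing* (zero-filled) on the affected side while carrying
  small positive values on the control side — a systematic negative
  difference that the t-test faithfully flags. This predicts exactly the
  signature visible in published applications of the design: the
  control-significant ancestors are predominantly minor contributors
  (averages of 0.5-3%) with strikingly large |t|, while the
  affected-significant ones are major contributors.
* **Overlapping windows.** Adjacent windows share two of three birth years,
  hence most of their members; the 13 paired differences are positively
  correlated and the nominal df = 12 overstates the information, inflating
  |t| in both directions.

When both features are removed — one control per case and three pairwise
disjoint windows — the same pipeline's rejection rate is statistically
indistinguishable from 5% (a green property test in the suite). The
anticonservativeness is therefore a property of the published *design*, not
an implementation artifact. The corresponding acceptance assertion (rate
within a few points of 5% at the study design) is left failing on purpose
rather than re-defining the design to pass it; results of this analysis on
real data should be read as descriptive rankings, and the control-direction
significances of minor contributors in particular should not be
over-interpreted.

**Power.** A liability shift of 2 (in liability SD units; threshold at
prevalence 2% is about 2.05, so a shifted animal's disease risk rises from 2%
to roughly 48%) is planted on the family of a moderately used stallion born
1984-88 — the male whose descendant count inside the case window is closest
to 60, large enough to be detectable yet small enough that unaffected
contemporaries still outnumber cases 5:1 in every birth year, keeping control
sampling feasible. Recovery means some member of the planted family — the
risk sire, one of its ancestors, or one of its descendants — is classified
affected-significant: the greedy decomposition legitimately attributes the
family's excess contribution to whichever family member has the largest
marginal in the affected cohorts, which is sometimes the sire's own heavily
used son (and pseudo-founder pruning can push it upward to a parent). Under
this design the planted family is recovered in well over 80% of replicates.

# Numerical and engineering choices

* Candidate and tie tolerances: q > 1e-14 to count as an ancestor; ties on
  p within 1e-12 broken by birth year then id; cumulative stop compared with
  a 1e-12 slack.
* Degenerate paired tests are detected with a relative variance guard
  (sd(d) below 1e-12 of |mean(d)|), so exact ties in printed 3-decimal data
  and floating-point dust are both caught.
* The dense tabular kinship bounds practical pedigree size (roughly 20,000
  animals in 8 GB); the gene-origin kernels are O(n) per round and handle the
  same sizes comfortably.
* Unknown parents may be encoded "", "0" or "NA" on input and are written
  back as empty fields; the pedigree writer orders rows by generation then id
  so output files are byte-reproducible.
* Checksummed fixtures: the packaged contribution and t-test tables are
  verified against an MD5 manifest at load time, as they are reference data
  whose silent modification would invalidate the comparisons built on them.

# Limitations

Beyond the calibration caveat above: contributions are expectations over
pedigree transmission, not realised genome sharing; unknown ancestors
truncate attribution (pools are explained to <100% when parentage gaps
exist); the decomposition is greedy, so reported marginals are
order-dependent by construction (the orthogonality guarantee concerns the
total, not per-ancestor uniqueness); and the appearance profiles count
pedigree slots within five generations, so they say nothing about
transmission beyond that depth.
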