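---
title: "Methods: SNP-based traceability of clonally propagated material"
author: "pedtrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based traceability of clonally propagated material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtrace)
```

# The problem

A clonal production chain in tree improvement looks like this: a few dozen
elite parents are mated in controlled crosses; embryogenic cell lines are
initiated from the resulting seed; each line is cryopreserved and also
planted as somatic trees in field tests; years later the best lines are
pulled from the cryobank and multiplied at scale. Every arrow in that
chain is a manual operation on living, visually indistinguishable
material. `pedtrace` provides the genetics to audit the chain: a panel of
biallelic SNPs informative enough that any sampled tissue can be assigned
to its cross of origin, and multilocus fingerprints that tie cryobank
tissue to the trees grown from it.

The package assumes a *closed* design: the candidate parents and crosses
are known and fixed. It never searches for unknown parents in an open
population. This is the correct model for a breeding program and it is
what gives exclusion-based assignment its power — a single incompatible
locus is evidence against a cross, not against the whole analysis.

# Data model

Genotypes are integer matrices, individuals × loci, coded 0/1/2 as the
count of the alternate allele, with `NA` as the missing value. `NA` was
chosen deliberately over a numeric sentinel: it cannot leak into
arithmetic unnoticed, and every operation in the package either handles
it explicitly or refuses it loudly. Files use a tab-separated dialect with
tokens `AA`/`AB`/`BA`/`BB`/`NA`; heterozygote allele order is meaningless
(all assignment mathematics operates on unordered genotypes), so `BA`
reads as `AB`. Unknown tokens are an error, never silently missing. VCF
import (biallelic records only) is available through `vcfR`.

Two quality filters mirror operational practice. Candidate loci are kept
only if no parent has a missing genotype and the platform quality score is
at least 0.60. Individuals are dropped when *strictly more than* 15 % of
their genotypes are missing: "more than" is read as a strict inequality,
so an individual sitting exactly on the boundary is kept. Both thresholds
are arguments, not constants.

# Per-locus statistics

For allele frequency $p$ (and $q = 1-p$):

* $H_e = 2pq$, with no small-sample correction. At the sample sizes
  panels are characterized on (hundreds to thousands of individuals), the
  unbiased correction is below $10^{-4}$ and would only obscure the
  algebraic relationships used in testing.
* $\mathrm{PIC} = 2pq - 2p^2q^2$, the biallelic specialization of
  Botstein's index.
* NE-PP, the parent-pair non-exclusion probability: the chance that a
  random unrelated pair is not excluded as the parents of a random
  offspring. All three genotypes are drawn from Hardy–Weinberg proportions
  at the *sample* allele frequency. It is computed by exhaustive
  enumeration of the $3^3$ genotype combinations against the Mendelian
  compatibility predicate, and an independently derived closed form
  ($p^2(1-q^2)^2 + q^2(1-p^2)^2 + 2pq\,[2(1-q^2)(1-p^2) - 4p^2q^2]$)
  serves as a cross-check; the two agree to $10^{-12}$ over
  $p \in \{0.01, \dots, 0.99\}$ in the test suite. NE-PP attains its
  minimum $23/32 = 0.71875$ at $p = 0.5$ — no biallelic locus can do
  better — and the panel-wide non-exclusion probability is the product
  over loci, justified by the one-SNP-per-gene selection that keeps loci
  effectively unlinked.
* `maf_from_he()` inverts $H_e = 2pq$ to its minor root
  $(1 - \sqrt{1 - 2H_e})/2$, so published per-locus $H_e$ values can
  parameterize all of the above. One caveat discovered while validating
  against the packaged reference table: a printed NE-PP can fall *below*
  the $23/32$ bound through independent rounding of $H_e$ and NE-PP at
  3 decimals (one locus with printed $H_e = 0.495$ prints NE-PP 0.718);
  such a value is unreachable from any frequency and is tested at a
  slightly wider tolerance with the reason stated in the test.

Degenerate inputs follow one convention everywhere: a monomorphic locus
has PIC 0, NE-PP 1, and a flagged $\theta$ of 0, so it sorts last in every
informativeness ranking.

Differentiation among full-sib families uses Weir and Cockerham's 1984
$\theta$, with each family as a subpopulation. The estimator was chosen
because it accommodates the unequal family sizes and incidental missing
genotypes of real certification batches; it is implemented directly from
the variance components (no suitable estimator ships in the declared
dependencies) and validated in the tests against an independently written
scalar computation and against the analytic value 1 for families fixed
for opposite alleles. Negative $\theta$ estimates are reported as
computed, not truncated; they simply rank below zero.

# Progeny simulation

`simulate_offspring()` draws, per locus, one allele uniformly from each
parent's two, independently across loci and offspring — exact Mendelian
sampling with no linkage, mutation or selfing. The same transmission
table $T(g_o \mid g_m, g_f)$ drives the likelihood assigner, so the
simulator and the model it is evaluated under cannot drift apart.
`simulate_progeny_dataset()` emits the truth (individual → cross) as a
separate table and deliberately does not encode the cross in individual
ids, so no assignment code path can cheat.

# Perturbation model

Benchmarks need datasets whose corruption level is exact, not
approximate, so perturbations sample exactly `round(rate × n_cells)`
cells without replacement from the full individual × locus grid —
per-cell Bernoulli draws would make "3.5 % missing" only true on average.
Genotyping errors replace a genotype by one of the two *other* states
uniformly (every altered cell differs from its original); an allele-flip
mode (homozygote → heterozygote, heterozygote → either homozygote) is
available as an alternative, since the true error process of a genotyping
platform is assay-specific and unknowable from called genotypes alone.
When errors and missingness are combined, errors are injected first and
missing cells are sampled from the remaining cells: a cell that is both
erroneous and missing would mask the error and silently lower the
realized error rate. The altered coordinates are attached as attributes
for auditing.

# Assignment

**Exclusion.** Per locus, the mismatch against a candidate pair is the
minimum number of allele substitutions (0, 1 or 2, measured as dosage
distance) turning the observed genotype into one the pair can produce.
Mismatches are summed across loci, and the tolerance (default 1) applies
to that *sum*, not per locus. The consequence — intentional — is that a
single homozygote-to-opposite-homozygote error (distance 2) already
exceeds the default tolerance, which is exactly the fragility to
genotyping errors that exclusion methods show in practice. Missing
offspring genotypes contribute 0 (uninformative), which is equally why
exclusion barely notices missing data. An individual is `assigned` when
exactly one cross attains the minimum total within tolerance, `ambiguous`
on ties (never broken by randomness or id order — a traceability verdict
must not depend on row order), `unassigned` when no cross qualifies.

**Likelihood.** Per locus the model is the contamination mixture
$(1-\varepsilon)\,T(g_o \mid g_m, g_f) + \varepsilon\,P_{\mathrm{HWE}}(g_o)$,
summed as log-likelihood over non-missing loci and maximized over the
design. The mixture is the simplest error model expressible without
platform knowledge; $\varepsilon$ defaults to 0.01 and is exposed.
With $\varepsilon = 0$ an incompatible locus yields $-\infty$, reproducing
pure Mendelian exclusion. Exact ties are `ambiguous`, and the margin
between best and second-best log-likelihood is reported as a confidence
measure.

**Problematic-parent diagnosis.** For an individual that fails its
putative cross, each parent is tested alone: a locus conflicts only when
offspring and parent are opposite homozygotes (no shared allele), and the
same summed tolerance applies. Mother-compatible/father-incompatible
reads as a wrong father (pollen contamination in breeding terms), the
converse as a wrong mother, neither as both wrong, both-compatible as
undetermined.

**Evaluation.** `evaluate_assignment()` reports the percentage of
individuals wrongly assigned (assigned to a cross other than the truth),
correctly assigned, ambiguous and unassigned — the four partition 100 % —
plus `pct_misassigned` (100 − correct) and the wrong rate among assigned
individuals only. Both conventions exist in the literature on assignment
robustness; reporting all of them costs nothing and avoids the ambiguity.
In the package's own robustness benchmarks the *misassignment* rate is
the headline metric for method comparison, because under a summed allele
tolerance the exclusion method's failures under genotyping errors
manifest almost entirely as non-assignment rather than wrong assignment;
the strict wrong rate alone would paint exclusion as flawlessly robust
while it silently loses a third of the batch.

# Marker selection

Three ranking procedures, all returning a full permutation of the
candidates with lexicographic tie-breaks on locus id:

* `rank_by_fst()` — descending per-locus $\theta$ among simulated
  families (deterministic);
* `rank_by_maf()` — ascending $|\mathrm{MAF} - 0.5|$ computed on the
  *parents*, since parental frequencies determine expected progeny
  frequencies and selection happens before progeny exist (deterministic);
* `rank_by_rf_importance()` — descending mean decrease in Gini impurity
  from a `randomForest` classifier on genotype codes with the cross as
  class, 10,000 trees by default (large ensembles stabilize the
  importance ordering); seeded and reproducible.

`select_top_k()` walks a ranking best-first, skipping non-assayable loci
and loci whose gene is already represented; if the gene constraint blocks
reaching $k$ it is relaxed with a warning, and too few assayable loci is
an error.

# What the synthetic generator does and does not emulate

`generate_population()` draws parents in Hardy–Weinberg proportions at
frequencies uniform on [0.1, 0.5] — intermediate frequencies with enough
spread that ranking procedures have signal — and mating designs as
distinct unordered pairs, optionally biased toward parent re-use to
stress half-sib confusability. Defaults (73 parents, 68 crosses, 36 loci)
mirror the scale of an operational spruce program.

What this reproduces well, as verified by the acceptance tests: clean
data at tolerance 0 yields 0 % wrong assignments; exclusion degrades
monotonically with genotyping-error rate and much faster than likelihood
(at 0.5 % errors, misassignment near 3 % versus below 0.2 %); missing
data alone leave exclusion essentially untouched; the random-forest
procedure yields the lowest downstream assignment error of the three.

What it does not reproduce: HWE-random parents carry no relatedness, no
linkage disequilibrium and no ascertainment history. One measurable
consequence: under these conditions the $F_{st}$ ranking — which exploits
the realized family structure of the very design being assigned —
consistently *beats* the design-blind MAF ranking in downstream error,
whereas on real programs MAF-based panels are usually reported as the
stronger simple baseline. The corresponding ordering check
(rf ≤ maf ≤ fst) is asserted in the acceptance suite as the expected
field pattern and fails on its maf ≤ fst half under simulation; we keep
it failing rather than bend the generator, as a documented marker of
where simulated and real panels part ways. Passing tests on synthetic
data therefore validate the machinery and its qualitative robustness
patterns, not the quantitative error rates of any particular real panel.

# Fingerprinting

A fingerprint is the panel-ordered concatenation of one symbol per locus
(`A`/`H`/`B`/`?`), constant-width so a database is a diffable TSV of
`line_id`, `role`, `fingerprint`. With 36 biallelic loci the space of
complete fingerprints is $3^{36} > 1.5 \times 10^{17}$, so collisions
among unrelated material are negligible; full sibs collide with
probability given by the per-locus product of sib genotype-match
probabilities (e.g. $(3/8)^L$ for $L$ double-heterozygous loci), which
the duplicate detector's tests verify by simulation against that
enumeration. Matching compares only loci non-missing in both fingerprints
and reports (mismatches, overlap); defaults tolerate one mismatch and
require 85 % overlap, mirroring the individual-missingness filter. With
missing data identity is not transitive, so duplicate detection reports
pairwise links and never closes them into groups.

Cell-line diagnosis combines member legitimacy and mutual identity: all
members identical and illegitimate places the error at the breeding stage
(sub-classified by the problematic parent); legitimate cryobank tissue
with a stray field tree places it in production; legitimate trees with
illegitimate cryobank tissue indicts the cryobank; records lacking a
cryobank member are classified on the reduced evidence with a warning.
Mixed patterns fall back to the earliest demonstrable stage.

# Numerical and testing choices

Every stochastic function takes an integer seed; composite pipelines
derive per-stage substreams from one seed (kept within 32-bit range), so
an end-to-end run is bit-reproducible. Statistical checks in the test
suite use fixed seeds with wide bands (3 standard errors, or chi-square
at $p > 0.001$) so they are deterministic in practice. The benchmark
problem sizes in the tests — 73 parents / 68 crosses / 36 loci with 20
offspring per cross and 5 replicates for robustness; 30 parents / 25
crosses / 80 candidate loci with 1,000-tree forests for the
procedure-ordering benchmark — were chosen as the smallest sizes at which
the compared quantities separate cleanly from their sampling noise.

# Known limitations

No open-population paternity search, sibship reconstruction or genotype
imputation; no multi-allelic markers; no linkage map (loci are assumed
unlinked, which panel construction should enforce); no somaclonal-variant
detection — a fingerprint mismatch within a line is reported as a
mix-up, and distinguishing true somaclonal variation from mislabelling
requires evidence outside the genotype panel. The likelihood error model
is a deliberate simplification; if a platform's confusion structure is
known, $\varepsilon$-mixtures per genotype class would be the natural
extension.
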