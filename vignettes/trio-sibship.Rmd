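---
title: "Trio sibship testing: model, enumeration and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio sibship testing: model, enumeration and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibtrio)
```

## The hypothesis test

sibtrio evaluates one pair of hypotheses about a tested individual S3 and two
reference full siblings S1, S2 typed at autosomal STR loci:

* **H1 (related):** S1, S2 and S3 are full siblings — children of one
  (untyped) parental pair.
* **H2 (unrelated):** S1 and S2 are full siblings; S3 is unrelated to both.

At a single locus the likelihood ratio is `LR = R/U` with

* `R = P(g1, g2, g3 | H1)`: the joint probability of the three genotypes as
  children of a common parental pair,
* `U = P(g1, g2 | siblings) · P(g3 | HWE)`.

Both terms come from the same likelihood engine: a sum over ordered parental
genotype pairs (father, mother) of Hardy–Weinberg priors (`a²` for a
homozygote, `2ab` for a heterozygote) times Mendelian transmission
probabilities (`1`, `1/2` or `0` per parent and allele) for every child.
Modelling assumptions, made explicit:

* Hardy–Weinberg equilibrium and linkage equilibrium across loci; per-locus
  LRs multiply.
* No population substructure correction (no theta/Fst adjustment) and no
  mutation model: a trio with `R = 0` is a hard exclusion.
* No silent/null alleles; the sex marker AMEL is carried through parsing but
  excluded from every likelihood product.

These assumptions suit the intended use — screening candidate sibships
against a reference allele-frequency table — but mean a single apparent
inconsistency in casework (possibly a mutation or a null allele) is scored
as an exclusion; the per-trio inconsistency histogram
(`inconsistency_locus_counts()`) exists precisely so users can see how many
loci an exclusion rests on.

### Exact aggregation of unobserved alleles

The parental sum runs over the alleles observed in the tested genotypes plus
**one** pseudo-allele carrying all remaining frequency mass (unlisted rare
alleles as well as listed-but-unobserved ones). This is exact, not an
approximation: no child carries an unobserved allele, so for any parental
genotype containing an unobserved allele the transmission factors are
identical whichever unobserved allele it is, and the sum over them
telescopes into a single term with the aggregated mass. The test suite
checks this by comparing against a brute-force oracle that sums over ordered
parental allele 4-tuples across the full universe.

With at most 6 distinct observed alleles per trio the engine works on at
most 28 unordered parental genotypes; each per-locus LR is a pair of
quadratic forms in a 28-vector, so no compiled code is needed.

## Pattern classes and closed forms

Up to relabelling of alleles, a trio at one locus belongs to one of 63
classes: within each of the 7 reference-pair classes (AA/AA, AA/AB, AA/BB,
AA/BC, AB/AB, AB/AC, AB/CD) the tested genotype is a pair over the observed
letters A–D plus the placeholders X, Y for alleles unseen in the references.
`enumerate_trio_patterns()` lists them; 37 are non-excluded and 26 are
excluded. Exclusion is decided combinatorially — does any ordered parental
genotype pair over the children's alleles plus two wildcards produce all
three children? — so it is exact and independent of frequencies. One class,
AB/CD/BC, is sometimes tabulated as an exclusion, but parents AC × BD
produce AB, CD and BC, and its LR formula `1/(16bc)` verifies; counting it
on both sides is what yields the alternative totals 64/27 instead of 63/37/26.

`canonicalize_trio()` maps concrete genotypes to their class. The canonical
form is the lexicographically smallest pattern string over the reference
orientation (S1/S2 are exchangeable) and the scan order of each genotype's
two alleles. A fixed scan order alone is not sufficient: when the allele
shared by S1 and S2 sorts last in both genotypes, a fixed scan spells the
class "AB BC …", which no enumeration lists; minimising over scan orders
always lands on the conventional spelling ("AB AC …") and keeps the map
deterministic, relabelling-invariant and swap-invariant. The function also
returns the letter→allele bindings so the class's closed form can be
evaluated on concrete frequencies.

Each non-excluded class carries a closed-form LR, a rational function of the
observed-allele frequencies only (terms in an unobserved allele's frequency
always cancel). The stored forms were derived by exact symbolic summation
over parental pairs and are verified in the tests against the numeric oracle
at 100 random frequency points per class to a relative 1e-9. Users should be
aware that some published tabulations of these 37 formulas contain
derivation errors in 10 classes (AA/AB/AB, five of the AB/AB classes, and
three of the AB/AC classes, e.g. `(1 + 3a)` instead of `(1 + 3a + b)` for
AA/AB/AB): those versions implicitly give a heterozygous child of two
heterozygous parents transmission probability 1/4 per ordered parental pair,
where the correct value is 1/2 because the child can receive its two alleles
from either parent. Monte-Carlo simulation independent of the engine — e.g.
P(third child AB | two AB children of the same parents) at a = b = 1/4 is
exactly 1/2, not the 0.49 the uncorrected AB/AB/AB formula implies —
confirms the corrected forms.

## Combining loci: the exclusion floor

An excluded locus has `lr = 0`; multiplying zeros would make every combined
LR with a single inconsistency identically zero and its log undefined. At
combination time each excluded locus therefore contributes `floor_value`
(default **0.001**) instead. The floor is deliberately harsh — three
inconsistent loci drive the combined LR down by 10^9 — but keeps the
statistic finite and plottable. Whether the surrogate should apply per
excluded locus or once per profile set is a genuinely open convention;
sibtrio defaults to per-locus (`floor_scope = "locus"`, consistent with
per-locus multiplication) and exposes `floor_scope = "profile"` for the
alternative. Combined LRs are reported in natural scale and log10; after
flooring, `log10(0)` cannot occur.

## The population simulator

`simulate_population()` emulates the virtual-family design used to calibrate
trio sibship tests: both parents drawn from HWE at every locus of a
frequency table, children formed by picking one allele per locus from each
parent, and four modes — 3S (two reference siblings + true sibling), 2S1U
(+ independent HWE individual), and duo controls 2S and 2U. Every family is
scored with the combined LR (trio) or duo SI.

Design choices:

* **Seeding.** A root seed spawns one L'Ecuyer-CMRG substream per family
  (`parallel::nextRNGSubStream`), so populations are bit-reproducible and
  order-independent; the user's RNG state is saved and restored.
* **Residual mass.** Unaccounted frequency mass is simulated as one explicit
  synthetic allele, `"_OTHER"`, so every sampled profile can be scored
  against the same table.
* **Duo controls** are fresh draws, not reuses of the trio families; the two
  estimands are independent either way, and fresh draws keep each mode a
  self-contained experiment.
* **Synthetic panels.** `synthetic_panel()` stands in for a published
  population table: 15 loci × 8 alleles by default, frequencies drawn from a
  symmetric Dirichlet with concentration 2, giving expected heterozygosity
  `1 − (α+1)/(kα+1) ≈ 0.82` — typical of forensic STR multiplexes.
  `concentration = Inf` gives equifrequent alleles.

What the simulation does *not* emulate: genotyping error, mutation,
population substructure, relatives other than one nuclear family, and the
allele-frequency spectrum of any real population. Passing operating
characteristics on a synthetic panel therefore demonstrate the method's
behaviour under its own assumptions at realistic heterozygosity, not
population-specific performance; with a real frequency table supplied as
CSV the same code computes the population-specific equivalents.

## Classification metrics

`confusion_at_threshold()` calls a comparison "sibling" when its combined LR
clears a threshold, with both strict (`LR > t`, natural for "greater than 1")
and non-strict (`LR ≥ t`, natural for "at least 100") conventions exposed.
Rates follow the standard definitions; accuracy is `(TP+TN)/(TP+TN+FP+FN)`.
(An alternative sometimes quoted, `TP/(TP+FP+FN)`, is not a proper accuracy
and does not reproduce the standard worked values; sibtrio uses the standard
formula.) Percentages are kept at full precision; display rounding is
half-up at two decimals (`round_half_up()`), with a small snap tolerance so
decimal values sitting a few ulp below .5 in binary round as intended.

## Numerical notes and problem sizes

* Exclusion is detected as `R ≤ 0`; `R` is a sum of non-negative products,
  so it is exactly zero precisely when no parental pair is compatible, and
  the combinatorial and numeric routes agree (tested over all 63 classes).
* The allele universe is put in canonical order before summation, so LRs are
  bit-identical under swapping S1 and S2.
* Per-locus results inside `simulate_population()` are memoised per locus on
  the canonical genotype-triple key; with 8-allele loci and 10,000 families
  this cuts the number of engine evaluations by roughly an order of
  magnitude.
* Test and acceptance problem sizes: populations of 10,000 families on a
  15-locus, 8-allele synthetic panel for operating characteristics
  (sensitivity and specificity at `LR > 1` each ≥ 99%, non-exclusion of
  unrelated trios ≤ 5%, median log10 LR separation > 10); 10,000 draws for
  HWE recovery within 4σ binomial bounds; 100 random frequency points per
  pattern class for formula verification. A full 10,000-family population
  simulates and scores in well under a minute on one CPU.

## Limitations

* Only the full-sibling-of-both vs unrelated hypothesis pair; no
  half-sibling, avuncular or parent–offspring alternatives.
* No theta correction, mutation model, or allowance for silent alleles — an
  exclusion is absolute under the model.
* The duo/trio case report is only as good as the supplied frequency table;
  alleles missing from the table are an error by default rather than being
  silently floored.
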