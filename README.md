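# sibtrio

Trio sibship testing from autosomal STR genotypes: is a tested individual a
full sibling of **two** reference siblings, or unrelated to them?

Kinship casework — disaster victim identification, immigration, inheritance
disputes — often has no parent available, only putative siblings. A single
reference sibling is a weak anchor: full siblings share 0, 1 or 2 alleles
identical by descent with probabilities 1/4, 1/2, 1/4, so at any one locus a
true sibling may share nothing. With two reference siblings the hypothesis
test sharpens dramatically: incompatible trios can be positively *excluded*
(no parental pair could have produced all three genotypes), and compatible
ones accrue much larger likelihood ratios than duo comparisons.

## The statistic

For genotypes of reference siblings S1, S2 and tested individual S3 at one
locus, sibtrio computes the likelihood ratio

    LR = R / U

- `R` = P(S1, S2, S3 | all three are full siblings), obtained by exact
  summation over ordered parental genotype pairs: Hardy–Weinberg priors for
  the parents (`a²` homozygote, `2ab` heterozygote) times Mendelian
  transmission probabilities for each child.
- `U` = P(S1, S2 | full siblings) × P(S3 | unrelated, HWE).

Per-locus LRs multiply across independent autosomal loci into a combined
sibling index (SI); loci where `R = 0` (a genetic inconsistency, i.e. an
exclusion) enter the product as a small surrogate value (default 0.001) so
the combined SI stays finite. The duo sibling index for a single reference
sibling uses the same engine and equals the classical IBD form with
κ = (1/4, 1/2, 1/4); two individuals sharing no allele score exactly 1/4.

Up to allele relabelling there are 63 trio genotype classes at a locus, of
which 37 are non-excluded; each carries a closed-form LR as a rational
function of the observed allele frequencies (e.g. `AA/AB/AC → 1/(8a + 8a²)`,
`AB/CD/AC → 1/(16ac)`). The package enumerates the classes, decides exclusion
combinatorially, and stores exactly derived closed forms that are verified
against a brute-force likelihood oracle in the test suite. (Several
previously published tabulations of these formulas drop terms arising from
heterozygote × heterozygote parental pairs; see the vignette.)

A Hardy–Weinberg simulator generates virtual populations — 3S (two reference
siblings + true sibling), 2S1U (+ unrelated), and duo controls 2S / 2U — and
classification metrics (sensitivity, specificity, PPV, NPV, accuracy) are
tabulated at chosen LR thresholds.

## Worked example

```r
library(sibtrio)

db <- synthetic_panel(n_loci = 15, n_alleles = 8, seed = 7)  # frequency tables
set.seed(42)
father <- sample_parent(db, "F"); mother <- sample_parent(db, "M")
s1 <- sample_child(father, mother, "S1")
s2 <- sample_child(father, mother, "S2")
s3 <- sample_child(father, mother, "S3")   # true sibling of s1, s2

combined_lr(list(s1, s2, s3), db)
#> <combined_lr> 15 loci, 0 excluded
#>   combined LR = 6.96681e+10  (log10 = 10.8430; floor 0.001 per locus)

combined_lr(list(s1, s2, sample_parent(db, "U")), db)   # unrelated individual
#> <combined_lr> 15 loci, 4 excluded
#>   combined LR = 5.45566e-15  (log10 = -14.2632; floor 0.001 per locus)
```

The true sibling scores a combined LR of ~7 × 10^10 with no inconsistent
locus; the unrelated individual is excluded at 4 of 15 loci and its combined
LR collapses to ~5 × 10^-15. Pattern classification and threshold metrics:

```r
canonicalize_trio(c("12","17"), c("13","15"), c("12","15"))
#> <trio_pattern> AB CD AC  [LR = 1/(16ac)]
#>   bindings: A=12, B=17, C=15, D=13

confusion_summary(tp = 9850, fn = 150, fp = 1, tn = 9999, threshold = 100)
#> <confusion_summary> threshold 100 (LR >= t)
#>   TP 9850  FN 150  FP 1  TN 9999
#>   sensitivity 98.50%  specificity 99.99%  PPV 99.99%  NPV 98.52%  accuracy 99.25%
```

## Command line

A thin CLI over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sibtrio.R", package = "sibtrio"))')
Rscript $CLI fixtures --loci 15 --alleles 8 --seed 1 --out freqs.csv
Rscript $CLI simulate --freqs freqs.csv --n 10000 --mode 3S   --seed 1 --out pop_3s.tsv
Rscript $CLI simulate --freqs freqs.csv --n 10000 --mode 2S1U --seed 2 --out pop_2s1u.tsv
Rscript $CLI metrics  --sib pop_3s.tsv --unrel pop_2s1u.tsv --threshold 1
Rscript $CLI patterns
Rscript $CLI lr --freqs freqs.csv --profiles profiles.csv
```

Input formats: frequency CSV with header `locus,allele,frequency` (one row
per allele; per-locus sums may be below 1, the remainder is treated as
residual rare-allele mass) and profile CSV with header
`sample_id,locus,allele1,allele2` (homozygotes repeat the allele; AMEL is
accepted and skipped in all LR products).

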