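# snpdist

Distance-based case–control analysis of SNP genotype data: which
minor-allele-frequency class of variants — common (MAF ≥ 5%), low-frequency
(0.5% ≤ MAF < 5%) or rare (MAF < 0.5%) — separates cases from controls?

The package is aimed at researchers with exome-array or sequencing genotype
matrices for a case–control cohort who want a variant-*class*-level view of
genetic signal (the "missing heritability" question), rather than
single-variant association tests.

## The method

For two diploid individuals genotyped on an ordered SNP set of size *n*, the
genotype Hamming distance is

    H(X, Y) = Σᵢ δ(gᵢˣ, gᵢʸ),   δ(a, b) = 0 if a = b, 1 otherwise

with genotypes compared as unordered allele pairs (A/G = G/A), and the
normalized form NH = H/n. The workflow is: read genotypes (VCF, PLINK 1
binary, or a plain genotype table) → variant QC (call rate ≥ 0.95, biallelic,
Hardy–Weinberg exact P ≥ 1e−6 in controls) → MAF classification → per-class
pairwise distance matrix → classical (Torgerson) MDS into the plane → a
two-sample Hotelling's T² test of case–control mean separation,

    T² = (n₁n₂/(n₁+n₂)) (x̄₁−x̄₂)ᵀ S⁻¹ (x̄₁−x̄₂),
    F  = T² (n₁+n₂−p−1)/(p(n₁+n₂−2)) ~ F(p, n₁+n₂−p−1).

An allele-sharing IBS distance drives the conventional
population-stratification screen, and a seeded synthetic cohort generator
with class-specific allele-frequency divergence supports end-to-end
validation. See the methods vignette
(`vignettes/genotype-distance-methods.Rmd`) for assumptions, numerical
conventions and limitations.

## Worked example

Three subjects genotyped at eight SNPs:

```r
library(snpdist)
gm <- table1_fixture()
d  <- pairwise_distances(gm, metric = "hamming")
d
#> genotype_dist (hamming): 3 samples, 8 variants (set: all)
#>   X Y Z
#> X 0 7 5
#> Y 7 0 3
#> Z 5 3 0
```

X and Y differ at 7 of the 8 SNPs, Y and Z at 3, X and Z at 5 — subjects
with smaller Hamming distance are genetically closer, the premise the
class-level analysis builds on. A full analysis on a synthetic cohort:

```r
sim <- simulate_cohort(n_cases = 40, n_controls = 40, n_common = 300,
                       n_low_freq = 100, n_rare = 300,
                       affected_fraction = c(common = 1), effect_size = 1.4,
                       seed = 71)
fit <- hamming_analysis(sim$genotypes, sim$phenotypes,
                        classes = c("common", "low_frequency"))
summary(fit)
#> Case-control separation by variant class (metric: hamming)
#>          class n_variants        t2   p_print p_bonferroni note
#>         common        312 358.46000 < 2.2e-16 3.226442e-29
#>  low_frequency        189   0.83282    0.6644 1.000000e+00
```

Here the planted common-variant divergence is detected (T² = 358, P <
2.2e−16) while the unaffected class stays null. `stratification_check()`
runs the same flow with the IBS metric and flags MDS-plane outliers;
`plot(fit)` draws the per-class MDS scatters colored by case/control
status. A thin command-line wrapper with `run`, `stratify` and `simulate`
subcommands is installed at `inst/scripts/snpdist`.

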