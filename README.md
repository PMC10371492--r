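# kinmatrix

Genetic relationship matrices for diploid and autopolyploid species:
pedigree-based (**A**), marker-based (**G**), and single-step combined
(**H**), with allele-dosage marker QC, a gene-dropping simulation oracle,
and exports for mixed-model and GWAS software.

## Who this is for

Breeders, quantitative geneticists and ecologists who need the covariance
structure among individuals before fitting anything: diversity summaries,
ABLUP/GBLUP breeding-value prediction, variance-component estimation, or a
polygenic kinship term in association studies. The package covers species
where standard diploid tooling falls short — autotetraploids and higher
even ploidies, pedigrees with no sex distinction, bulk-harvested offspring
with probabilistic parentage — while remaining a complete toolkit for
diploids.

## What it computes

Fifteen constructions, enumerated by `method_grid()`:

* **Pedigree (A)** — diploid additive (tabular recursion,
  `A[i,i] = 1 + F`); diploid dominance; autopolyploid additive for any even
  ploidy *m* with double-reduction fraction `w` (the probability that a
  gamete allele pair carries two copies of one parental allele; entries are
  normalized so non-inbred founders have diagonal 1 and
  `A[i,i] = 1 + (m-1)F`); an alternative `slater = TRUE` polyploid variant.
  Plus polycross pedigrees (`Amatrix_polycross()`: a bulk offspring of a
  candidate group C is related `1/|C|` to each candidate, or
  `0.5 / n` to each of n pollen donors when the mother is fixed) and
  incremental expansion (`expand_Amatrix()`, exactly equal to a rebuild).
* **Genomic (G)** — VanRaden `ZZ'/(m Σ p_k q_k)` for any even ploidy;
  Yang marker-standardized; Liu weighted; Su and Vitezica diploid
  dominance; Endelman digenic dominance for autopolyploids; the
  full-autopolyploid dosage-class-indicator model; the pseudo-diploid
  recoding; and a `[0,1]` allele-ratio mode for GBS-style continuous
  scores.
* **Hybrid (H)** — Martini `H22 = (τG⁻¹ + (1-ω)A22⁻¹)⁻¹` block blending,
  and Munoz per-relationship-class shrinkage of G toward A; both with
  positive-definiteness management (`ensure_positive_definite()`).

A compiled gene-dropping engine (`gene_drop()`) transmits labelled founder
alleles through the pedigree under the same gamete model (including double
reduction) and serves as the package's identity-by-descent ground truth;
`simulate_pedigree()` / `simulate_markers()` generate synthetic test data
with the same machinery.

## Worked example

A tetraploid pedigree with a cross and a selfing, with 10% double
reduction:

```r
library(kinmatrix)

ped <- data.frame(id      = c("F1", "F2", "F3", "cross1", "self1"),
                  parent1 = c(0, 0, 0, "F1", "cross1"),
                  parent2 = c(0, 0, 0, "F2", "cross1"))
A <- Amatrix(ped, ploidy = 4, w = 0.1)
A
#> <relmat> A_additive, 5 x 5, ploidy 4, method kerr
#>   mean diagonal 1.1560, range [0.0000, 1.6800]
#>         F1  F2 F3 cross1 self1
#> F1     1.0 0.0  0    0.5  0.50
#> F2     0.0 1.0  0    0.5  0.50
#> F3     0.0 0.0  1    0.0  0.00
#> cross1 0.5 0.5  0    1.1  1.10
#> self1  0.5 0.5  0    1.1  1.68

round(inbreeding_coef(A), 4)
#>     F1     F2     F3 cross1  self1
#> 0.0000 0.0000 0.0000 0.0333 0.2267
```

Parent-offspring relatedness is 0.5 as in diploids, but double reduction
makes even the outcross `cross1` slightly inbred (F = w/3 = 0.0333: a
duplicated allele pair can arrive in one gamete), and the selfed offspring
reaches F = 0.2267, well above the diploid-intuition value. The diagonal is
`1 + 3F` for tetraploids.

Genomic and single-step matrices on a simulated tetraploid population
(30 founders, one generation, 5,000 markers):

```r
pop <- simulate_pedigree(sim_config(n_founders = 30, n_generations = 1,
                                    ploidy = 4, w = 0.1, seed = 11))
M <- simulate_markers(pop, n_markers = 5000, ploidy = 4, w = 0.1, seed = 12)
G <- Gmatrix(M, method = "VanRaden", ploidy = 4)
mean(diag(G))        # 1.048  -- close to 1, as expected at HWE-like founders
Apop <- Amatrix(pop, ploidy = 4, w = 0.1)
mean(abs(G[rel_labels(Apop), rel_labels(Apop)] - Apop))   # 0.05

geno <- tail(rel_labels(Apop), 30)   # only the progeny are genotyped
Gsub <- relmat(unclass(G)[geno, geno], geno, kind = "G_additive", ploidy = 4)
H <- Hmatrix(Apop, Gsub, method = "Martini", tau = 1, omega = 1)
round(unclass(H)[c("F01", "G1_01", "G1_02"), c("F01", "G1_01", "G1_02")], 3)
#>       F01 G1_01 G1_02
#> F01     1 0.000 0.000
#> G1_01   0 1.064 0.414
#> G1_02   0 0.414 0.980
```

The genotyped block of H carries the realized (marker) relationships —
e.g. the two sibs `G1_01`/`G1_02` realized 0.414 rather than their
expected 0.5 — while ungenotyped founders keep pedigree values, corrected
through the pedigree links.

Matrices are written with `write_relmat()` as dense labelled CSV or as the
lower-triangle `(row, col, value)` long format that asreml-R, rrBLUP and
GWASpoly-style tools ingest; `invert_relmat()` provides checked inverses.
A thin command line lives at `inst/cli/kinmatrix.R`
(`Rscript kinmatrix.R amatrix --pedigree ped.csv --ploidy 4 --w 0.1 ...`).

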