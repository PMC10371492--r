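---
title: "Relationship matrices for diploids and autopolyploids: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relationship matrices for diploids and autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmatrix)
```

## The problem

Most quantitative-genetic analyses — variance-component estimation, breeding-value
prediction (ABLUP/GBLUP), association mapping with a polygenic control term —
require a matrix describing how related every pair of individuals is. kinmatrix
builds the three standard flavours under one roof, for diploids and
autopolyploids of any even ploidy:

* **A**: the *expected* additive relationship implied by a pedigree;
* **G**: the *realized* relationship estimated from allele-dosage markers, under
  several additive and dominance parametrizations;
* **H**: a single-step blend that extends genomic information to ungenotyped
  relatives through the pedigree.

All matrices are returned on a normalized scale where a non-inbred founder has
diagonal exactly 1, so entries are directly comparable across ploidies.

## Pedigree expectations (A)

Pedigrees are three columns (individual, parent 1, parent 2); parent order
carries no information and unknown parents are coded `0`, `NA` or empty.
Records are deduplicated, parents that never appear as individuals are appended
as founders with a warning, and the table is reordered so parents precede
offspring. The reordering scans the remaining rows repeatedly in input order and
places each row as soon as both parents are placed; this makes the sort stable,
idempotent, and exactly reproducible when a pedigree is extended and rebuilt.
Self-parenting and ancestry cycles are rejected with an error naming one cycle
(an iterative fixer that never terminated would be strictly worse than a clear
error).

For diploids the classical tabular recursion applies:
`A[i,j] = 0.5 (A[s(i),j] + A[d(i),j])`, `A[i,i] = 1 + 0.5 A[s(i),d(i)]`,
with unknown parents contributing zero. For higher even ploidies we track
`alpha_i`, the probability that two *distinct* homologous alleles of individual
`i` are identical by descent (IBD), and a per-gamete quantity `gamma`, the
probability that two distinct alleles of a transmitted gamete are IBD. A gamete
of `v = m/2` alleles is modelled as `floor(v/2)` allele pairs plus a uniform
singleton when `v` is odd: with probability `w` (the **double-reduction
fraction**, a consequence of multivalent pairing in autopolyploids) a pair
carries two copies of one uniformly chosen parental allele; otherwise it carries
two distinct parental alleles drawn without replacement; pairs are independent.
The exact expectation of that generative model is

```
gamma_p  = [ npair (w + (1-w) alpha_p) + (C(v,2) - npair) A[p,p]/m ] / C(v,2)
alpha_i  = [ C(v,2) (gamma_s + gamma_d) + v^2 A[s,d]/m ] / C(m,2)
A[i,i]   = 1 + (m-1) alpha_i,   A[i,j] = 0.5 (A[s,j] + A[d,j])
```

which collapses to the tabular method at `m = 2` and reproduces the textbook
result that a selfed non-inbred tetraploid has `F = alpha = 1/6` at `w = 0`
(diagonal 1.5) and `F = (2w+1)/6` in general. Unknown parents transmit fresh,
mutually non-IBD alleles, so the unknown x unknown diagonal is exactly 1 at
every ploidy and every `w`. Double reduction is the probability of a duplicated
*allele pair* per transmitted pair event; for tetraploids this coincides with
the usual "fraction of gametes carrying two copies of one parental allele". For
ploidies above 4 the literature does not pin down a unique convention; this
pairwise formalization is the package's normative choice, and the gene-dropping
engine below implements the identical model, so the recursion and the simulator
cannot drift apart.

The `slater = TRUE` variant exposes the alternative autopolyploid pedigree
construction behind the same signature. Its original closed form is defined in
literature this package deliberately does not re-derive; here the variant is
the same gamete-transmission recursion with double reduction fixed at 0 (it
takes no `w`, and `w != 0` is an error). Users needing the historically exact
variant coefficients should treat this as a documented stand-in.

The diploid pedigree **dominance** matrix uses
`D[i,j] = 0.25 (A[s_i,s_j] A[d_i,d_j] + A[s_i,d_j] A[d_i,s_j])` with unit
diagonal; it assumes non-inbred individuals (the classical closed form, exact
for outbred pedigrees) and is defined for diploids only.

`Amatrix()` fills the matrix in compiled code: one `O(N^2)` pass, one row
against all previous columns, no recursion depth limits. A 20,000-individual
pedigree builds in seconds in about 3.2 GB (the matrix itself); for matrices
above 2,000 individuals the constructor skips the redundant `O(N^2)` symmetry
re-check since the fill writes both triangles. `expand_Amatrix()` appends new
crosses by computing only the new rows (the per-individual `alpha` values are
stored on the matrix), and equals a full rebuild exactly because it executes
the same kernel on the same prefix.

### Non-deterministic (polycross) pedigrees

`Amatrix_polycross()` handles bulk-harvested offspring whose parents are known
only as a candidate set, in a wide table (column 1 = id, remaining columns =
possible parents; with `fixed = TRUE` column 2 is the known mother). The
expected relationship averages the tabular recursion over equally likely draws
of two distinct parents from the candidate set: an offspring's row is the mean
of its candidates' rows (`1/|C|` to each unrelated non-inbred candidate, e.g.
1/3 for a group of three), or `0.5` x mother + `0.5/n` x each of `n` pollen
donors when the mother is fixed. Candidates are drawn without replacement (no
accidental selfing) and all diagonals are set to 1 — the construction assumes
no inbreeding, which is the regime where the averaging argument is exact. A
"group" of one candidate is simply a deterministic single-parent record, so
under this interface a malformed group with fewer than two candidates cannot
be expressed.

## Marker QC

Dosage matrices are individuals x markers with integer values `0..m` (exactly
`m + 1` genotype classes; violations are reported with marker and individual).
`marker_stats()` computes, over observed entries only: reference-allele
frequency `p` (mean dosage / m), `maf`, call rate, observed heterozygosity
(dosages not in `{0, m}`) and a monomorphic flag. `filter_markers()` drops a
marker iff `maf < maf_min`, `call_rate < callrate_min`, `het_obs > het_max`
(an upper bound, aimed at inbred breeding lines; a lower bound is exposed but
defaults to 0), or monomorphic when requested; markers with no observed calls
are always dropped. Individuals are never dropped. `impute_markers()` fills
missing entries by column mean (real-valued dosages, accepted by every G
construction) or mode (ties toward the smaller dosage, for determinism).
G construction itself requires a complete matrix: missing entries there are a
hard error rather than a silent pairwise adjustment, because pairwise handling
changes the normalization invisibly.

## Realized relationships (G)

All parametrizations estimate allele frequencies from the supplied matrix
itself. With `Z = M - mP` and `p_k` the sample frequency:

| method | formula (denominator) | scope |
|---|---|---|
| `g_vanraden` | `ZZ' / (m Σ p_k q_k)` | any even m |
| `g_weighted` (Liu) | `Z diag(d) Z' / (m Σ d_k p_k q_k)` | any even m, `d >= 0` caller-supplied |
| `g_yang` | per-marker standardized; diagonal `1 + (x² - (1+2p)x + 2p²)/(2pq)` averaged | diploid |
| `g_dominance_su` | heterozygosity coding `(H - 2PQ)(H - 2PQ)' / Σ 2pq(1-2pq)` | diploid |
| `g_dominance_vitezica` | `(-2q², 2pq, -2p²)` coding `/ Σ (2pq)²` | diploid |
| `g_endelman` | digenic covariate `C(m,2)p² - (m-1)px + C(x,2)`, exact Binomial `E[c²]` denominator | any even m |
| `g_slater_full` | centered dosage-class indicators `/ Σ_kc f(1-f)` | even m >= 4 |
| `g_pseudo_diploid` | recode `0 -> 0, m -> 2, else 1`, then diploid VanRaden | even m >= 4 |
| `g_ratio` | `(R-P)(R-P)' / Σ p(1-p)` on `[0,1]` ratios | any |

Numerical conventions worth knowing:

* Zero-variance (constant) marker columns are excluded from both numerator and
  denominator in the VanRaden family (`vanraden`, `weighted`, `ratio`, and the
  second stage of `pseudo_diploid`). A constant intermediate dosage has
  `p(1-p) > 0` but carries no relationship information; including it would
  deflate every entry. The marker count actually used is recorded in the
  matrix metadata, along with the denominator value.
* `g_ratio` of hard dosages passed as `x/m` equals `g_vanraden / m`; the factor
  `m` is recorded as `dosage_scale_factor` in the metadata rather than silently
  rescaled, since ratio inputs (genotype probabilities, read-depth ratios,
  mixed-ploidy panels, family pools) have no unique dosage scale.
* The diploid Endelman digenic matrix equals the Vitezica matrix exactly
  (`c = -w/2` and `E[c²] = (2pq)²/4` under the Binomial), which the tests pin
  to 1e-10.
* Yang's diagonal is an inbreeding estimator, not the Gram diagonal, so the
  matrix is symmetric but not guaranteed positive semidefinite at small marker
  counts; every Gram-form construction is PSD by construction.
* Sample-estimated frequencies make rows and columns of the centered
  constructions sum to zero; under Hardy-Weinberg simulation mean diagonals are
  close to 1 (the suite checks 1 +/- 0.05 at n = 500 individuals and 5,000 to
  10,000 markers).

Legal method x ploidy combinations are enforced by `Gmatrix()` and enumerated
by `method_grid()`, which lists the 15 supported constructions (4 pedigree,
9 genomic, 2 blended).

## Single-step blends (H)

Given A over everyone and G over the genotyped subset (matched by labels),
`Hmatrix(method = "Martini")` computes
`H22 = (tau G^-1 + (1-omega) A22^-1)^-1` and propagates the update
`Delta = H22 - A22` through the pedigree blocks. `tau = omega = 1` is the plain
single-step matrix; the limits `G = A22 -> H = A` and
"everyone genotyped `-> H = G`" hold to 1e-10 and are tested. G is bent
automatically (diagonal jitter, `eps = 1e-8`, with a warning) if it is not
positive definite, since `G^-1` is required. A grid helper over `(tau, omega)`
is provided; choosing the factors by cross-validation is downstream work.

`method = "Munoz"` shrinks G toward A within relationship classes: genotyped
pairs are grouped by their pedigree value (rounded at 1e-6 — pedigree
expectations are a small discrete set, so the rounding merely guards against
floating-point noise), and class `c` moves `b_c` of the way from A to G. The
default `b_c = max(0, 1 - s²_sampling / s²_class)` needs a caller-supplied
sampling variance; with the default of 0 no shrinkage is applied (`b_c = 1`),
and per-class overrides make any estimator of `b_c` usable. Singleton classes
fall back to `b_c = 1` with a warning. Output entries on the genotyped block
always lie between the corresponding A and G entries when `0 <= b_c <= 1`.

`ensure_positive_definite()` offers minimal diagonal jitter (smallest constant
making `lambda_min >= eps`) and eigenvalue clipping (floors the spectrum at
`eps`, preserving eigenvectors); `invert_relmat()` verifies
`max |M M^-1 - I| < 1e-6` and can bend first.

## The gene-dropping oracle and the synthetic-data generator

`gene_drop()` transmits uniquely labelled founder alleles through the pedigree
at independent loci using *exactly* the gamete model of the A recursion and
reports per-entry means and Monte-Carlo standard errors of
`m x P(two alleles drawn with replacement, one from each individual, are IBD)`.
It is the package's semantic ground truth: the closed-form A must agree with it
within Monte-Carlo error, and the suite verifies this on random pedigrees at
ploidies 2 and 4 (including `w > 0`). Some entries are exactly deterministic —
unrelated pairs share no labels, a diploid parent-offspring pair shares exactly
one allele per locus — so their standard errors are 0 and the agreement is
exact. For the stochastic entries the deviation/SE ratios are standard normal;
across thousands of entries individual ratios above 3 occur at the expected
~0.3% rate, so the suite's calibrated bound is 4.5 SE plus a 1e-3 floor, chosen
a priori to keep the familywise false-alarm rate around 1e-4 while still
detecting any real bias an order of magnitude smaller than the quantities of
interest.

`simulate_pedigree()` generates a founder panel plus constant-size generations
(parent pairs from the previous generation, configurable selfing probability,
`offspring_per_cross` full sibs per drawn pair); `simulate_markers()` drops
biallelic founder alleles (frequencies from a caller-supplied distribution,
default Uniform(0.1, 0.9)) through the same transmission engine, yielding
dosages, optional Bernoulli missingness, and optional Beta-distributed
read-ratio observations `rbeta(depth·x/m + 1, depth·(1-x/m) + 1)` emulating
allele counts at finite depth (default depth 25, a typical GBS coverage).
Loci are unlinked; the generator reproduces expectations, founder allele
frequencies, and IBD structure of real data but not linkage disequilibrium,
genotyping-error structure, or selection, so passing tests validate the
expectation semantics, not LD-dependent behaviour.

Problem sizes used by the suite were chosen as realistic desk-scale designs:
20 random pedigrees of 36 individuals (12 founders, two generations, 10%
selfing) at 100,000 loci for the oracle comparison; a 60-founder, one-generation
population of N = 120 with 20,000 markers for the pedigree-genomic consistency
check. The latter shape matters scientifically: VanRaden G is centered with
sample-estimated allele frequencies, so it differs from A by a systematic term
that grows with mean relatedness and does not shrink with marker count. For a
founder panel plus one progeny generation the mean absolute difference is about
0.025; for deep, inbred pedigrees it can exceed 0.1 even with perfect data.
"G tracks A" is therefore a statement about populations whose mean relatedness
is low — exactly the genomic-selection training sets the check emulates.

## Known limitations

* No sparse `A^-1` construction (Henderson's rules) — inverses are dense and
  numerical, via `invert_relmat()`.
* Dominance pedigree matrices assume non-inbred individuals; dominance is not
  defined here for ploidy > 2 from pedigree (marker-based dominance via
  `g_endelman` covers autopolyploids).
* The Munoz class-shrinkage estimator for `b_c` is interface-complete but the
  sampling-variance term must come from the caller.
* Allele frequencies cannot yet be supplied externally to the G constructions;
  the metadata records what was estimated to keep that door open.
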