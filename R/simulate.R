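#' Configuration for synthetic pedigree / marker simulation
#'
#' Bundles the generator settings: population design (founders, generations,
#' offspring per cross, selfing probability), genetic model (ploidy, double
#' reduction), marker model (number of loci, founder allele-frequency
#' distribution, missing rate) and the mandatory seed.
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations number of non-founder generations.
#' @param offspring_per_cross offspring sharing each drawn parent pair.
#' @param selfing_probability probability a cross is a selfing event.
#' @param ploidy even integer ploidy.
#' @param w expected double-reduction fraction.
#' @param n_loci number of loci for gene dropping / marker simulation.
#' @param p_fun function(k) drawing k founder reference-allele frequencies
#'   in (0, 1).
#' @param missing_rate Bernoulli masking rate for simulated dosages.
#' @param seed integer seed (mandatory, for reproducibility).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20, n_generations = 3, offspring_per_cross = 2,
                       selfing_probability = 0.05, ploidy = 2, w = 0,
                       n_loci = 10000, p_fun = function(k) runif(k, 0.1, 0.9),
                       missing_rate = 0, seed) {
  if (missing(seed) || is.null(seed))
    stop_parameter("sim_config requires an explicit seed")
  for (pr in c(selfing_probability, missing_rate, w))
    if (pr < 0 || pr > 1) stop_parameter("probabilities must lie in [0, 1]")
  if (n_founders < 2) stop_parameter("need at least 2 founders")
  if (ploidy %% 2 != 0 || ploidy < 2) stop_parameter("ploidy must be even, >= 2")
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 offspring_per_cross = as.integer(offspring_per_cross),
                 selfing_probability = selfing_probability,
                 ploidy = as.integer(ploidy), w = w,
                 n_loci = as.integer(n_loci), p_fun = p_fun,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random multi-generation pedigree
#'
#' Founders form generation 0; each later generation keeps the population
#' size constant. Parent pairs are drawn from the previous generation, each
#' pair producing `offspring_per_cross` offspring; with probability
#' `selfing_probability` a cross is a selfing (parent1 == parent2). The
#' result is acyclic by construction and deterministic under the seed.
#'
#' @param cfg a [sim_config()].
#' @return a `pedigree_table`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  founders <- sprintf("F%02d", seq_len(cfg$n_founders))
  df <- data.frame(id = founders, parent1 = NA_character_, parent2 = NA_character_,
                   stringsAsFactors = FALSE)
  prev <- founders
  for (g in seq_len(cfg$n_generations)) {
    n_off <- cfg$n_founders
    ids <- sprintf("G%d_%02d", g, seq_len(n_off))
    p1 <- character(n_off); p2 <- character(n_off)
    made <- 0L
    while (made < n_off) {
      if (runif(1) < cfg$selfing_probability || length(prev) < 2) {
        a <- sample(prev, 1); b <- a
      } else {
        ab <- sample(prev, 2); a <- ab[1]; b <- ab[2]
      }
      take <- min(cfg$offspring_per_cross, n_off - made)
      p1[made + seq_len(take)] <- a
      p2[made + seq_len(take)] <- b
      made <- made + take
    }
    df <- rbind(df, data.frame(id = ids, parent1 = p1, parent2 = p2,
                               stringsAsFactors = FALSE))
    prev <- ids
  }
  structure(df, appended_founders = 0L, unknown_codes = c("0", "NA", ""),
            class = c("pedigree_table", "data.frame"))
}

#' Gene-dropping Monte-Carlo estimate of realized relationships
#'
#' Transmits uniquely labelled founder alleles through the pedigree at
#' `n_loci` independent loci and measures realized identity-by-descent
#' sharing. A gamete of m/2 alleles is built from allele pairs: with
#' probability `w` a pair consists of two copies of one uniformly chosen
#' parental allele (double reduction), otherwise of two distinct parental
#' alleles drawn without replacement; for diploids the gamete is a single
#' uniform allele and `w` is ignored. Unknown parents contribute fresh,
#' mutually non-IBD alleles. The reported relationship is
#' `m * P(two alleles drawn with replacement, one from each individual, are
#' IBD)`, averaged over loci, so unrelated non-inbred founders score 0 with
#' each other and exactly 1 with themselves. This simulation is the
#' package's semantic oracle for [Amatrix()].
#'
#' @param pedigree anything accepted by [order_pedigree()].
#' @param ploidy even integer ploidy.
#' @param w double-reduction fraction in `[0, 1]`.
#' @param n_loci number of independent loci.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @return list with `est` (labelled realized relationship matrix), `se`
#'   (per-entry Monte-Carlo standard errors) and `n_loci`.
#' @export
gene_drop <- function(pedigree, ploidy = 2, w = 0, n_loci = 10000, seed = NULL) {
  op <- order_pedigree(pedigree)
  if (ploidy %% 2 != 0 || ploidy < 2)
    stop_parameter("gene_drop requires an even ploidy >= 2")
  if (w < 0 || w > 1) stop_parameter("w must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  res <- gene_drop_cpp(op$sire, op$dam, as.integer(ploidy), w, as.integer(n_loci))
  dimnames(res$est) <- list(op$labels, op$labels)
  dimnames(res$se) <- list(op$labels, op$labels)
  list(est = res$est, se = res$se, n_loci = as.integer(n_loci))
}

#' Simulate biallelic dosage markers through a pedigree
#'
#' Founder alleles are drawn as reference with per-marker frequency from
#' `p_fun` and dropped through the pedigree with the same transmission
#' engine as [gene_drop()] (including double reduction). Dosage = count of
#' reference alleles (0..ploidy). Entries are masked missing at
#' `missing_rate`; with `ratio = TRUE` a Beta-distributed read-ratio
#' observation around x/m is returned alongside
#' (`rbeta(depth * x/m + 1, depth * (1 - x/m) + 1)`, emulating allele
#' counts at finite read depth).
#'
#' @param pedigree anything accepted by [order_pedigree()].
#' @param n_markers number of markers.
#' @param ploidy,w transmission model, as in [gene_drop()].
#' @param p_fun function(k) drawing founder reference-allele frequencies.
#' @param missing_rate Bernoulli masking rate.
#' @param ratio also return a noisy allele-ratio matrix.
#' @param depth pseudo read depth governing the Beta noise concentration.
#' @param seed optional integer seed.
#' @return dosage matrix (individuals x markers), or
#'   `list(dosage, ratio)` when `ratio = TRUE`.
#' @export
simulate_markers <- function(pedigree, n_markers, ploidy = 2, w = 0,
                             p_fun = function(k) runif(k, 0.1, 0.9),
                             missing_rate = 0, ratio = FALSE, depth = 25,
                             seed = NULL) {
  op <- order_pedigree(pedigree)
  if (ploidy %% 2 != 0 || ploidy < 2)
    stop_parameter("simulate_markers requires an even ploidy >= 2")
  if (!is.null(seed)) set.seed(seed)
  p <- p_fun(n_markers)
  if (any(p <= 0 | p >= 1))
    stop_parameter("founder allele frequencies must lie strictly in (0, 1)")
  D <- sim_markers_cpp(op$sire, op$dam, as.integer(ploidy), w, p)
  dimnames(D) <- list(op$labels, sprintf("mk%05d", seq_len(n_markers)))
  R <- NULL
  if (ratio) {
    x <- as.vector(D) / ploidy
    R <- matrix(rbeta(length(x), depth * x + 1, depth * (1 - x) + 1),
                nrow(D), ncol(D), dimnames = dimnames(D))
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(length(D)) < missing_rate, nrow(D), ncol(D))
    D[mask] <- NA_integer_
    if (!is.null(R)) R[mask] <- NA_real_
  }
  if (ratio) list(dosage = D, ratio = R) else D
}
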