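# ---- realized (marker-based) relationship matrices ------------------------
#
# All constructions estimate allele frequencies from the supplied matrix
# itself and require a complete matrix: missing entries are a hard error
# (impute upstream), since silent pairwise handling would change the
# normalization invisibly.

check_complete <- function(M, what = "dosage") {
  if (anyNA(M))
    stop_validation(sprintf(
      "%s matrix contains missing values; filter and impute before building G", what))
  invisible(M)
}

g_freqs <- function(M, ploidy) colMeans(M) / ploidy

# zero-variance (constant) columns carry no relationship information and are
# excluded from both numerator and denominator in the VanRaden-family
# constructions, so that e.g. an all-simplex marker contributes nothing
zero_variance_cols <- function(M) {
  apply(M, 2, function(x) all(x == x[1]))
}

check_denominator <- function(denom, method) {
  if (!is.finite(denom) || denom <= 1e-12)
    stop_numeric(sprintf(
      "degenerate denominator in %s (all markers monomorphic?); nothing to scale by", method))
  denom
}

g_relmat <- function(G, labels, kind, ploidy, method, denom, K, extra = list()) {
  G <- (G + t(G)) / 2
  relmat(G, labels, kind = kind, ploidy = ploidy, method = method,
         params = c(list(denominator = denom, n_markers = K), extra))
}

#' VanRaden additive genomic relationship matrix (any even ploidy)
#'
#' `G = Z Z' / (m * sum_k p_k (1 - p_k))` with `Z = M - m P`, where
#' `p_k` is the sample reference-allele frequency (mean dosage / m). Rows
#' and columns sum to zero because frequencies are estimated from the
#' sample; under Hardy-Weinberg the mean diagonal is close to 1.
#'
#' @param M complete individuals x markers dosage matrix (values in
#'   `[0, ploidy]`; real values from mean imputation are accepted).
#' @param ploidy even integer ploidy m.
#' @return a [relmat] of kind `G_additive`.
#' @export
g_vanraden <- function(M, ploidy = 2) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, ploidy, allow_real = TRUE)
  labels <- rownames(M)
  M <- M[, !zero_variance_cols(M), drop = FALSE]
  if (ncol(M) == 0L)
    stop_numeric("degenerate denominator in g_vanraden: every marker is monomorphic")
  p <- g_freqs(M, ploidy)
  denom <- check_denominator(ploidy * sum(p * (1 - p)), "g_vanraden")
  Z <- sweep(M, 2, ploidy * p)
  g_relmat(tcrossprod(Z) / denom, labels, "G_additive", ploidy,
           "vanraden", denom, ncol(M))
}

#' Yang marker-standardized additive genomic relationship (diploid)
#'
#' Off-diagonals standardize each marker by its variance:
#' `G[i,j] = (1/K) sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k q_k)`; the
#' diagonal uses `1 + (1/K) sum_k (x^2 - (1 + 2 p) x + 2 p^2) / (2 p q)`,
#' which estimates `1 + F` and need not be close to 1 for any single
#' individual. Monomorphic markers must be filtered out first.
#'
#' @param M complete diploid dosage matrix (0/1/2).
#' @return a [relmat] of kind `G_additive`; the number of markers used is
#'   recorded in the params.
#' @export
g_yang <- function(M) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, 2, allow_real = TRUE)
  p <- g_freqs(M, 2)
  if (any(p <= 0 | p >= 1))
    stop_validation("g_yang requires polymorphic markers; filter monomorphic markers first")
  q <- 1 - p
  K <- ncol(M)
  W <- sweep(sweep(M, 2, 2 * p), 2, sqrt(2 * p * q), "/")
  G <- tcrossprod(W) / K
  num <- M^2 - sweep(M, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(M), K, byrow = TRUE)
  dg <- 1 + rowMeans(sweep(num, 2, 2 * p * q, "/"))
  diag(G) <- dg
  g_relmat(G, rownames(M), "G_additive", 2L, "yang", K, K)
}

#' Weighted (Liu) additive genomic relationship matrix
#'
#' `G = Z diag(d) Z' / (m * sum_k d_k p_k (1 - p_k))` with caller-supplied
#' non-negative per-marker weights `d`; with unit weights this is exactly
#' [g_vanraden()].
#'
#' @inheritParams g_vanraden
#' @param weights non-negative per-marker weights, length `ncol(M)`.
#' @export
g_weighted <- function(M, ploidy = 2, weights) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, ploidy, allow_real = TRUE)
  if (length(weights) != ncol(M))
    stop_parameter("weights must have one entry per marker")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop_parameter("marker weights must be non-negative")
  if (sum(weights) <= 0) stop_parameter("marker weights must not all be zero")
  labels <- rownames(M)
  keep <- !zero_variance_cols(M)
  M <- M[, keep, drop = FALSE]
  weights <- weights[keep]
  if (ncol(M) == 0L)
    stop_numeric("degenerate denominator in g_weighted: every marker is monomorphic")
  p <- g_freqs(M, ploidy)
  denom <- check_denominator(ploidy * sum(weights * p * (1 - p)), "g_weighted")
  Z <- sweep(M, 2, ploidy * p)
  Zw <- sweep(Z, 2, sqrt(weights), "*")
  g_relmat(tcrossprod(Zw) / denom, labels, "G_additive", ploidy,
           "liu_weighted", denom, ncol(M))
}

#' Su genotypic-dominance genomic relationship (diploid)
#'
#' Codes heterozygosity `h_ik = 1(x_ik == 1)` and centers by its
#' Hardy-Weinberg expectation:
#' `D = (H - 2PQ)(H - 2PQ)' / sum_k 2 p_k q_k (1 - 2 p_k q_k)`.
#'
#' @param M complete diploid dosage matrix with `0 < p_k < 1` for all
#'   markers.
#' @export
g_dominance_su <- function(M) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, 2, allow_real = TRUE)
  p <- g_freqs(M, 2)
  if (any(p <= 0 | p >= 1))
    stop_validation("g_dominance_su requires polymorphic markers; filter first")
  q <- 1 - p
  H <- (M == 1) * 1
  S <- sweep(H, 2, 2 * p * q)
  denom <- check_denominator(sum(2 * p * q * (1 - 2 * p * q)), "g_dominance_su")
  g_relmat(tcrossprod(S) / denom, rownames(M), "G_dominance", 2L, "su",
           denom, ncol(M))
}

#' Vitezica breeding-value-orthogonal dominance relationship (diploid)
#'
#' Dominance covariate `w`: `-2 q^2` for dosage 2, `2 p q` for dosage 1,
#' `-2 p^2` for dosage 0; `D = W W' / sum_k (2 p_k q_k)^2`. Invariant to
#' swapping which allele is counted.
#'
#' @inheritParams g_dominance_su
#' @export
g_dominance_vitezica <- function(M) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, 2)
  p <- g_freqs(M, 2)
  if (any(p <= 0 | p >= 1))
    stop_validation("g_dominance_vitezica requires polymorphic markers; filter first")
  q <- 1 - p
  n <- nrow(M)
  P <- matrix(p, n, ncol(M), byrow = TRUE)
  Q <- 1 - P
  W <- matrix(0, n, ncol(M), dimnames = dimnames(M))
  W[M == 0] <- (-2 * P^2)[M == 0]
  W[M == 1] <- (2 * P * Q)[M == 1]
  W[M == 2] <- (-2 * Q^2)[M == 2]
  denom <- check_denominator(sum((2 * p * q)^2), "g_dominance_vitezica")
  g_relmat(tcrossprod(W) / denom, rownames(M), "G_dominance", 2L, "vitezica",
           denom, ncol(M))
}

# exact E[c^2] for the digenic covariate under x ~ Binomial(m, p)
endelman_var <- function(p, m) {
  x <- 0:m
  vapply(p, function(pk) {
    ck <- choose(m, 2) * pk^2 - (m - 1) * pk * x + choose(x, 2)
    sum(dbinom(x, m, pk) * ck^2)
  }, numeric(1))
}

#' Endelman digenic-dominance genomic relationship (any even ploidy)
#'
#' Digenic covariate `c_ik = C(m,2) p_k^2 - (m-1) p_k x_ik + C(x_ik, 2)`,
#' which has expectation 0 under `x ~ Binomial(m, p_k)`;
#' `D = C C' / sum_k v_k` with `v_k = E[c^2]` evaluated as the exact finite
#' sum over dosages 0..m. For diploids this reduces algebraically to
#' [g_dominance_vitezica()].
#'
#' @inheritParams g_vanraden
#' @export
g_endelman <- function(M, ploidy = 2) {
  M <- as_marker_matrix(M); check_complete(M)
  validate_dosage(M, ploidy, allow_real = TRUE)
  m <- ploidy
  p <- g_freqs(M, m)
  Cc <- sweep(-(m - 1) * sweep(M, 2, p, "*"), 2, choose(m, 2) * p^2, "+") +
    M * (M - 1) / 2
  denom <- check_denominator(sum(endelman_var(p, m)), "g_endelman")
  g_relmat(tcrossprod(Cc) / denom, rownames(M), "G_dominance", m,
           "endelman", denom, ncol(M))
}

#' Full-autopolyploid genomic relationship (dosage-class indicators)
#'
#' Expands every marker into `m + 1` dosage-class indicator columns, centers
#' each indicator by its observed class frequency `f_kc`, and scales by the
#' total indicator variance:
#' `G = T T' / s`, `s = sum_k sum_c f_kc (1 - f_kc)`. Captures additive and
#' non-additive resemblance jointly; rows and columns sum to 0. Markers with
#' a single observed class contribute nothing.
#'
#' @param M complete dosage matrix, even ploidy >= 4.
#' @param ploidy even integer >= 4.
#' @return a [relmat] of kind `G_full`.
#' @export
g_slater_full <- function(M, ploidy) {
  M <- as_marker_matrix(M); check_complete(M)
  if (ploidy < 4) stop_parameter("the full-autopolyploid model requires even ploidy >= 4")
  validate_dosage(M, ploidy)
  n <- nrow(M)
  G <- matrix(0, n, n)
  s <- 0
  for (cls in 0:ploidy) {
    Ic <- (M == cls) * 1
    f <- colMeans(Ic)
    s <- s + sum(f * (1 - f))
    Tc <- sweep(Ic, 2, f)
    G <- G + tcrossprod(Tc)
  }
  s <- check_denominator(s, "g_slater_full")
  g_relmat(G / s, rownames(M), "G_full", ploidy, "slater_full", s, ncol(M))
}

#' Pseudo-diploid genomic relationship for autopolyploids
#'
#' Recodes dosages `0 -> 0`, `m -> 2`, every intermediate `-> 1`, then
#' applies the diploid [g_vanraden()] to the recoded matrix. Columns that
#' become constant (e.g. all-simplex markers) contribute nothing.
#'
#' @inheritParams g_slater_full
#' @export
g_pseudo_diploid <- function(M, ploidy) {
  M <- as_marker_matrix(M); check_complete(M)
  if (ploidy < 4) stop_parameter("the pseudo-diploid model requires even ploidy >= 4")
  validate_dosage(M, ploidy)
  R <- matrix(1, nrow(M), ncol(M), dimnames = dimnames(M))
  R[M == 0] <- 0
  R[M == ploidy] <- 2
  out <- g_vanraden(R, 2)
  attr(out, "method") <- "pseudo_diploid"
  attr(out, "params") <- c(rel_params(out),
                           list(recode = c(`0` = 0, intermediate = 1, m = 2),
                                source_ploidy = ploidy))
  out
}

#' Additive genomic relationship from continuous allele ratios
#'
#' For markers scored continuously in `[0, 1]` (genotype probabilities,
#' read-depth allele ratios, mixed-ploidy panels, family pools):
#' `p_k` = column mean ratio, `Z = R - P`,
#' `G = Z Z' / sum_k p_k (1 - p_k)`. If integer dosages are passed as
#' `x/m`, the result equals [g_vanraden()] divided by m; the scale factor to
#' the dosage parametrization is recorded in the params rather than silently
#' rescaled.
#'
#' @param R complete ratio matrix, values in `[0, 1]`.
#' @param ploidy nominal ploidy, recorded in metadata (the computation is
#'   scale-free in m).
#' @export
g_ratio <- function(R, ploidy = 2) {
  R <- as_marker_matrix(R); check_complete(R, "ratio")
  if (any(R < 0 | R > 1))
    stop_validation("ratio matrix values must lie in [0, 1]")
  labels <- rownames(R)
  R <- R[, !zero_variance_cols(R), drop = FALSE]
  if (ncol(R) == 0L)
    stop_numeric("degenerate denominator in g_ratio: every marker is constant")
  p <- colMeans(R)
  denom <- check_denominator(sum(p * (1 - p)), "g_ratio")
  Z <- sweep(R, 2, p)
  g_relmat(tcrossprod(Z) / denom, labels, "G_additive", ploidy,
           "vanraden_ratio", denom, ncol(R),
           extra = list(dosage_scale_factor = ploidy))
}

#' Genomic relationship matrix front end
#'
#' Dispatches to the individual constructions, enforcing the legal
#' method x ploidy combinations (Yang, Su and Vitezica are diploid-only;
#' Slater, PseudoDiploid and Endelman need even ploidy >= 4; VanRaden and
#' Liu accept any even ploidy; `ratio = TRUE` pairs with VanRaden).
#'
#' @param M complete dosage (or, with `ratio = TRUE`, ratio) matrix.
#' @param method one of `"VanRaden"`, `"Yang"`, `"Liu"`, `"Su"`,
#'   `"Vitezica"`, `"Slater"`, `"PseudoDiploid"`, `"Endelman"`.
#' @param ploidy even integer ploidy.
#' @param ratio treat `M` as a `[0, 1]` ratio matrix (VanRaden only).
#' @param weights per-marker weights (Liu only).
#' @return a [relmat].
#' @export
Gmatrix <- function(M, method = "VanRaden", ploidy = 2, ratio = FALSE,
                    weights = NULL) {
  methods <- c("VanRaden", "Yang", "Liu", "Su", "Vitezica", "Slater",
               "PseudoDiploid", "Endelman")
  method <- match.arg(method, methods)
  if (ploidy %% 2 != 0 || ploidy < 2)
    stop_parameter("ploidy must be an even integer >= 2")
  if (ratio && method != "VanRaden")
    stop_parameter("ratio = TRUE is available for method 'VanRaden' only")
  if (method %in% c("Yang", "Su", "Vitezica") && ploidy != 2)
    stop_validation(sprintf(
      "method '%s' is defined for diploids only; legal combinations are listed by method_grid()",
      method))
  if (method %in% c("Slater", "PseudoDiploid", "Endelman") && ploidy < 4)
    stop_validation(sprintf(
      "method '%s' requires even ploidy >= 4; legal combinations are listed by method_grid()",
      method))
  switch(method,
         VanRaden = if (ratio) g_ratio(M, ploidy) else g_vanraden(M, ploidy),
         Yang = g_yang(M),
         Liu = {
           if (is.null(weights)) stop_parameter("method 'Liu' needs per-marker weights")
           g_weighted(M, ploidy, weights)
         },
         Su = g_dominance_su(M),
         Vitezica = g_dominance_vitezica(M),
         Slater = g_slater_full(M, ploidy),
         PseudoDiploid = g_pseudo_diploid(M, ploidy),
         Endelman = g_endelman(M, ploidy))
}
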