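#' Pedigree-expectation (numerator) relationship matrix
#'
#' Builds the expected additive relationship matrix **A** from a pedigree by
#' the tabular recursion, for any even ploidy. For diploids this is the
#' classical method (founder diagonal 1, offspring diagonal 1 + F); for
#' autopolyploids the recursion accounts for double reduction through the
#' fraction `w`, the probability that a transmitted allele pair within a
#' gamete consists of two copies of a single parental allele. The matrix is
#' reported on the normalized scale where non-inbred founders have diagonal
#' exactly 1, so entries are directly comparable across ploidies. With
#' `dominance = TRUE` (diploids only) the pedigree dominance relationship
#' matrix is returned instead:
#' `D[i,j] = 0.25 (A[si,sj] A[di,dj] + A[si,dj] A[di,sj])`, diagonal 1.
#'
#' The `slater = TRUE` variant exposes the alternative autopolyploid
#' construction behind the same signature; in this package its semantics are
#' the same gamete-transmission recursion with double reduction fixed at 0
#' (the variant takes no `w`); see the methods vignette for the rationale.
#'
#' @param pedigree anything accepted by [order_pedigree()].
#' @param ploidy even integer >= 2.
#' @param w expected double-reduction fraction in `[0, 1]`; ignored for
#'   diploids (a one-allele gamete cannot carry a duplicated pair).
#' @param dominance build the diploid pedigree dominance matrix.
#' @param slater use the alternative polyploid variant (even ploidy >= 4,
#'   `w` must be 0).
#' @return a [relmat] of kind `A_additive` (or `A_dominance`), with the
#'   per-individual probability that two distinct alleles are IBD stored in
#'   attribute `alpha`.
#' @examples
#' ped <- data.frame(id = c("A", "B", "C"), p1 = c(0, 0, "A"), p2 = c(0, 0, "B"))
#' Amatrix(ped)
#' Amatrix(ped, ploidy = 4, w = 0.1)
#' @export
Amatrix <- function(pedigree, ploidy = 2, w = 0, dominance = FALSE, slater = FALSE) {
  op <- order_pedigree(pedigree)
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L || ploidy %% 2L != 0L)
    stop_parameter(sprintf("ploidy must be an even integer >= 2 (got %s)", ploidy))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop_parameter("double-reduction fraction w must be a single value in [0, 1]")
  if (slater) {
    if (w != 0) stop_parameter("the slater variant does not take a double-reduction fraction (w must be 0)")
    if (ploidy < 4L) stop_parameter("the slater variant is defined for even ploidy >= 4")
  }
  if (dominance && ploidy != 2L)
    stop_parameter("the pedigree dominance matrix is defined for diploids only")
  if (dominance && slater)
    stop_parameter("dominance and slater options are mutually exclusive")

  fit <- amatrix_kernel_cpp(op$sire, op$dam, ploidy, w)
  A <- fit$A
  if (dominance) {
    A0 <- rbind(0, cbind(0, A))  # row/col 1 = unknown parent (all zeros)
    s1 <- op$sire + 1L
    d1 <- op$dam + 1L
    D <- 0.25 * (A0[s1, s1, drop = FALSE] * A0[d1, d1, drop = FALSE] +
                 A0[s1, d1, drop = FALSE] * A0[d1, s1, drop = FALSE])
    diag(D) <- 1
    return(relmat(D, op$labels, kind = "A_dominance", ploidy = 2L,
                  method = "pedigree_dominance",
                  params = list(assumes_noninbred_diagonal = TRUE)))
  }
  meth <- if (slater) "slater" else if (ploidy == 2L) "tabular" else "kerr"
  pars <- list(w = if (slater || ploidy == 2L) 0 else w)
  alpha <- as.numeric(fit$alpha)
  if (op$n > 2000) {
    # set attributes in place: a function round trip would duplicate a
    # matrix this size (O(N^2) doubles)
    fit$A <- NULL
    dimnames(A) <- list(op$labels, op$labels)
    attr(A, "kind") <- "A_additive"
    attr(A, "ploidy") <- ploidy
    attr(A, "method") <- meth
    attr(A, "params") <- pars
    attr(A, "alpha") <- alpha
    class(A) <- c("relmat", "matrix", "array")
    return(A)
  }
  out <- relmat(A, op$labels, kind = "A_additive", ploidy = ploidy,
                method = meth, params = pars)
  attr(out, "alpha") <- alpha
  out
}

#' Inbreeding coefficients from an additive relationship matrix
#'
#' The inbreeding coefficient F is the probability that two distinct
#' homologous alleles of an individual are identical by descent. On the
#' normalized A scale the diagonal equals `1 + (m - 1) F`, so
#' `F = (diag(A) - 1) / (ploidy - 1)`; for diploids this is the familiar
#' `diag(A) - 1`.
#'
#' @param A a [relmat] of kind `A_additive`.
#' @return named numeric vector of F per individual (founders are 0).
#' @export
inbreeding_coef <- function(A) {
  if (!identical(rel_kind(A), "A_additive"))
    stop_parameter("inbreeding coefficients are defined for A_additive matrices")
  m <- rel_ploidy(A)
  F <- (diag(rel_values(A)) - 1) / (m - 1)
  names(F) <- rel_labels(A)
  F
}

#' Expand an existing A matrix with new pedigree records
#'
#' Adds new crosses to a previously built additive relationship matrix
#' without recomputing the existing block: only the new rows/columns are
#' filled, using the same recursion (and the stored per-individual IBD
#' probabilities), so the result equals a full rebuild from the concatenated
#' pedigree.
#'
#' @param A existing [relmat] of kind `A_additive`, built from `ped_old`.
#' @param ped_old the pedigree `A` was built from (anything accepted by
#'   [order_pedigree()]); its ordered labels must match `A`'s labels.
#' @param new data.frame of new records (id, parent1, parent2); parents must
#'   resolve within the old pedigree or `new` itself.
#' @return a [relmat] of kind `A_additive` over old + new individuals.
#' @export
expand_Amatrix <- function(A, ped_old, new) {
  if (!identical(rel_kind(A), "A_additive"))
    stop_parameter("expand_Amatrix requires an A_additive matrix")
  op <- order_pedigree(ped_old)
  if (!identical(op$labels, rel_labels(A)))
    stop_validation("labels of the existing matrix do not match the ordered old pedigree")
  if (is.null(new) || NROW(new) == 0L) return(A)
  op2 <- append_pedigree(op, new)
  m <- rel_ploidy(A)
  w <- rel_params(A)$w
  if (is.null(w)) w <- 0
  alpha <- attr(A, "alpha")
  if (is.null(alpha)) alpha <- (diag(rel_values(A)) - 1) / (m - 1)
  fit <- amatrix_kernel_cpp(op2$sire, op2$dam, m, w,
                            prefill = rel_values(A), prealpha = alpha)
  out <- relmat(fit$A, op2$labels, kind = "A_additive", ploidy = m,
                method = attr(A, "method"), params = rel_params(A),
                check = op2$n <= 2000)
  attr(out, "alpha") <- as.numeric(fit$alpha)
  out
}
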