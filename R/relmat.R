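#' Relationship-matrix container
#'
#' A `relmat` is a plain numeric matrix carrying the metadata every
#' relationship matrix in this package needs: individual labels as dimnames,
#' the matrix `kind` (pedigree additive/dominance, genomic, combined), the
#' ploidy it was built for, the construction method, and a free-form
#' parameter list (double-reduction fraction, normalizing denominator,
#' number of markers used, blending factors, ...).
#'
#' @param values square numeric matrix.
#' @param labels character vector of individual labels (row/column names).
#' @param kind one of `"A_additive"`, `"A_dominance"`, `"G_additive"`,
#'   `"G_dominance"`, `"G_full"`, `"H"`.
#' @param ploidy even integer ploidy the matrix refers to.
#' @param method construction method name.
#' @param params named list of construction metadata.
#' @param check verify symmetry (to 1e-10) and label uniqueness. Skipped
#'   automatically above 2000 individuals, where the fill routines are
#'   symmetric by construction.
#' @return a matrix of class `relmat`.
#' @export
relmat <- function(values, labels = rownames(values), kind, ploidy = 2L,
                   method = NULL, params = list(), check = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_validation("relationship matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop_validation("label count does not match matrix dimension")
  if (anyDuplicated(labels))
    stop_validation("individual labels must be unique")
  kinds <- c("A_additive", "A_dominance", "G_additive", "G_dominance", "G_full", "H")
  kind <- match.arg(kind, kinds)
  if (check && nrow(values) <= 2000 && nrow(values) > 0) {
    if (max(abs(values - t(values))) > 1e-10)
      stop_validation("relationship matrix is not symmetric (tolerance 1e-10)")
  }
  dimnames(values) <- list(labels, labels)
  structure(values,
            kind = kind, ploidy = as.integer(ploidy), method = method,
            params = params,
            class = c("relmat", class(values)))
}

#' @export
print.relmat <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<relmat> %s, %d x %d, ploidy %d%s\n",
              attr(x, "kind"), n, n, attr(x, "ploidy"),
              if (!is.null(attr(x, "method"))) paste0(", method ", attr(x, "method")) else ""))
  if (n > 0)
    cat(sprintf("  mean diagonal %.4f, range [%.4f, %.4f]\n",
                mean(diag(x)), min(x), max(x)))
  k <- min(n, 6L)
  if (k > 0) print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (n > k) cat(sprintf("  ... %d more individuals\n", n - k))
  invisible(x)
}

#' Individual labels of a relationship matrix
#' @param x a `relmat` (or any labelled matrix).
#' @return character vector of labels.
#' @export
rel_labels <- function(x) rownames(x)

rel_kind   <- function(x) attr(x, "kind")
rel_ploidy <- function(x) attr(x, "ploidy")
rel_params <- function(x) attr(x, "params")

# strip class/attrs for raw numeric work
rel_values <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}
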