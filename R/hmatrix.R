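# ---- single-step combined (H) relationship matrices -----------------------

# partition A's ordering into ungenotyped (1) / genotyped (2) by G's labels
genotyped_partition <- function(A, G) {
  la <- rel_labels(A)
  lg <- rel_labels(G)
  missing <- setdiff(lg, la)
  if (length(missing))
    stop_validation(sprintf("genotyped individual(s) absent from A: %s",
                            paste(utils::head(missing, 5), collapse = ", ")))
  idx2 <- which(la %in% lg)
  list(idx1 = setdiff(seq_along(la), idx2), idx2 = idx2,
       geno = la[idx2])
}

solve_block <- function(M, name) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out))
    stop_numeric(sprintf(
      "%s block is singular and cannot be inverted; consider ensure_positive_definite()",
      name))
  out
}

#' Single-step combined relationship matrix
#'
#' Merges a pedigree matrix **A** (all individuals) and a genomic matrix
#' **G** (genotyped subset, identified by `G`'s labels) into one coherent
#' matrix **H**.
#'
#' `method = "Martini"` uses scaling factors `tau` and `omega`: with A
#' partitioned into ungenotyped (1) and genotyped (2) blocks,
#' `H22 = (tau G^-1 + (1 - omega) A22^-1)^-1`, `Delta = H22 - A22`, and
#' `H = A + [[A12 A22^-1 Delta A22^-1 A21, A12 A22^-1 Delta],
#' [Delta A22^-1 A21, Delta]]`. `tau = omega = 1` gives the plain
#' single-step H (and `H = G` when everyone is genotyped). `G` is bent
#' (diagonal jitter, `eps = 1e-8`) before inversion if it is not positive
#' definite, with a warning.
#'
#' `method = "Munoz"` shrinks G toward A within relationship classes:
#' genotyped pairs are grouped by their A22 value (rounded to 1e-6), and
#' within class c `H22[i,j] = A22[i,j] + b_c (G[i,j] - A22[i,j])`. The
#' default `b_c = max(0, 1 - sampling_var / var_c)` uses the sample variance
#' `var_c` of the G entries in the class and a caller-supplied sampling
#' variance (default 0, i.e. `b_c = 1`); `shrink_overrides` (a single value
#' or a vector named by formatted class value) takes precedence. The
#' ungenotyped block and cross block are copied from A.
#'
#' @param A pedigree [relmat] covering all individuals.
#' @param G genomic [relmat] over the genotyped subset.
#' @param method `"Martini"` or `"Munoz"`.
#' @param tau,omega Martini scaling factors; `tau` must be > 0.
#' @param sampling_var Munoz within-class sampling variance term.
#' @param shrink_overrides Munoz per-class shrinkage in `[0, 1]`: scalar, or
#'   named by `sprintf("%.6f", class_value)`.
#' @param bend_eps eigenvalue floor used when G must be bent.
#' @return a [relmat] of kind `H` in A's label order.
#' @export
Hmatrix <- function(A, G, method = c("Martini", "Munoz"), tau = 1, omega = 1,
                    sampling_var = 0, shrink_overrides = NULL, bend_eps = 1e-8) {
  method <- match.arg(method)
  part <- genotyped_partition(A, G)
  Av <- rel_values(A)
  Gv <- rel_values(G)[part$geno, part$geno, drop = FALSE]  # align to A's order
  i1 <- part$idx1; i2 <- part$idx2
  A22 <- Av[i2, i2, drop = FALSE]

  if (method == "Martini") {
    if (!is.numeric(tau) || tau <= 0) stop_parameter("Martini blending requires tau > 0")
    ev <- min(eigen((Gv + t(Gv)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < bend_eps) {
      warning(sprintf("G is not positive definite (lambda_min = %.3g); bending with diagonal jitter", ev))
      Gv <- rel_values(ensure_positive_definite(
        relmat(Gv, rownames(Gv), kind = "G_additive", ploidy = rel_ploidy(G), check = FALSE),
        method = "diagonal_jitter", eps = bend_eps))
    }
    Ginv <- solve_block(Gv, "G")
    A22inv <- solve_block(A22, "A22")
    B <- tau * Ginv + (1 - omega) * A22inv
    H22 <- tryCatch(solve(B), error = function(e)
      stop_numeric("the Martini blend matrix tau*G^-1 + (1-omega)*A22^-1 is singular"))
    Delta <- H22 - A22
    H <- Av
    H[i2, i2] <- A22 + Delta
    if (length(i1)) {
      A12 <- Av[i1, i2, drop = FALSE]
      C12 <- A12 %*% A22inv
      H[i1, i2] <- A12 + C12 %*% Delta
      H[i2, i1] <- t(H[i1, i2, drop = FALSE])
      H[i1, i1] <- Av[i1, i1, drop = FALSE] + C12 %*% Delta %*% t(C12)
    }
    H <- (H + t(H)) / 2
    return(relmat(H, rel_labels(A), kind = "H", ploidy = rel_ploidy(A),
                  method = "martini", params = list(tau = tau, omega = omega)))
  }

  # Munoz per-class shrinkage
  cls_val <- round(A22, 6)
  keys <- sprintf("%.6f", cls_val[upper.tri(cls_val, diag = TRUE)])
  H22 <- A22
  ut <- which(upper.tri(A22, diag = TRUE), arr.ind = TRUE)
  dev <- Gv - A22
  b_used <- list()
  for (key in unique(keys)) {
    sel <- ut[keys == key, , drop = FALSE]
    g_entries <- Gv[sel]
    b <- NA_real_
    if (!is.null(shrink_overrides)) {
      if (length(shrink_overrides) == 1L && is.null(names(shrink_overrides)))
        b <- as.numeric(shrink_overrides)
      else if (key %in% names(shrink_overrides))
        b <- as.numeric(shrink_overrides[[key]])
    }
    if (is.na(b)) {
      if (nrow(sel) < 2L) {
        warning(sprintf("relationship class %s has a single pair; using b = 1", key))
        b <- 1
      } else if (sampling_var > 0) {
        v_class <- stats::var(g_entries)
        b <- if (v_class > 0) max(0, 1 - sampling_var / v_class) else 0
      } else b <- 1
    }
    if (b < 0 || b > 1) stop_parameter("shrinkage coefficients must lie in [0, 1]")
    b_used[[key]] <- b
    H22[sel] <- A22[sel] + b * dev[sel]
  }
  H22[lower.tri(H22)] <- t(H22)[lower.tri(H22)]
  H <- Av
  H[i2, i2] <- H22
  relmat(H, rel_labels(A), kind = "H", ploidy = rel_ploidy(A),
         method = "munoz",
         params = list(sampling_var = sampling_var, shrinkage = unlist(b_used)))
}

#' Bend a symmetric matrix to positive definiteness
#'
#' `diagonal_jitter` adds the minimal constant c to the diagonal so that
#' `lambda_min + c >= eps`; `eigen_clip` floors the eigenvalues at `eps` and
#' reconstructs (preserving the eigenvectors). A matrix already satisfying
#' `lambda_min >= eps` is returned unchanged.
#'
#' @param x a [relmat] (or symmetric labelled matrix).
#' @param method `"diagonal_jitter"` or `"eigen_clip"`.
#' @param eps target smallest eigenvalue.
#' @return a [relmat] with `lambda_min >= eps`; the bending method is
#'   recorded in the params.
#' @export
ensure_positive_definite <- function(x, method = c("diagonal_jitter", "eigen_clip"),
                                     eps = 1e-8) {
  method <- match.arg(method)
  kind <- if (inherits(x, "relmat")) rel_kind(x) else "G_additive"
  ploidy <- if (inherits(x, "relmat")) rel_ploidy(x) else 2L
  xm <- rel_values(if (inherits(x, "relmat")) x else
    relmat(x, rownames(x), kind = kind, ploidy = ploidy, check = FALSE))
  eg <- eigen((xm + t(xm)) / 2, symmetric = TRUE)
  lmin <- min(eg$values)
  if (lmin >= eps) return(if (inherits(x, "relmat")) x else
    relmat(xm, rownames(xm), kind = kind, ploidy = ploidy))
  if (method == "diagonal_jitter") {
    out <- xm + diag(eps - lmin, nrow(xm))
  } else {
    vals <- pmax(eg$values, eps)
    out <- eg$vectors %*% (vals * t(eg$vectors))
    out <- (out + t(out)) / 2
  }
  relmat(out, rownames(xm), kind = kind, ploidy = ploidy,
         method = if (inherits(x, "relmat")) attr(x, "method") else NULL,
         params = c(if (inherits(x, "relmat")) rel_params(x) else list(),
                    list(bending = method, bend_eps = eps, lambda_min_before = lmin)))
}

#' Grid of Martini blends over (tau, omega)
#'
#' Convenience helper returning the H matrix for every combination of the
#' supplied scaling factors; choosing among them (e.g. by cross-validated
#' predictive ability) is the caller's task.
#'
#' @inheritParams Hmatrix
#' @param tau_grid,omega_grid numeric vectors of candidate factors.
#' @return named list of [relmat]s, names `"tau=..,omega=.."`.
#' @export
Hmatrix_grid <- function(A, G, tau_grid = c(0.5, 1, 1.5),
                         omega_grid = c(0.5, 1), bend_eps = 1e-8) {
  out <- list()
  for (tau in tau_grid) for (omega in omega_grid) {
    out[[sprintf("tau=%g,omega=%g", tau, omega)]] <-
      Hmatrix(A, G, method = "Martini", tau = tau, omega = omega,
              bend_eps = bend_eps)
  }
  out
}
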