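make_AG <- function(seed = 1, n_geno = 4) {
  ped <- rand_ped(seed, n_founders = 4, gens = 2)
  A <- Amatrix(ped)
  labs <- rel_labels(A)
  geno <- utils::tail(labs, n_geno)
  A22 <- unclass(A)[geno, geno]
  list(A = A, geno = geno, A22 = A22)
}

test_that("Martini blending: consistency limits H = A and H = G", {
  fx <- make_AG(51)
  G_eq <- relmat(fx$A22, fx$geno, kind = "G_additive")
  H <- Hmatrix(fx$A, G_eq, method = "Martini", tau = 1, omega = 1)
  expect_lt(max(abs(unclass(H) - unclass(fx$A))), 1e-10)

  # everyone genotyped: H equals G
  labs <- rel_labels(fx$A)
  Gall <- unclass(fx$A) + diag(0.05, length(labs))
  Gall <- relmat(Gall, labs, kind = "G_additive")
  H2 <- Hmatrix(fx$A, Gall, method = "Martini", tau = 1, omega = 1)
  expect_lt(max(abs(unclass(H2) - unclass(Gall))), 1e-10)
})

test_that("Martini blending matches brute-force block arithmetic", {
  A <- Amatrix(ped_trio())
  G <- relmat(matrix(1.2, 1, 1), "C", kind = "G_additive")
  tau <- 0.8; omega <- 0.6
  H <- Hmatrix(A, G, method = "Martini", tau = tau, omega = omega)

  Av <- unclass(A)
  A22 <- Av["C", "C", drop = FALSE]
  A12 <- Av[c("A", "B"), "C", drop = FALSE]
  H22 <- solve(tau * solve(matrix(1.2, 1, 1)) + (1 - omega) * solve(A22))
  Delta <- H22 - A22
  Href <- Av
  Href["C", "C"] <- A22 + Delta
  Href[c("A", "B"), "C"] <- A12 + A12 %*% solve(A22) %*% Delta
  Href["C", c("A", "B")] <- t(Href[c("A", "B"), "C", drop = FALSE])
  Href[c("A", "B"), c("A", "B")] <- Av[c("A", "B"), c("A", "B")] +
    (A12 %*% solve(A22)) %*% Delta %*% t(A12 %*% solve(A22))
  expect_lt(max(abs(unclass(H) - Href)), 1e-10)
})

test_that("H varies continuously over a (tau, omega) grid without NaN/Inf", {
  fx <- make_AG(52)
  G <- relmat(fx$A22 + diag(0.1, length(fx$geno)), fx$geno, kind = "G_additive")
  grid <- Hmatrix_grid(fx$A, G, tau_grid = c(0.5, 1, 1.5), omega_grid = c(0.25, 1))
  expect_length(grid, 6L)
  for (H in grid) expect_true(all(is.finite(unclass(H))))
  # neighbouring grid points stay close
  d <- max(abs(unclass(grid[["tau=1,omega=1"]]) - unclass(grid[["tau=1,omega=0.25"]])))
  expect_lt(d, 1)
})

test_that("Munoz shrinkage: b = 0 returns A, b = 1 returns G, betweenness", {
  fx <- make_AG(53)
  set.seed(53)
  G <- relmat(fx$A22 + 0.05 * crossprod(matrix(rnorm(16), 4)), fx$geno,
              kind = "G_additive")
  H0 <- suppressWarnings(Hmatrix(fx$A, G, method = "Munoz", shrink_overrides = 0))
  expect_lt(max(abs(unclass(H0) - unclass(fx$A))), 1e-12)

  H1 <- suppressWarnings(Hmatrix(fx$A, G, method = "Munoz", shrink_overrides = 1))
  expect_lt(max(abs(unclass(H1)[fx$geno, fx$geno] - unclass(G))), 1e-12)
  ungeno <- setdiff(rel_labels(fx$A), fx$geno)
  expect_equal(unclass(H1)[ungeno, ], unclass(fx$A)[ungeno, ])

  Hb <- suppressWarnings(Hmatrix(fx$A, G, method = "Munoz", shrink_overrides = 0.4))
  lo <- pmin(unclass(fx$A)[fx$geno, fx$geno], unclass(G))
  hi <- pmax(unclass(fx$A)[fx$geno, fx$geno], unclass(G))
  Hg <- unclass(Hb)[fx$geno, fx$geno]
  expect_true(all(Hg >= lo - 1e-12 & Hg <= hi + 1e-12))

  expect_warning(Hmatrix(fx$A, G, method = "Munoz"), "single pair")
  expect_error(suppressWarnings(Hmatrix(fx$A, G, method = "Munoz",
                                        shrink_overrides = 2)),
               class = "kin_parameter_error")
})

test_that("bending reaches the eigenvalue floor by jitter or clipping", {
  X <- relmat(matrix(c(1, 1, 1, 1), 2, 2), c("a", "b"), kind = "G_additive")
  eps <- 1e-6
  J <- ensure_positive_definite(X, "diagonal_jitter", eps = eps)
  expect_equal(unclass(J), matrix(c(1 + eps, 1, 1, 1 + eps), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  Cp <- ensure_positive_definite(X, "eigen_clip", eps = eps)
  ev <- eigen(unclass(Cp), symmetric = TRUE)$values
  expect_equal(sort(ev), sort(c(2, eps)), tolerance = 1e-9)
  # dominant eigenvector is preserved
  v1 <- eigen(unclass(Cp), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(v1), rep(1 / sqrt(2), 2), tolerance = 1e-9)

  # already-PD input is returned unchanged
  P <- relmat(diag(2), c("a", "b"), kind = "G_additive")
  expect_identical(ensure_positive_definite(P, eps = 1e-8), P)

  for (m in c("diagonal_jitter", "eigen_clip")) {
    set.seed(4)
    S <- crossprod(matrix(rnorm(20), 4, 5)); S[1, 1] <- S[1, 1] - 10
    S <- (S + t(S)) / 2
    B <- ensure_positive_definite(relmat(S, letters[1:5], kind = "G_additive",
                                         check = FALSE), m, eps = 1e-6)
    expect_gte(min(eigen(unclass(B), symmetric = TRUE)$values), 1e-6 - 1e-9)
  }
})

test_that("singular blocks raise informative numeric errors", {
  fx <- make_AG(54)
  Gs <- relmat(matrix(1, 4, 4), fx$geno, kind = "G_additive")  # rank 1
  expect_warning(Hmatrix(fx$A, Gs, method = "Martini"), "bending")
  bad <- relmat(diag(4), c("zz", fx$geno[1:3]), kind = "G_additive")
  expect_error(Hmatrix(fx$A, bad, method = "Martini"),
               "absent from A", class = "kin_validation_error")
  expect_error(Hmatrix(fx$A, Gs, method = "Martini", tau = -1),
               class = "kin_parameter_error")
})
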