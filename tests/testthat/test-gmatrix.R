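test_that("VanRaden G matches the hand-computed single-marker example", {
  M <- cbind(m1 = c(0, 1, 2))
  rownames(M) <- c("a", "b", "c")
  G <- g_vanraden(M, 2)
  expect_equal(unclass(G),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3), ignore_attr = TRUE)
  expect_equal(rel_params(G)$denominator, 0.5)

  expect_error(g_vanraden(cbind(m1 = c(2, 2, 2)), 2), class = "kin_numeric_error")
  expect_error(g_vanraden(cbind(m1 = c(0, NA)), 2), class = "kin_validation_error")
})

test_that("Yang G: hand examples and non-unit diagonal", {
  M <- cbind(m1 = c(0, 2))
  G <- g_yang(M)
  expect_equal(G[1, 2], -2)
  expect_equal(unname(diag(unclass(G))), c(2, 2))

  # all-heterozygous individuals at p = 0.5: diagonal 1 + (1 - 2 + 0.5)/0.5 = 0
  G2 <- g_yang(cbind(m1 = c(1, 1, 0, 2)))  # p = 0.5
  expect_equal(unname(diag(unclass(G2))[1:2]), c(0, 0))

  expect_error(g_yang(cbind(m1 = c(2, 2))), "polymorphic",
               class = "kin_validation_error")
})

test_that("weighted G reduces to VanRaden and matches the brute-force oracle", {
  M <- rand_dosage(5, 6, 2, seed = 4)
  expect_rel_equal(g_weighted(M, 2, rep(1, 6)), g_vanraden(M, 2), 1e-12)

  d <- c(1, 1, 0, 0, 1, 0)
  expect_rel_equal(g_weighted(M, 2, d), g_vanraden(M[, d == 1], 2), 1e-12)

  set.seed(5)
  M2 <- rand_dosage(3, 2, 2, seed = 5)
  w <- runif(2)
  expect_rel_equal(g_weighted(M2, 2, w), bf_weighted(M2, 2, w))

  expect_error(g_weighted(M, 2, c(-1, rep(1, 5))), class = "kin_parameter_error")
  expect_error(g_weighted(M, 2, rep(1, 3)), class = "kin_parameter_error")
})

test_that("Su dominance: hand examples and brute-force equivalence", {
  M <- cbind(m1 = c(0, 1, 2))
  D <- g_dominance_su(M)
  expect_equal(D[2, 2], 1)

  # no heterozygotes at p = 0.5: every entry (2pq)^2-sum over denominator
  D2 <- g_dominance_su(cbind(m1 = c(0, 2)))
  expect_equal(unclass(D2), matrix(1, 2, 2), ignore_attr = TRUE)

  M3 <- rand_dosage(4, 3, 2, seed = 6)
  M3[1, ] <- 0; M3[2, ] <- 1; M3[3, ] <- 2  # keep every marker polymorphic
  expect_rel_equal(g_dominance_su(M3), bf_su(M3))
})

test_that("Vitezica dominance: hand example, allele-swap symmetry, brute force", {
  M <- cbind(m1 = c(0, 1, 2))
  D <- g_dominance_vitezica(M)
  expect_equal(D[1, 1], 1)

  M2 <- rand_dosage(5, 4, 2, seed = 7)
  expect_rel_equal(g_dominance_vitezica(M2), g_dominance_vitezica(2 - M2), 1e-10)
  expect_rel_equal(g_dominance_vitezica(M2), bf_vitezica(M2))
})

test_that("Endelman digenic: zero-mean covariate, diploid reduction, brute force", {
  # E[c] = 0 under x ~ Binomial(m, p)
  for (p in c(0.1, 0.5)) for (m in c(2, 4)) {
    x <- 0:m
    cx <- choose(m, 2) * p^2 - (m - 1) * p * x + choose(x, 2)
    expect_lt(abs(sum(dbinom(x, m, p) * cx)), 1e-12)
  }

  M2 <- rand_dosage(6, 5, 2, seed = 8)
  expect_rel_equal(g_endelman(M2, 2), g_dominance_vitezica(M2), 1e-10)

  M4 <- cbind(m1 = c(0, 2, 4))
  p <- mean(M4) / 4
  cc <- choose(4, 2) * p^2 - 3 * p * M4[, 1] + choose(M4[, 1], 2)
  expect_equal(unname(cc), c(1.5, -0.5, 1.5))
  M4b <- rand_dosage(5, 3, 4, seed = 9)
  expect_rel_equal(g_endelman(M4b, 4), bf_endelman(M4b, 4))
})

test_that("full-autopolyploid G: indicator expansion by hand and brute force", {
  M <- cbind(m1 = c(0, 4))
  G <- g_slater_full(M, 4)
  expect_equal(unclass(G), matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)
  expect_equal(rel_params(G)$denominator, 0.5)

  # identical genotype rows are indistinguishable
  M2 <- rand_dosage(4, 3, 4, seed = 10)
  M2[2, ] <- M2[1, ]
  G2 <- g_slater_full(M2, 4)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(G2[2, 2], G2[1, 1])

  M3 <- rand_dosage(5, 3, 4, seed = 11)
  expect_rel_equal(g_slater_full(M3, 4), bf_slater_full(M3, 4))
  expect_error(g_slater_full(cbind(m1 = rep(2, 4)), 4), class = "kin_numeric_error")
})

test_that("pseudo-diploid recodes 0/intermediate/m and composes with VanRaden", {
  M <- cbind(m1 = c(0, 2, 4), m2 = c(4, 1, 3))
  G <- g_pseudo_diploid(M, 4)
  R <- cbind(m1 = c(0, 1, 2), m2 = c(2, 1, 1))
  dimnames(R) <- dimnames(M)
  expect_rel_equal(G, g_vanraden(R, 2), 1e-12)

  # all-simplex column recodes to a constant and contributes nothing
  M2 <- cbind(M, simplex = c(1, 1, 1))
  expect_rel_equal(g_pseudo_diploid(M2, 4), G, 1e-12)
})

test_that("ratio G: hand example, proportionality to VanRaden, constant columns", {
  R <- cbind(m1 = c(0, 0.5, 1))
  G <- g_ratio(R, 2)
  expect_equal(unclass(G),
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3), ignore_attr = TRUE)

  M <- rand_dosage(6, 8, 4, seed = 12)
  Gr <- g_ratio(M / 4, 4)
  Gv <- g_vanraden(M, 4)
  expect_rel_equal(Gv, unclass(Gr) * attr(Gr, "params")$dosage_scale_factor, 1e-10)

  R2 <- cbind(m1 = c(0, 0.5, 1), flat = c(0.3, 0.3, 0.3))
  expect_rel_equal(g_ratio(R2, 2), G, 1e-12)
  expect_error(g_ratio(cbind(m1 = c(0, 1.2)), 2), class = "kin_validation_error")
})

test_that("brute-force oracle equivalence across all methods on random inputs", {
  M2 <- rand_dosage(6, 4, 2, seed = 13)
  expect_rel_equal(g_vanraden(M2, 2), bf_vanraden(M2, 2))
  expect_rel_equal(g_yang(M2), bf_yang(M2))
  expect_rel_equal(g_dominance_su(M2), bf_su(M2))
  expect_rel_equal(g_dominance_vitezica(M2), bf_vitezica(M2))
  M4 <- rand_dosage(6, 4, 4, seed = 14)
  expect_rel_equal(g_vanraden(M4, 4), bf_vanraden(M4, 4))
  expect_rel_equal(g_endelman(M4, 4), bf_endelman(M4, 4))
  expect_rel_equal(g_slater_full(M4, 4), bf_slater_full(M4, 4))
  R <- matrix(runif(24), 6, 4); dimnames(R) <- dimnames(M4)
  expect_rel_equal(g_ratio(R, 4), bf_ratio(R))
})

test_that("sample-estimated frequencies give zero row sums; duplication invariance", {
  M <- rand_dosage(8, 10, 4, seed = 15)
  for (G in list(g_vanraden(M, 4), g_weighted(M, 4, runif(10) + 0.1),
                 g_slater_full(M, 4), g_ratio(M / 4, 4)))
    expect_lt(max(abs(rowSums(unclass(G)))), 1e-8)

  # duplicating every marker column changes nothing
  Md <- cbind(M, M)
  expect_rel_equal(g_vanraden(Md, 4), g_vanraden(M, 4), 1e-10)
  expect_rel_equal(g_endelman(Md, 4), g_endelman(M, 4), 1e-10)
  expect_rel_equal(g_slater_full(Md, 4), g_slater_full(M, 4), 1e-10)
  M2 <- rand_dosage(6, 5, 2, seed = 16)
  expect_rel_equal(g_yang(cbind(M2, M2)), g_yang(M2), 1e-10)
})

test_that("symmetry and numerical PSD hold for every construction", {
  M2 <- rand_dosage(10, 12, 2, seed = 17)
  M4 <- rand_dosage(10, 12, 4, seed = 18)
  mats <- list(g_vanraden(M2, 2), g_dominance_su(M2),
               g_dominance_vitezica(M2), g_weighted(M2, 2, runif(12) + 0.1),
               g_vanraden(M4, 4), g_endelman(M4, 4), g_slater_full(M4, 4),
               g_pseudo_diploid(M4, 4), g_ratio(M4 / 4, 4))
  for (G in mats) {
    expect_lt(max(abs(unclass(G) - t(unclass(G)))), 1e-10)
    expect_gt(min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  # Yang replaces the Gram diagonal by an inbreeding estimator, so it is
  # symmetric but not guaranteed PSD at small marker counts
  GY <- g_yang(M2)
  expect_lt(max(abs(unclass(GY) - t(unclass(GY)))), 1e-10)
})

test_that("the Gmatrix front end enforces the legal method x ploidy grid", {
  M2 <- rand_dosage(5, 6, 2, seed = 19)
  expect_rel_equal(Gmatrix(M2, "VanRaden"), g_vanraden(M2, 2), 1e-12)
  expect_error(Gmatrix(rand_dosage(5, 6, 4, seed = 20), "Yang", ploidy = 4),
               "diploid", class = "kin_validation_error")
  expect_error(Gmatrix(M2, "Su", ploidy = 4), class = "kin_validation_error")
  expect_error(Gmatrix(M2, "Slater", ploidy = 2), class = "kin_validation_error")
  expect_error(Gmatrix(M2, "Liu"), class = "kin_parameter_error")  # weights missing
  expect_error(Gmatrix(M2, "Yang", ratio = TRUE), class = "kin_parameter_error")
})
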