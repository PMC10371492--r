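test_that("diploid additive A reproduces the tabular method by hand", {
  A <- Amatrix(data.frame(id = c("A", "B"), p1 = c("0", "0"), p2 = c("0", "0")))
  expect_equal(unclass(A), diag(2), ignore_attr = TRUE)

  A <- Amatrix(ped_trio())
  expect_equal(A["C", "A"], 0.5)
  expect_equal(A["C", "C"], 1.0)

  A <- Amatrix(ped_selfed())
  expect_equal(A["S", "S"], 1.5)
  expect_equal(A["S", "A"], 1.0)
})

test_that("inbreeding coefficients follow the diagonal", {
  A <- Amatrix(ped_fullsib_mating())
  F <- inbreeding_coef(A)
  expect_equal(unname(F[c("A", "B")]), c(0, 0))
  expect_equal(unname(F["X"]), 0.25)   # full-sib mating
  expect_equal(unname(inbreeding_coef(Amatrix(ped_selfed()))["S"]), 0.5)
})

test_that("pedigree dominance matrix: founders, full sibs, half sibs", {
  D <- Amatrix(data.frame(id = c("A", "B"), p1 = "0", p2 = "0"), dominance = TRUE)
  expect_equal(unclass(D), diag(2), ignore_attr = TRUE)

  ped <- data.frame(id = c("A", "B", "C", "S1", "S2", "H"),
                    p1 = c("0", "0", "0", "A", "A", "A"),
                    p2 = c("0", "0", "0", "B", "B", "C"))
  D <- Amatrix(ped, dominance = TRUE)
  expect_equal(D["S1", "S2"], 0.25)  # full sibs share both parental pairs
  expect_equal(D["S1", "H"], 0)      # half sibs share one parent only
  expect_equal(unname(diag(D)), rep(1, 6))
})

test_that("polyploid A: diploid reduction, founder normalization, parameter errors", {
  ped <- rand_ped(3)
  expect_lt(max(abs(Amatrix(ped) - Amatrix(ped, ploidy = 2, w = 0.9))), 1e-12)

  A4 <- Amatrix(data.frame(id = c("A", "B"), p1 = "0", p2 = "0"), ploidy = 4)
  expect_equal(unclass(A4), diag(2), ignore_attr = TRUE)

  expect_error(Amatrix(ped, ploidy = 3), class = "kin_parameter_error")
  expect_error(Amatrix(ped, ploidy = 4, w = 1.2), class = "kin_parameter_error")
  expect_error(Amatrix(ped, ploidy = 4, w = 0.1, slater = TRUE),
               class = "kin_parameter_error")
  expect_error(Amatrix(ped, ploidy = 2, slater = TRUE), class = "kin_parameter_error")
  expect_error(Amatrix(ped, ploidy = 4, dominance = TRUE), class = "kin_parameter_error")
})

test_that("tetraploid selfing: closed-form diagonals and monotonicity in w", {
  # alpha(self of non-inbred founder) = (2w + 1)/6, diagonal 1 + 3 alpha
  for (w in c(0, 0.1, 0.25))
    expect_equal(Amatrix(ped_selfed(), ploidy = 4, w = w)["S", "S"],
                 1 + (2 * w + 1) / 2)

  ped <- ped_fullsib_mating()
  grid <- seq(0, 0.25, by = 0.05)
  diags <- sapply(grid, function(w) diag(unclass(Amatrix(ped, ploidy = 4, w = w))))
  expect_true(all(diff(t(diags)) >= -1e-12))  # every diagonal non-decreasing in w
})

test_that("slater variant builds a valid tetraploid A without double reduction", {
  ped <- rand_ped(5)
  As <- Amatrix(ped, ploidy = 4, slater = TRUE)
  expect_equal(attr(As, "method"), "slater")
  expect_lt(max(abs(As - Amatrix(ped, ploidy = 4, w = 0))), 1e-12)
})

test_that("A matrices are numerically PSD with unit founder diagonals", {
  for (s in c(21, 22, 23)) {
    ped <- rand_ped(s)
    for (m in c(2, 4)) {
      A <- Amatrix(ped, ploidy = m, w = 0.05 * (m > 2))
      expect_gt(min(eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values),
                -1e-8)
      op <- order_pedigree(ped)
      founders <- op$labels[op$sire == 0 & op$dam == 0]
      expect_equal(unname(diag(unclass(A))[match(founders, rel_labels(A))]),
                   rep(1, length(founders)))
    }
  }
})

test_that("polycross expectations: bulk groups, fixed parents, pair groups", {
  ped3 <- data.frame(id = c("P1", "P2", "P3", "bulk"),
                     a = c("0", "0", "0", "P1"), b = c("0", "0", "0", "P2"),
                     c = c("0", "0", "0", "P3"))
  A <- Amatrix_polycross(ped3)
  expect_equal(unname(A["bulk", c("P1", "P2", "P3")]), rep(1 / 3, 3))
  expect_equal(A["bulk", "bulk"], 1)

  pedf <- data.frame(id = c("M", "D1", "D2", "off"),
                     a = c("0", "0", "0", "M"), b = c("0", "0", "0", "D1"),
                     c = c("0", "0", "0", "D2"))
  Af <- Amatrix_polycross(pedf, fixed = TRUE)
  expect_equal(Af["off", "M"], 0.5)
  expect_equal(unname(Af["off", c("D1", "D2")]), c(0.25, 0.25))

  # two-candidate group coincides with the deterministic cross
  ped2 <- data.frame(id = c("A", "B", "C"), a = c("0", "0", "A"),
                     b = c("0", "0", "B"))
  A2 <- Amatrix_polycross(ped2)
  expect_equal(unclass(A2)[c("A", "B", "C"), c("A", "B", "C")],
               unclass(Amatrix(ped_trio()))[c("A", "B", "C"), c("A", "B", "C")])

  expect_error(Amatrix_polycross(data.frame(id = c("M", "off"),
                                            a = c("0", "M"), b = c("0", "M")),
                                 fixed = TRUE),
               class = "kin_validation_error")
})

test_that("expand_Amatrix adds rows without touching the existing block", {
  ped2 <- data.frame(id = c("A", "B"), p1 = "0", p2 = "0")
  A2 <- Amatrix(ped2)
  expect_identical(expand_Amatrix(A2, ped2, NULL), A2)

  A3 <- expand_Amatrix(A2, ped2, data.frame(id = "C", p1 = "A", p2 = "B"))
  expect_equal(unname(A3["C", ]), c(0.5, 0.5, 1.0))

  expect_error(expand_Amatrix(A2, ped_trio(), data.frame(id = "D", p1 = "A", p2 = "B")),
               class = "kin_validation_error")
})

test_that("expanding equals rebuilding from the concatenated pedigree", {
  for (s in c(31, 32)) {
    ped <- rand_ped(s, n_founders = 10, gens = 3)
    op <- order_pedigree(ped)
    full <- as.data.frame(op)
    set.seed(s)
    cut <- sample(seq(10, op$n - 1), 1)
    old <- full[seq_len(cut), ]
    new <- full[-seq_len(cut), ]
    for (m in c(2, 4)) {
      A_old <- Amatrix(old, ploidy = m, w = 0.1 * (m > 2))
      A_exp <- expand_Amatrix(A_old, old, new)
      A_all <- Amatrix(full, ploidy = m, w = 0.1 * (m > 2))
      expect_lt(max(abs(A_exp - A_all)), 1e-12)
    }
  }
})
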