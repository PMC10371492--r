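# ---- shared fixtures -------------------------------------------------------

ped_trio <- function() {
  data.frame(id = c("A", "B", "C"), parent1 = c("0", "0", "A"),
             parent2 = c("0", "0", "B"), stringsAsFactors = FALSE)
}

ped_selfed <- function() {
  data.frame(id = c("A", "S"), parent1 = c("0", "A"), parent2 = c("0", "A"),
             stringsAsFactors = FALSE)
}

# full-sib family then a full-sib mating
ped_fullsib_mating <- function() {
  data.frame(id = c("A", "B", "S1", "S2", "X"),
             parent1 = c("0", "0", "A", "A", "S1"),
             parent2 = c("0", "0", "B", "B", "S2"),
             stringsAsFactors = FALSE)
}

rand_ped <- function(seed, n_founders = 12, gens = 2, selfing = 0.1) {
  simulate_pedigree(sim_config(n_founders = n_founders, n_generations = gens,
                               offspring_per_cross = 2,
                               selfing_probability = selfing, seed = seed))
}

rand_dosage <- function(n, k, ploidy, seed) {
  set.seed(seed)
  M <- matrix(sample(0:ploidy, n * k, replace = TRUE), n, k,
              dimnames = list(paste0("i", seq_len(n)), paste0("m", seq_len(k))))
  M
}

# ---- independent brute-force oracles for the G parametrizations ------------
# Naive double loops over individual pairs, written directly from each
# method's per-pair formula; deliberately share no code with the package.

bf_pairloop <- function(X, denom) {
  n <- nrow(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- sum(X[i, ] * X[j, ]) / denom
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

bf_drop_constant <- function(M) M[, apply(M, 2, function(x) any(x != x[1])), drop = FALSE]

bf_vanraden <- function(M, m) {
  M <- bf_drop_constant(M)
  p <- colMeans(M) / m
  Z <- M - matrix(m * p, nrow(M), ncol(M), byrow = TRUE)
  bf_pairloop(Z, m * sum(p * (1 - p)))
}

bf_weighted <- function(M, m, d) {
  keep <- apply(M, 2, function(x) any(x != x[1]))
  M <- M[, keep, drop = FALSE]; d <- d[keep]
  p <- colMeans(M) / m
  n <- nrow(M)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(ncol(M)))
      acc <- acc + d[k] * (M[i, k] - m * p[k]) * (M[j, k] - m * p[k])
    G[i, j] <- acc / (m * sum(d * p * (1 - p)))
  }
  G
}

bf_yang <- function(M) {
  p <- colMeans(M) / 2
  q <- 1 - p
  K <- ncol(M)
  n <- nrow(M)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      G[i, i] <- 1 + mean((M[i, ]^2 - (1 + 2 * p) * M[i, ] + 2 * p^2) / (2 * p * q))
    } else {
      G[i, j] <- mean((M[i, ] - 2 * p) * (M[j, ] - 2 * p) / (2 * p * q))
    }
  }
  G
}

bf_su <- function(M) {
  p <- colMeans(M) / 2
  q <- 1 - p
  H <- (M == 1) * 1
  S <- H - matrix(2 * p * q, nrow(M), ncol(M), byrow = TRUE)
  bf_pairloop(S, sum(2 * p * q * (1 - 2 * p * q)))
}

bf_vitezica <- function(M) {
  p <- colMeans(M) / 2
  q <- 1 - p
  W <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (k in seq_len(ncol(M)))
    W[i, k] <- switch(as.character(M[i, k]),
                      "0" = -2 * p[k]^2, "1" = 2 * p[k] * q[k], "2" = -2 * q[k]^2)
  bf_pairloop(W, sum((2 * p * q)^2))
}

bf_endelman <- function(M, m) {
  p <- colMeans(M) / m
  Cc <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (k in seq_len(ncol(M)))
    Cc[i, k] <- choose(m, 2) * p[k]^2 - (m - 1) * p[k] * M[i, k] + choose(M[i, k], 2)
  v <- numeric(ncol(M))
  for (k in seq_len(ncol(M))) {
    x <- 0:m
    cx <- choose(m, 2) * p[k]^2 - (m - 1) * p[k] * x + choose(x, 2)
    v[k] <- sum(dbinom(x, m, p[k]) * cx^2)
  }
  bf_pairloop(Cc, sum(v))
}

bf_slater_full <- function(M, m) {
  cols <- list()
  s <- 0
  for (k in seq_len(ncol(M))) for (cls in 0:m) {
    ind <- as.numeric(M[, k] == cls)
    f <- mean(ind)
    s <- s + f * (1 - f)
    cols[[length(cols) + 1L]] <- ind - f
  }
  T <- do.call(cbind, cols)
  bf_pairloop(T, s)
}

bf_ratio <- function(R) {
  R <- bf_drop_constant(R)
  p <- colMeans(R)
  Z <- R - matrix(p, nrow(R), ncol(R), byrow = TRUE)
  bf_pairloop(Z, sum(p * (1 - p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel_equal <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(unclass(x) - unclass(y))), tol)
}
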