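test_that("half-vectorization uses lexicographic pair order and round-trips", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[1, 2] <- m[2, 1] <- 12; m[1, 3] <- m[3, 1] <- 13
  m[2, 3] <- m[3, 2] <- 23
  ev <- half_vectorize(conn_matrix(m, letters[1:3], "distance"))
  expect_equal(ev$values, c(12, 13, 23))
  expect_equal(ev$i, c(1L, 1L, 2L))
  expect_equal(ev$j, c(2L, 3L, 3L))
  rebuilt <- edge_to_matrix(ev)
  expect_equal(rebuilt, m)
  # a 47-node network has 1081 unordered pairs
  big <- conn_matrix(matrix(0, 47, 47), sprintf("n%02d", 1:47), "distance")
  expect_length(half_vectorize(big)$values, 1081)
  asym <- matrix(rnorm(16), 4)
  expect_error(half_vectorize(asym), "asymmetric")
})

test_that("distance residuals are exactly decorrelated from distance", {
  set.seed(14)
  d0 <- half_vectorize(euclidean_distance_matrix(
    contact_set(sprintf("c%d", 1:15), matrix(runif(45, 0, 80), 15))))
  for (rep in 1:20) {
    y <- d0; y$values <- rnorm(length(d0$values))
    res <- residualize_on_distance(y, d0)
    expect_lt(abs(cor(res$values, d0$values)), 1e-10)
    expect_lt(abs(mean(res$values)), 1e-12)
  }
  # an exact linear function of distance leaves nothing
  lin <- d0; lin$values <- 2 - 0.3 * d0$values
  expect_lt(max(abs(residualize_on_distance(lin, d0)$values)), 1e-10)
  # y orthogonal to demeaned distance is returned demeaned
  dc <- d0$values - mean(d0$values)
  y <- d0; y$values <- rnorm(length(dc))
  y$values <- y$values - dc * sum(y$values * dc) / sum(dc^2)
  expect_equal(residualize_on_distance(y, d0)$values,
               y$values - mean(y$values), tolerance = 1e-10)
  const <- d0; const$values <- rep(5, length(d0$values))
  expect_error(residualize_on_distance(y, const), "degenerate geometry")
})

test_that("spearman matches a hand-ranked oracle, including ties", {
  # x = (1, 2, 2, 4) has mid-ranks (1, 2.5, 2.5, 4); y = (3, 1, 4, 4) has
  # (2, 1, 3.5, 3.5); the oracle is Pearson on those ranks
  rank_oracle <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  rx <- rank_oracle(x); ry <- rank_oracle(y)
  expect_equal(rx, c(1, 2.5, 2.5, 4))
  o <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_edges(x, y)$r, o, tolerance = 1e-12)
  # monotone invariance and perfect anticorrelation
  set.seed(15)
  z <- rnorm(20)
  expect_equal(spearman_edges(z, exp(z))$r, 1)
  expect_equal(spearman_edges(1:5, 5:1)$r, -1)
  expect_error(spearman_edges(rep(1, 5), rnorm(5)), "constant")
  # t-approximation p agrees with the analytic formula
  sp <- spearman_edges(z, z + rnorm(20))
  tstat <- sp$r * sqrt((sp$n - 2) / (1 - sp$r^2))
  expect_equal(sp$p, 2 * pt(-abs(tstat), sp$n - 2))
})

test_that("exact permutation p is consistent with the enumeration null", {
  set.seed(16)
  x <- rnorm(6); y <- rnorm(6)
  sp <- spearman_edges(x, y, method = "permutation")
  expect_gte(sp$p, 1 / factorial(6))
  expect_lte(sp$p, 1)
  # strong monotone signal at n = 7 is extreme under the permutation null
  x <- 1:7; y <- c(1, 2, 3, 4, 5, 7, 6)
  expect_lt(spearman_edges(x, y, method = "permutation")$p, 0.01)
  expect_error(spearman_edges(rnorm(9), rnorm(9), method = "permutation"),
               "n <= 8")
})

test_that("couple_fc_fc is exact for identical matrices and null-calibrated", {
  set.seed(17)
  cs <- contact_set(sprintf("c%d", 1:12), matrix(runif(36, 0, 70), 12))
  dist <- euclidean_distance_matrix(cs)
  rnd_fc <- function() {
    v <- matrix(rnorm(12 * 40), 12)
    pearson_fc(ts_panel(v, 1, cs$contact_id, "bold"))
  }
  x <- rnd_fc()
  expect_equal(couple_fc_fc(x, x, dist)$r, 1)
  # independent matrices: p roughly uniform over 200 draws
  ps <- replicate(200, couple_fc_fc(rnd_fc(), rnd_fc(), dist)$p)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  other <- euclidean_distance_matrix(
    contact_set(sprintf("z%d", 1:12), matrix(runif(36, 0, 70), 12)))
  expect_error(couple_fc_fc(x, x, other), "node sets differ")
})

test_that("couple_sc_fc masks nonzero-SC edges exactly as a brute-force filter", {
  set.seed(18)
  n <- 10
  cs <- contact_set(sprintf("c%d", 1:n), matrix(runif(3 * n, 0, 60), n))
  dist <- euclidean_distance_matrix(cs)
  scv <- matrix(0, n, n)
  idx <- which(upper.tri(scv))
  on <- sample(idx, 20)
  scv[on] <- rpois(20, 3) + 1
  scv <- scv + t(scv)
  sc <- conn_matrix(scv, cs$contact_id, "sc")
  fcv <- matrix(tanh(rnorm(n * n)), n); fcv <- (fcv + t(fcv)) / 2
  fc <- conn_matrix(fcv, cs$contact_id, "bold_fc")
  got <- couple_sc_fc(sc, fc, dist, comparison = "sc_vs_bold")
  # brute-force: filter the pair lists by hand, then residualize + rank
  es <- half_vectorize(sc); ef <- half_vectorize(fc)
  ed <- half_vectorize(dist)
  keep <- es$values > 0
  X <- cbind(1, ed$values[keep])
  rs <- qr.resid(qr(X), es$values[keep])
  rf <- qr.resid(qr(X), ef$values[keep])
  expect_equal(got$n_edges, sum(keep))
  expect_equal(got$r, cor(rank(rs), rank(rf)), tolerance = 1e-12)
  # FC that is a monotone function of SC couples near-perfectly
  mono <- conn_matrix(tanh(scv / 4), cs$contact_id, "bold_fc")
  expect_gt(couple_sc_fc(sc, mono, dist, comparison = "sc_vs_bold")$r, 0.9)
  empty <- conn_matrix(matrix(0, n, n), cs$contact_id, "sc")
  expect_error(couple_sc_fc(empty, fc, dist),
               "insufficient nonzero structural connections")
})

test_that("BH-FDR equals the step-up enumeration oracle and flags correctly", {
  tab1 <- data.frame(participant = "p1", band = "1-4",
                     comparison = "bold_vs_seeg", r = 0.2, p = 0.03,
                     n_edges = 100)
  out1 <- fdr_correct(tab1)
  expect_equal(out1$p_fdr, 0.03)  # single test: unchanged
  # hand example: p = (.01, .02, .03, .04) adjusts to 0.04 everywhere
  tab4 <- data.frame(participant = sprintf("p%d", 1:4), band = "1-4",
                     comparison = "bold_vs_seeg", r = 0.1,
                     p = c(0.01, 0.02, 0.03, 0.04), n_edges = 50)
  expect_equal(fdr_correct(tab4)$p_fdr, rep(0.04, 4))
  # exhaustive step-up oracle on random p vectors, m <= 10
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (pos in seq_len(m)) {
      cand <- Inf
      for (k in pos:m) cand <- min(cand, m * p[o[k]] / k)
      adj[o[pos]] <- min(1, cand)
    }
    adj
  }
  set.seed(19)
  for (rep in 1:50) {
    m <- sample(2:10, 1)
    p <- runif(m)^sample(1:3, 1)
    tab <- data.frame(participant = seq_len(m), band = "b",
                      comparison = "x", r = 0, p = p, n_edges = 10)
    expect_equal(fdr_correct(tab)$p_fdr, bh_oracle(p), tolerance = 1e-12)
  }
  # families are corrected separately
  fam <- data.frame(participant = 1, band = "b",
                    comparison = c("a", "a", "b"), r = 0,
                    p = c(0.01, 0.04, 0.04), n_edges = 10)
  out <- fdr_correct(fam)
  expect_equal(out$p_fdr, c(0.02, 0.04, 0.04))
  expect_error(fdr_correct(data.frame(p = c(0.5, 0), comparison = "a")),
               "p values")
})

test_that("band summaries use the sample median per comparison and band", {
  tab <- data.frame(participant = rep(sprintf("p%d", 1:4), 2),
                    band = rep(c("1-4", "4-8"), each = 4),
                    comparison = "bold_vs_seeg",
                    r = c(0.1, 0.2, 0.3, 0.8, 0.5, 0.4, 0.3, 0.2),
                    p = 0.01, n_edges = 10)
  s <- summarize_bands(fdr_correct(tab))
  expect_equal(s$median_r[s$band == "1-4"], median(c(0.1, 0.2, 0.3, 0.8)))
  # even participant count: mean of the middle two (sort-based oracle)
  expect_equal(s$median_r[s$band == "1-4"], (0.2 + 0.3) / 2)
  expect_equal(s$n_participants, c(4, 4))
  one <- summarize_bands(tab[1, ])
  expect_equal(one$median_r, 0.1)
})

test_that("coupling r is invariant to positive affine rescaling of FC", {
  set.seed(20)
  cs <- contact_set(sprintf("c%d", 1:10), matrix(runif(30, 0, 60), 10))
  dist <- euclidean_distance_matrix(cs)
  mk <- function(v) conn_matrix(v, cs$contact_id, "seeg_fc")
  v1 <- matrix(tanh(rnorm(100)), 10); v1 <- (v1 + t(v1)) / 2
  v2 <- matrix(tanh(rnorm(100)), 10); v2 <- (v2 + t(v2)) / 2
  base <- couple_fc_fc(mk(v1), mk(v2), dist)$r
  shifted <- couple_fc_fc(mk(v1 * 0.4 + 0.2), mk(v2), dist)$r
  expect_equal(shifted, base, tolerance = 1e-12)
})
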