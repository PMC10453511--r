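test_that("steady-state detection converges, flags oscillation, tracks decay", {
  m <- 4
  init <- matrix(0.5, 3, m)
  ss <- run_to_steady_state(copy_agents(3), init, eps = 1e-3)
  expect_true(ss$converged)
  expect_equal(ss$t_f, m)  # already stationary at the seed

  # period-2 oscillator with amplitude above eps never converges
  osc <- list(stub_agent(1, function(s) 1 - s[1, ncol(s)]))
  expect_warning(
    ss2 <- run_to_steady_state(osc, matrix(c(0.1, 0.9, 0.1, 0.9), 1, 4),
                               eps = 1e-3, t_max = 60),
    "no steady state")
  expect_false(ss2$converged)
  expect_equal(ss2$t_f, 60L)

  # geometric decay x(t+1) = x(t)/2 from 1: range < 1e-3 within 20 steps
  damp <- list(stub_agent(1, function(s) s[1, ncol(s)] / 2))
  ss3 <- run_to_steady_state(damp, matrix(1, 1, 4), eps = 1e-3, t_max = 100)
  expect_true(ss3$converged)
  expect_lt(ss3$t_f, 20L)
})

test_that("regulatory value is the arctangent of the OLS slope", {
  expect_equal(regulatory_value(c(0, 0.1, 0.2, 0.3)), atan(0.1))
  expect_equal(regulatory_value(c(0, 1, 2, 3)), pi / 4)
  expect_equal(regulatory_value(rep(0.7, 10)), 0)
  # lm() as the independent least-squares oracle on random trajectories
  set.seed(17)
  for (i in 1:20) {
    y <- cumsum(rnorm(sample(5:40, 1), 0, 0.3))
    slope <- unname(coef(lm(y ~ t, data.frame(y = y, t = seq_along(y) - 1)))[2])
    expect_equal(regulatory_value(y), atan(slope), tolerance = 1e-9)
    expect_lt(abs(regulatory_value(y)), pi / 2)
  }
})

test_that("perturbation recording spans the whole instability interval", {
  m <- 5; n <- 3
  snapshot <- matrix(0.4, n, m)
  spec <- perturbation_spec("instant", 2, phi_b = 0.4, phi_w = 0.3, phi_d = m)
  Xr <- perturb_and_record(copy_agents(n), snapshot, spec)
  expect_equal(dim(Xr), c(2L * m + m, n))  # 2m + phi_d rows
  # stability window, forced plateau, then agent-held release value
  expect_equal(unname(Xr[1:m, 2]), rep(0.4, m))
  expect_equal(unname(Xr[(m + 1):(2 * m), 2]), rep(0.7, m))
  expect_equal(unname(Xr[(2 * m + 1):(3 * m), 2]), rep(0.7, m))
  # unperturbed genes stay at the fixed point
  expect_true(all(Xr[, c(1, 3)] == 0.4))

  # zero-width perturbation on constant agents leaves everything flat
  flat <- perturbation_spec("instant", 1, phi_b = 0.4, phi_w = 0, phi_d = m)
  Xr0 <- perturb_and_record(constant_agents(rep(0.4, n)), snapshot, flat)
  expect_true(all(Xr0 == 0.4))
})

test_that("the regulatory matrix captures a known causal link", {
  n <- 3; m <- 4
  # gene 2 copies gene 1; genes 1 and 3 hold their own value
  agents <- causal_agents(n, source = 1, target = 2)
  init <- matrix(0.3, n, m)
  res <- build_regulatory_matrix(agents, init, g_max = rep(1, n),
                                 kind = "instant")
  expect_equal(dim(res$R), c(n, n))
  expect_true(all(is.finite(res$R)), all(abs(res$R) <= pi / 2))
  # perturbing gene 1 upward drags gene 2 upward: positive regulatory value
  expect_gt(res$R[1, 2], 0)
  # and clearly exceeds the non-edge responses measured the same way
  off <- res$R[cbind(c(2, 3, 2, 3), c(3, 2, 1, 1))]
  expect_gt(res$R[1, 2], max(abs(off)))

  # zero-width perturbations of constant agents give an exactly zero matrix
  const <- constant_agents(rep(0.5, n))
  res0 <- build_regulatory_matrix(const, matrix(0.5, n, m),
                                  g_max = rep(0.5, n), kind = "instant")
  expect_true(all(res0$R == 0))
})

test_that("thresholds are column medians of signed values with extrema", {
  R <- cbind(c(0.3, -0.1, 0.2, -0.5, 0.0),
             c(0.3, -0.1, 0.2, -0.5, 0.0))
  th <- thresholds(R)
  expect_equal(th$tau_p[1], 0.25)   # median of {0.3, 0.2}; zero excluded
  expect_equal(th$tau_n[1], -0.3)   # median of {-0.1, -0.5}
  expect_equal(th$r_max[1], 0.3)
  expect_equal(th$r_min[1], -0.5)
  # brute-force median oracle on random matrices
  set.seed(23)
  for (i in 1:10) {
    Rr <- matrix(rnorm(36, 0, 0.4), 6)
    tr <- suppressWarnings(thresholds(Rr))
    for (j in 1:6) {
      pos <- Rr[, j][Rr[, j] > 0]; neg <- Rr[, j][Rr[, j] < 0]
      if (length(pos)) expect_equal(tr$tau_p[j], median(pos))
      if (length(neg)) expect_equal(tr$tau_n[j], median(neg))
    }
  }
  # degenerate columns warn and fall back
  allpos <- cbind(c(0.1, 0.2, 0.4))
  expect_warning(thp <- thresholds(allpos), "degenerate")
  expect_true(thp$neg_degenerate[1])
  expect_equal(thp$tau_p[1], 0.2)
  # a positive singleton is its own median
  expect_equal(suppressWarnings(thresholds(cbind(c(0.4))))$tau_p[1], 0.4)
})

test_that("edge probabilities follow the piecewise calibration exactly", {
  expect_equal(edge_probability(0, 0.2, -0.2, 0.6, -0.6), 0)
  expect_equal(edge_probability(0.1, 0.2, -0.2, 0.6, -0.6), 0.125)
  expect_equal(edge_probability(0.4, 0.2, -0.2, 0.6, -0.6), 0.75)
  # hitting either threshold always gives probability one half
  set.seed(29)
  for (i in 1:10) {
    tp <- runif(1, 0.05, 0.5); tn <- -runif(1, 0.05, 0.5)
    rmax <- tp + runif(1, 0.05, 1); rmin <- tn - runif(1, 0.05, 1)
    expect_equal(edge_probability(tp, tp, tn, rmax, rmin), 0.5)
    expect_equal(edge_probability(tn, tp, tn, rmax, rmin), 0.5)
    expect_equal(edge_probability(rmax, tp, tn, rmax, rmin), 1)
    expect_equal(edge_probability(rmin, tp, tn, rmax, rmin), 1)
    # continuity at both thresholds
    for (tau in c(tp, tn)) {
      lo <- edge_probability(tau - 1e-9, tp, tn, rmax, rmin)
      hi <- edge_probability(tau + 1e-9, tp, tn, rmax, rmin)
      expect_lt(abs(hi - lo), 1e-6)
    }
    # bounded on a dense grid
    grid <- seq(rmin, rmax, length.out = 500)
    p <- edge_probability(grid, tp, tn, rmax, rmin)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_warning(pc <- edge_probability(2, 0.2, -0.2, 0.6, -0.6), "clamped")
  expect_equal(pc, 1)
})

test_that("probability matrices match an element-wise oracle", {
  set.seed(37)
  R <- matrix(rnorm(49, 0, 0.3), 7)
  th <- suppressWarnings(thresholds(R))
  P <- suppressWarnings(build_probability_matrix(R, th))
  expect_true(all(P >= 0 & P <= 1))
  for (j in 1:7) for (i in 1:7) {
    expected <- suppressWarnings(edge_probability(
      R[i, j], th$tau_p[j], th$tau_n[j], th$r_max[j], th$r_min[j]))
    if (th$pos_degenerate[j] && R[i, j] > 0) expected <- 0
    if (th$neg_degenerate[j] && R[i, j] < 0) expected <- 0
    expect_identical(P[i, j], expected)
  }
  # zero matrix maps to zero probabilities everywhere
  Z <- matrix(0, 3, 3)
  expect_true(all(suppressWarnings(
    build_probability_matrix(Z, suppressWarnings(thresholds(Z)))) == 0))
  # an entry equal to its column's activation threshold maps to one half
  # (odd positive count: the median is the middle element, here 0.4)
  Rt <- cbind(c(0.2, 0.4, 0.6, -0.1, -0.3))
  tht <- thresholds(Rt)
  expect_equal(tht$tau_p[1], 0.4)
  Pt <- build_probability_matrix(Rt, tht)
  expect_equal(Pt[2, 1], 0.5)
})

test_that("AUC-ROC equals the pairwise win probability with half-ties", {
  gold4 <- gold_network(matrix(c(0, 1, 0, 0,
                                 1, 0, 0, 0,
                                 0, 0, 0, 1,
                                 0, 0, 0, 0), 4, byrow = TRUE),
                        include_self_loops = FALSE)
  # hand-checkable 4-score instance: scores 0.9,0.8,0.4,0.2 with labels
  # 1,0,1,0 -> the positives win 3 of the 4 positive x negative comparisons
  g2 <- gold_network(matrix(c(1, 0, 1, 0), 2), include_self_loops = TRUE)
  P2 <- matrix(c(0.9, 0.8, 0.4, 0.2), 2)
  expect_equal(auc_roc(P2, g2, include_self_loops = TRUE), 0.75)

  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    wins <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(wins)
  }
  set.seed(41)
  for (i in 1:100) {
    P <- matrix(runif(16), 4)
    if (i %% 3 == 0) P <- round(P, 1)  # force ties
    expect_equal(auc_roc(P, gold4),
                 pairwise_auc(as.vector(P)[row(P) != col(P)],
                              as.vector(gold4$adjacency)[row(P) != col(P)]),
                 tolerance = 1e-12)
  }
  # perfect separation and all-tied scores
  Psep <- matrix(0, 4, 4); Psep[gold4$adjacency == 1] <- 0.9
  expect_equal(auc_roc(Psep, gold4), 1)
  expect_equal(auc_roc(matrix(0.5, 4, 4), gold4), 0.5)
  empty <- gold_network(matrix(0, 4, 4))
  expect_error(auc_roc(Psep, empty), "single class")
})

test_that("a stub environment with one causal link ranks the true edge high", {
  n <- 4; m <- 4
  agents <- causal_agents(n, source = 1, target = 3)
  init <- matrix(0.3, n, m)
  res <- build_regulatory_matrix(agents, init, g_max = rep(1, n),
                                 kind = "trapezium", phi_p = 2)
  th <- suppressWarnings(thresholds(res$R))
  P <- suppressWarnings(build_probability_matrix(res$R, th))
  offdiag <- P[row(P) != col(P)]
  expect_gt(P[1, 3], median(offdiag))
})
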