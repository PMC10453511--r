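test_that("seed_initial_state takes the first m observations or zeros", {
  set.seed(1)
  obs <- matrix(runif(50 * 3), 50, dimnames = list(NULL, paste0("G", 1:3)))
  st <- seed_initial_state(obs, m = 10)
  expect_equal(dim(st), c(3L, 10L))
  expect_equal(unname(st), unname(t(obs[1:10, ])))
  expect_true(all(seed_initial_state(obs, 10, mode = "zeros") == 0))
  expect_error(seed_initial_state(obs[1:5, ], 10), "5 observations")

  # dataset source: experiments averaged first
  ds <- smooth_dataset(n = 2, b = 12, k = 3, seed = 2)
  st2 <- seed_initial_state(ds, m = 4)
  avg <- Reduce(`+`, ds$experiments) / 3
  expect_equal(unname(st2), unname(t(avg[1:4, ])))
})

test_that("instant perturbation holds its level for the whole duration", {
  spec <- perturbation_spec("instant", 1, phi_b = 0.2, phi_w = 0.5, phi_d = 3)
  expect_equal(perturbation_value(spec, 0:2), c(0.7, 0.7, 0.7))
  expect_error(perturbation_value(spec, 3), "out of range")
  expect_error(perturbation_spec("instant", 1, phi_b = 0.8, phi_w = 0.5,
                                 phi_d = 2, g_max = 1), "outside")
  expect_error(perturbation_spec("instant", 1, phi_b = 0, phi_w = 1, phi_d = 0),
               "phi_d")
})

test_that("trapezium perturbation ramps, holds, and releases symmetrically", {
  spec <- perturbation_spec("trapezium", 1, phi_b = 0, phi_w = 0.6,
                            phi_d = 6, phi_p = 2)
  expect_equal(perturbation_value(spec, 0:5), c(0.3, 0.6, 0.6, 0.6, 0.3, 0))
  # degenerate trapezium (peak-hold = duration) equals the instant shape
  flat <- perturbation_spec("trapezium", 1, phi_b = 0.1, phi_w = 0.4,
                            phi_d = 4, phi_p = 4)
  expect_equal(perturbation_value(flat, 0:3), rep(0.5, 4))
  expect_error(perturbation_spec("trapezium", 1, 0, 0.5, 4), "phi_p")
  expect_error(perturbation_spec("trapezium", 1, 0, 0.5, 4, phi_p = 5), "phi_p")
  # property: values stay within [phi_b, phi_b + phi_w] for fuzzed specs
  set.seed(31)
  for (i in 1:20) {
    d <- sample(1:12, 1)
    sp <- perturbation_spec("trapezium", 1, phi_b = runif(1, 0, 0.3),
                            phi_w = runif(1, 0, 0.5), phi_d = d,
                            phi_p = sample(d, 1))
    v <- perturbation_value(sp, 0:(d - 1))
    expect_true(all(v >= sp$phi_b - 1e-12 & v <= sp$phi_b + sp$phi_w + 1e-12))
  }
})

test_that("step_aes updates synchronously from the pre-step state", {
  set.seed(8)
  state <- matrix(runif(12), 3, 4)
  # each agent reads *another* gene's newest value: any sequential
  # (asynchronous) update would feed freshly written values forward
  agents <- lapply(1:3, function(i)
    stub_agent(i, local({ j <- (i %% 3) + 1; function(s) s[j, ncol(s)] })))
  res <- step_aes(agents, state)
  expected <- state[c(2, 3, 1), 4]
  expect_equal(unname(res$x), unname(expected))
  # state shift invariant: old columns 2..m then the new vector
  expect_equal(res$state[, 1:3], state[, 2:4])
  expect_equal(unname(res$state[, 4]), unname(res$x))
})

test_that("fixed-point stubs are stationary and overrides bypass agents", {
  state <- matrix(0.4, 2, 3)
  agents <- copy_agents(2)
  res <- step_aes(agents, state)
  expect_equal(unname(res$x), c(0.4, 0.4))
  res2 <- step_aes(agents, state, overrides = c("2" = 0.9))
  expect_equal(unname(res2$x), c(0.4, 0.9))
  # clipping bounds agent outputs but not overrides
  big <- constant_agents(c(7, 7))
  res3 <- step_aes(big, state, overrides = c("2" = 3))
  expect_equal(unname(res3$x), c(1.5, 3))
  expect_error(step_aes(agents[1], state), "agents for")
})

test_that("simulation seeds the trace, is deterministic, and counts agent calls", {
  m <- 4; n <- 3
  init <- matrix(runif(n * m), n, m)
  calls <- new.env(); calls$k <- 0L
  agents <- lapply(seq_len(n), function(i)
    stub_agent(i, local({ ii <- i; function(s) {
      calls$k <- calls$k + 1L
      s[ii, ncol(s)]
    }})))
  tr <- simulate_aes(agents, init, steps = 30)
  expect_equal(dim(unclass(tr)), c(n, 30L))
  expect_equal(unname(unclass(tr)[, 1:m]), unname(init))
  # fixed-point stubs give a constant continuation
  expect_true(all(unclass(tr)[, m:30] == init[, m]))
  expect_equal(calls$k, n * (30L - m))
  expect_identical(unclass(simulate_aes(copy_agents(n), init, 30)),
                   unclass(simulate_aes(copy_agents(n), init, 30)))
  expect_error(simulate_aes(agents, init, steps = 2), "at least")
})

test_that("perturbed rows reproduce the perturbation function exactly", {
  set.seed(44)
  for (kind in c("instant", "trapezium")) {
    for (rep in 1:5) {
      n <- 3; m <- 4
      d <- sample(2:8, 1)
      start <- m + sample(1:3, 1)
      spec <- perturbation_spec(kind, gene_index = sample(n, 1),
                                phi_b = runif(1, 0, 0.4), phi_w = runif(1, 0, 0.5),
                                phi_d = d,
                                phi_p = if (kind == "trapezium") sample(d, 1) else NULL,
                                start = start)
      init <- matrix(runif(n * m), n, m)
      tr <- unclass(simulate_aes(copy_agents(n), init, steps = start + d + 3,
                                 perturbations = list(spec)))
      window <- start:(start + d - 1)
      expect_equal(unname(tr[spec$gene_index, window]),
                   perturbation_value(spec, 0:(d - 1)))
      # after release the gene is back under agent control (copy stub holds
      # the last perturbed value)
      expect_equal(tr[spec$gene_index, start + d],
                   perturbation_value(spec, d - 1))
    }
  }
})
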