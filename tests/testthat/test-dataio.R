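test_that("read_expression parses headers, Time columns and experiment blocks", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Time\tG1\tG2",
               paste(1:5, seq(0, 0.4, 0.1), seq(1, 0.6, -0.1), sep = "\t")),
             path)
  ds <- read_expression(path)
  expect_equal(ds$gene_names, c("G1", "G2"))
  expect_equal(n_genes(ds), 2L)
  expect_equal(n_experiments(ds), 1L)
  expect_equal(unname(n_obs(ds)), 5L)
  expect_equal(ds$experiments[[1]][, "G1"], seq(0, 0.4, 0.1))

  # two blank-line-separated 21-row blocks -> k = 2, b = 21
  block <- c("G1\tG2", apply(matrix(round(runif(42), 6), 21), 1,
                             paste, collapse = "\t"))
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c(block, "", block), path2)
  ds2 <- read_expression(path2)
  expect_equal(n_experiments(ds2), 2L)
  expect_equal(unname(n_obs(ds2)), c(21L, 21L))
})

test_that("read_expression rejects malformed files", {
  ragged <- tempfile()
  writeLines(c("G1\tG2", "0.1\t0.2", "0.3"), ragged)
  expect_error(read_expression(ragged), "ragged")

  mismatched <- tempfile()
  writeLines(c("G1\tG2", "0.1\t0.2", "", "G1\tG2\tG3", "0.1\t0.2\t0.3"),
             mismatched)
  expect_error(read_expression(mismatched), "mismatched gene headers")

  nonmono <- tempfile()
  writeLines(c("Time\tG1", "2\t0.1", "1\t0.2"), nonmono)
  expect_error(read_expression(nonmono), "not strictly increasing")

  expect_error(read_expression(tempfile()), "not found")
})

test_that("expression TSV round-trips bit-identically", {
  set.seed(11)
  ds <- smooth_dataset(n = 4, b = 9, k = 3, seed = 11)
  ds$experiments <- lapply(ds$experiments, function(e) e + runif(length(e)) * 1e-9)
  path <- write_temp_expression(ds)
  back <- read_expression(path)
  expect_identical(back$experiments, ds$experiments)
})

test_that("min-max normalization follows the per-gene formula and is invertible", {
  ds <- expression_dataset(list(cbind(G1 = c(2, 4, 6), G2 = c(3, 3, 3))))
  expect_warning(norm <- min_max_normalize(ds), "constant gene")
  expect_equal(norm$experiments[[1]][, "G1"], c(0, 0.5, 1))
  expect_equal(norm$experiments[[1]][, "G2"], c(0, 0, 0))
  expect_error(min_max_normalize(norm), "already normalized")

  # training constants applied unchanged to evaluation experiments
  ds2 <- expression_dataset(list(cbind(G1 = c(0, 5, 10)), cbind(G1 = c(2, 12, 6))))
  norm2 <- min_max_normalize(ds2, train_experiments = 1L)
  expect_equal(norm2$experiments[[2]][, "G1"], c(0.2, 1.2, 0.6))

  # normalize -> denormalize identity on training data
  ds3 <- smooth_dataset(n = 3, b = 15, k = 2, seed = 4)
  back <- denormalize(min_max_normalize(ds3))
  for (e in 1:2)
    expect_lt(max(abs(back$experiments[[e]] - ds3$experiments[[e]])), 1e-12)
})

test_that("make_supervised windows gene-major and one step ahead", {
  # D (genes x time): gene1 = .0 .1 .2 .3 .4 ; gene2 = 1 .9 .8 .7 .6
  ds <- tiny_dataset(b = 5)
  ds <- min_max_normalize(ds)
  ds$experiments[[1]] <- cbind(G1 = seq(0, 0.4, 0.1), G2 = seq(1, 0.6, -0.1))
  sup <- make_supervised(ds, gene_index = 1, m = 2)
  expect_equal(dim(sup$inputs), c(3L, 4L))  # (b-m) x (n*m)
  expect_equal(length(sup$targets), 3L)
  # row 1: gene1's lags then gene2's lags, oldest first; target = gene1 at t=3
  expect_equal(unname(sup$inputs[1, ]), c(0.0, 0.1, 1.0, 0.9))
  expect_equal(sup$targets[1], 0.2)
  expect_equal(unname(sup$inputs[3, ]), c(0.2, 0.3, 0.8, 0.7))
  expect_equal(sup$targets[3], 0.4)

  expect_error(make_supervised(ds, 1, m = 5), "1 <= m < b")
})

test_that("supervised rows concatenate experiments without crossing boundaries", {
  ds <- min_max_normalize(smooth_dataset(n = 3, b = 21, k = 2, seed = 2))
  sup <- make_supervised(ds, gene_index = 2, m = 10)
  expect_equal(nrow(sup$inputs), 2L * (21L - 10L))
  # property: row count = sum over experiments of (b - m) for fuzzed shapes
  set.seed(9)
  for (case in 1:5) {
    n <- sample(2:5, 1); b <- sample(8:15, 1); k <- sample(1:3, 1)
    m <- sample(seq_len(b - 1), 1)
    dsf <- min_max_normalize(smooth_dataset(n, b, k, seed = case))
    supf <- make_supervised(dsf, 1, m)
    expect_equal(nrow(supf$inputs), k * (b - m))
    expect_equal(ncol(supf$inputs), n * m)
    # each target is the gene value one step after its window
    e1 <- dsf$experiments[[1]]
    expect_equal(supf$targets[1], unname(e1[m + 1, 1]))
  }
})

test_that("gold networks default unlisted pairs to zero and validate names", {
  path <- tempfile()
  writeLines(c("G1\tG2\t1", "G2\tG1\t0"), path)
  gold <- read_gold_network(path, c("G1", "G2", "G3"))
  expect_equal(sum(gold$adjacency), 1)
  expect_equal(gold$adjacency["G1", "G2"], 1)
  expect_equal(gold$adjacency["G1", "G3"], 0)

  self <- tempfile()
  writeLines(c("G1\tG1\t1", "G1\tG2\t1"), self)
  expect_warning(gold2 <- read_gold_network(self, c("G1", "G2")), "self-loop")
  expect_equal(gold2$adjacency["G1", "G1"], 1)  # retained in the adjacency
  expect_false(gold2$include_self_loops)        # but flagged out of evaluation

  bad <- tempfile()
  writeLines("G9\tG1\t1", bad)
  expect_error(read_gold_network(bad, paste0("G", 1:8)), "unknown gene")

  lab <- tempfile()
  writeLines("G1\tG2\t2", lab)
  expect_error(read_gold_network(lab, c("G1", "G2")), "0 or 1")
})

test_that("gold network edge lists round-trip", {
  adj <- matrix(0, 3, 3, dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  adj["G1", "G2"] <- 1; adj["G3", "G1"] <- 1
  gold <- gold_network(adj)
  path <- tempfile()
  write_gold_network(gold, path)
  back <- read_gold_network(path, paste0("G", 1:3))
  expect_equal(back$adjacency, gold$adjacency)
})
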