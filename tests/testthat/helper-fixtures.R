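# Shared fixtures: tiny datasets and stub agents built in code.

# a deterministic 2-gene, b-observation dataset (one experiment)
tiny_dataset <- function(b = 5) {
  expression_dataset(
    list(cbind(G1 = seq(0, by = 0.1, length.out = b),
               G2 = seq(1, by = -0.1, length.out = b))))
}

# k experiments of smooth, gene-coupled trajectories in [0, 1]
smooth_dataset <- function(n = 3, b = 21, k = 2, seed = 1) {
  set.seed(seed)
  phase <- runif(n, 0, pi)
  experiments <- lapply(seq_len(k), function(e) {
    t <- seq_len(b) + e
    sapply(seq_len(n), function(i) 0.5 + 0.4 * sin(0.3 * t + phase[i]))
  })
  experiments <- lapply(experiments, function(m) {
    colnames(m) <- paste0("G", seq_len(n)); m
  })
  expression_dataset(experiments)
}

# stub agents ------------------------------------------------------------

# each gene keeps its last value (fixed point of the simulator)
copy_agents <- function(n) {
  lapply(seq_len(n), function(i)
    stub_agent(i, local({ ii <- i; function(state) state[ii, ncol(state)] })))
}

constant_agents <- function(values) {
  lapply(seq_along(values), function(i)
    stub_agent(i, local({ v <- values[i]; function(state) v })))
}

# gene `target` copies gene `source`'s last value; everyone else holds
causal_agents <- function(n, source, target) {
  lapply(seq_len(n), function(i) {
    if (i == target)
      stub_agent(i, local({ s <- source; function(state) state[s, ncol(state)] }))
    else
      stub_agent(i, local({ ii <- i; function(state) state[ii, ncol(state)] }))
  })
}

# write a dataset to a temporary TSV and return the path
write_temp_expression <- function(ds) {
  path <- tempfile(fileext = ".tsv")
  write_expression(ds, path)
  path
}
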