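#' Fit an artificial environmental setting to a dataset
#'
#' End-to-end model estimation: min-max normalizes the dataset (constants
#' from the training experiments, by default the first 60%), builds one
#' supervised sliding-window set per gene, trains an agent per gene, and
#' optionally selects each agent's architecture with the genetic algorithm
#' (whose fitness is the negated simulation error against the evaluation
#' target, the mean over all experiments). The GA's initial population is
#' seeded with the three uniform single-architecture assignments, so the
#' selected mixed assignment can never score below the best uniform one.
#'
#' @param ds an `expression_dataset` (raw or already normalized).
#' @param m window length / state-matrix width (default 10).
#' @param train_fraction fraction of experiments used for training and for
#'   the normalization constants (default 0.6; the first
#'   `ceiling(train_fraction * k)` experiments).
#' @param optimize select architectures with the GA (`TRUE`) or use one
#'   fixed architecture for every agent (`FALSE`).
#' @param architecture architecture used when `optimize = FALSE`.
#' @param tuning_budget random-search trials per (gene, architecture); 0
#'   uses each architecture's default hyperparameters.
#' @param ga a [ga_config()] (its seed defaults to `seed`).
#' @param seed base RNG seed for training.
#' @param clip simulation output clipping, see [step_aes()].
#' @return An object of class `aes_model`: `agents`, `assignment`,
#'   `gene_names`, `m`, `norm_min`/`norm_max`, `eval_target` (n x b matrix),
#'   `g_max`, `fitness`, `ga` (a `ga_result` or NULL), `config`.
#' @export
fit_aes <- function(ds, m = 10L, train_fraction = 0.6, optimize = TRUE,
                    architecture = "FCNN", tuning_budget = 0L,
                    ga = ga_config(seed = seed), seed = 1L,
                    clip = c(0, 1.5)) {
  stopifnot(inherits(ds, "expression_dataset"))
  k <- n_experiments(ds)
  train_idx <- seq_len(max(1L, ceiling(train_fraction * k)))
  if (!ds$normalized) ds <- min_max_normalize(ds, train_experiments = train_idx)
  n <- n_genes(ds)
  fitness_fn <- make_aes_fitness(ds, m, train_experiments = train_idx,
                                 tuning_budget = tuning_budget, seed = seed,
                                 clip = clip)
  if (optimize) {
    uniform <- lapply(ARCHITECTURES, function(a) rep(a, n))
    ga_res <- run_ga(fitness_fn, n, config = ga, init_population = uniform)
    assignment <- ga_res$best
    fitness <- ga_res$best_fitness
  } else {
    assignment <- rep(architecture, n)
    fitness <- fitness_fn(assignment)
    ga_res <- NULL
  }
  cache <- attr(fitness_fn, "cache")
  agents <- lapply(seq_len(n), function(i)
    cache[[paste(i, assignment[i], sep = "/")]])
  g_max <- apply(do.call(rbind, ds$experiments), 2L, max)
  structure(list(agents = agents, assignment = assignment,
                 gene_names = ds$gene_names, m = as.integer(m),
                 norm_min = ds$norm_min, norm_max = ds$norm_max,
                 eval_target = attr(fitness_fn, "target"),
                 g_max = g_max, fitness = fitness, ga = ga_res,
                 config = list(train_fraction = train_fraction,
                               train_experiments = train_idx,
                               optimize = optimize,
                               architecture = architecture,
                               tuning_budget = tuning_budget,
                               seed = seed, clip = clip)),
            class = "aes_model")
}

#' @export
print.aes_model <- function(x, ...) {
  cat(sprintf("aes_model: %d agents (%s), m = %d, fitness %.4g\n",
              length(x$agents),
              paste(table(x$assignment)[unique(x$assignment)], unique(x$assignment),
                    collapse = " + "),
              x$m, x$fitness))
  invisible(x)
}

#' Simulate a fitted environment over the evaluation horizon
#'
#' Seeds the state matrix with the evaluation target's first m observations
#' and runs the closed loop for the target's full length.
#'
#' @param aes an `aes_model`.
#' @param steps trace length (default: evaluation-target length).
#' @param perturbations optional list of [perturbation_spec()].
#' @return A `simulation_trace`.
#' @export
simulate_fitted <- function(aes, steps = ncol(aes$eval_target),
                            perturbations = list()) {
  stopifnot(inherits(aes, "aes_model"))
  init <- seed_initial_state(t(aes$eval_target), aes$m)
  simulate_aes(aes$agents, init, steps, perturbations = perturbations,
               clip = aes$config$clip)
}

#' Evaluate a fitted environment
#'
#' Convenience wrapper: simulate with [simulate_fitted()] and score the
#' trace against the evaluation target with [evaluate_aes()].
#'
#' @param aes an `aes_model`.
#' @return An `evaluation_report`.
#' @export
evaluate_fitted <- function(aes) {
  evaluate_aes(simulate_fitted(aes), aes$eval_target, aes$m)
}

#' Infer a gene regulatory network from a fitted environment
#'
#' Runs the environment to a steady state, perturbs each gene in turn from
#' the same stabilized snapshot, converts the response slopes into the
#' signed regulatory matrix, calibrates per-responder thresholds, maps the
#' matrix to edge probabilities, and (when a gold standard is supplied)
#' scores the ranking with AUC-ROC.
#'
#' @param aes an `aes_model`.
#' @param kind perturbation shape (`"trapezium"`, default, or `"instant"`).
#' @param phi_p trapezium peak-hold steps (default 2).
#' @param phi_d perturbation duration (default m).
#' @param eps,t_max steady-state controls, see [run_to_steady_state()].
#' @param gold optional [gold_network()] for evaluation.
#' @param include_self_loops include diagonal pairs in the AUC vector.
#' @return A list of class `grn_inference`: `regulatory` (signed n x n),
#'   `thresholds`, `probability` (n x n), `edges` (ranked data frame),
#'   `auc` (or NA), `converged`, `t_f`.
#' @export
infer_network <- function(aes, kind = c("trapezium", "instant"), phi_p = 2L,
                          phi_d = aes$m, eps = 1e-3, t_max = 500L,
                          gold = NULL, include_self_loops = FALSE) {
  stopifnot(inherits(aes, "aes_model"))
  kind <- match.arg(kind)
  init <- seed_initial_state(t(aes$eval_target), aes$m)
  rm_res <- build_regulatory_matrix(aes$agents, init, aes$g_max, kind = kind,
                                    phi_p = phi_p, phi_d = phi_d, eps = eps,
                                    t_max = t_max, clip = aes$config$clip)
  th <- thresholds(rm_res$R)
  P <- build_probability_matrix(rm_res$R, th)
  auc <- if (!is.null(gold))
    auc_roc(P, gold, include_self_loops = include_self_loops) else NA_real_
  structure(list(regulatory = rm_res$R, thresholds = th, probability = P,
                 edges = rank_edges(P, include_self_loops = include_self_loops),
                 auc = auc, converged = rm_res$converged, t_f = rm_res$t_f,
                 kind = kind),
            class = "grn_inference")
}

#' @export
print.grn_inference <- function(x, ...) {
  cat(sprintf("grn_inference (%s perturbation): %d genes%s\n", x$kind,
              nrow(x$regulatory),
              if (is.na(x$auc)) "" else sprintf(", AUC-ROC %.4f", x$auc)))
  cat("top edges:\n")
  print(utils::head(x$edges, 5L), row.names = FALSE)
  invisible(x)
}

#' Write inference outputs
#'
#' Writes the regulatory matrix and probability matrix as gene-labelled TSV,
#' plus the ranked edge list.
#'
#' @param inference a `grn_inference`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_inference <- function(inference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(inference$regulatory, file.path(dir, "regulatory_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(unclass(inference$probability),
                     file.path(dir, "probability_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(inference$edges, file.path(dir, "ranked_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Save / load a fitted environment bundle
#'
#' The bundle directory holds a JSON manifest (gene names, assignment,
#' normalization constants, configuration) and the trained weights in R's
#' native serialization.
#'
#' @param aes an `aes_model`.
#' @param dir bundle directory.
#' @return `dir` (`save_aes`) or the restored `aes_model` (`load_aes`).
#' @export
save_aes <- function(aes, dir) {
  stopifnot(inherits(aes, "aes_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(gene_names = aes$gene_names, m = aes$m,
                   assignment = aes$assignment,
                   norm_min = as.list(aes$norm_min),
                   norm_max = as.list(aes$norm_max),
                   g_max = as.list(aes$g_max),
                   fitness = aes$fitness, config = aes$config,
                   weights_file = "weights.rds")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(aes, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_aes
#' @export
load_aes <- function(dir) {
  aes <- readRDS(file.path(dir, "weights.rds"))
  stopifnot(inherits(aes, "aes_model"))
  aes
}
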