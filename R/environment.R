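#' Seed the initial state matrix
#'
#' Fills the n x m state matrix (genes x time steps, columns oldest to
#' newest) with the first m observations of a source dataset, or with zeros.
#' When the source is an [expression_dataset()] its experiments are averaged
#' first, matching the evaluation target used elsewhere.
#'
#' @param source an `expression_dataset`, or a b x n matrix (rows =
#'   observations, columns = genes). Ignored when `mode = "zeros"`.
#' @param m window length.
#' @param mode `"observations"` (default) or `"zeros"`.
#' @return n x m numeric matrix with gene row names when available.
#' @export
seed_initial_state <- function(source, m, mode = c("observations", "zeros")) {
  mode <- match.arg(mode)
  if (mode == "zeros") {
    if (inherits(source, "expression_dataset"))
      return(matrix(0, n_genes(source), m,
                    dimnames = list(source$gene_names, NULL)))
    return(matrix(0, ncol(source), m, dimnames = list(colnames(source), NULL)))
  }
  obs <- if (inherits(source, "expression_dataset")) {
    Reduce(`+`, source$experiments) / n_experiments(source)
  } else {
    as.matrix(source)
  }
  if (nrow(obs) < m)
    stop(sprintf("source provides %d observations; %d required", nrow(obs), m))
  state <- t(obs[seq_len(m), , drop = FALSE])
  rownames(state) <- colnames(obs)
  state
}

#' Perturbation specification
#'
#' A manual override of one gene's expression for `phi_d` consecutive steps.
#' Two shapes are supported: `instant` jumps immediately to
#' `phi_b + phi_w` and holds it for the whole duration; `trapezium` ramps up
#' over `floor((phi_d - phi_p) / 2)` steps, holds the peak for `phi_p` steps
#' (plus the rounding remainder), and ramps back down symmetrically. Values
#' stay within `[phi_b, phi_b + phi_w]`, which must lie inside
#' `[0, g_max]`, the gene's maximum observed expression.
#'
#' @param kind `"instant"` or `"trapezium"`.
#' @param gene_index gene whose row is overridden.
#' @param phi_b baseline expression level (the value ramped from/back to).
#' @param phi_w perturbation width (peak is `phi_b + phi_w`).
#' @param phi_d duration in steps (>= 1).
#' @param phi_p peak-hold steps (trapezium only; `1 <= phi_p <= phi_d`).
#' @param start first simulated time step (1-based column index in the
#'   trace) at which the override applies.
#' @param g_max the gene's maximum observed expression (upper bound for the
#'   perturbed values).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("instant", "trapezium"), gene_index,
                              phi_b, phi_w, phi_d, phi_p = NULL,
                              start = 1L, g_max = 1) {
  kind <- match.arg(kind)
  if (phi_d < 1L) stop("phi_d must be >= 1")
  if (phi_b < 0 || phi_b + phi_w > g_max + 1e-12)
    stop(sprintf("perturbation range [%.4g, %.4g] outside [0, g_max = %.4g]",
                 phi_b, phi_b + phi_w, g_max))
  if (kind == "trapezium") {
    if (is.null(phi_p)) stop("trapezium perturbation requires phi_p")
    if (phi_p < 1L || phi_p > phi_d) stop("phi_p must satisfy 1 <= phi_p <= phi_d")
  }
  structure(list(kind = kind, gene_index = as.integer(gene_index),
                 phi_b = phi_b, phi_w = phi_w,
                 phi_d = as.integer(phi_d),
                 phi_p = if (is.null(phi_p)) NULL else as.integer(phi_p),
                 start = as.integer(start), g_max = g_max),
            class = "perturbation_spec")
}

#' Evaluate a perturbation function at a step offset
#'
#' @param spec a [perturbation_spec()].
#' @param s integer step offset within the perturbation, `0 <= s < phi_d`
#'   (vectorized).
#' @return The overridden expression value(s).
#' @export
perturbation_value <- function(spec, s) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (any(s < 0L | s >= spec$phi_d))
    stop(sprintf("step offset out of range [0, %d)", spec$phi_d))
  if (spec$kind == "instant") return(rep(spec$phi_b + spec$phi_w, length(s)))
  ramp <- (spec$phi_d - spec$phi_p) %/% 2L  # remainder widens the plateau
  up <- s < ramp
  down <- s >= spec$phi_d - ramp
  val <- rep(spec$phi_b + spec$phi_w, length(s))
  if (ramp > 0L) {
    val[up] <- spec$phi_b + spec$phi_w * (s[up] + 1) / ramp
    val[down] <- spec$phi_b + spec$phi_w * (spec$phi_d - s[down] - 1) / ramp
  }
  val
}

#' Advance the environment one step
#'
#' Synchronous update: every agent computes its forecast from the same
#' pre-step state matrix; then any overridden genes are forced to their
#' override values; the state matrix shifts one column left and the new
#' state-of-the-environment vector is appended as the newest column.
#'
#' @param agents list of `aes_agent`, one per gene, in gene order.
#' @param state n x m state matrix (columns oldest to newest).
#' @param overrides optional named numeric vector: element `i` forces gene
#'   `as.integer(names(overrides))[i]`'s new value (perturbed genes bypass
#'   their agents).
#' @param clip length-2 numeric bounds applied to agent outputs (default
#'   `c(0, 1.5)`), or `NULL` for no clipping. Overrides are not clipped.
#' @return A list: `state` (shifted matrix) and `x` (the new expression
#'   vector).
#' @export
step_aes <- function(agents, state, overrides = NULL, clip = c(0, 1.5)) {
  n <- nrow(state)
  if (length(agents) != n)
    stop(sprintf("%d agents for %d genes", length(agents), n))
  x_new <- vapply(agents, function(a) predict(a, state), numeric(1))
  if (!all(is.finite(x_new))) {
    bad <- which(!is.finite(x_new))
    stop(sprintf("non-finite agent output for gene(s) %s",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(clip)) x_new <- pmin(pmax(x_new, clip[1L]), clip[2L])
  if (!is.null(overrides) && length(overrides)) {
    idx <- as.integer(names(overrides))
    x_new[idx] <- as.numeric(overrides)
  }
  new_state <- cbind(state[, -1L, drop = FALSE], x_new, deparse.level = 0)
  rownames(new_state) <- rownames(state)
  list(state = new_state, x = x_new)
}

#' Simulate the environment over time
#'
#' Runs the closed loop for `steps` total time steps. The first m columns of
#' the returned trace are the seeded initial state; every later column is
#' produced by [step_aes()]. Perturbations are applied by overriding the
#' perturbed gene's value with [perturbation_value()] while
#' `start <= t < start + phi_d` (t being the 1-based trace column).
#'
#' @param agents list of `aes_agent`, one per gene.
#' @param init_state n x m initial state matrix.
#' @param steps total trace length (>= m).
#' @param perturbations list of [perturbation_spec()] (at most one per gene).
#' @param clip see [step_aes()].
#' @return An object of class `simulation_trace`: an n x steps matrix with
#'   attribute `perturbations` (list of the applied specs) and `m`.
#' @export
simulate_aes <- function(agents, init_state, steps, perturbations = list(),
                         clip = c(0, 1.5)) {
  m <- ncol(init_state)
  n <- nrow(init_state)
  if (steps < m) stop("steps must be at least the window length m")
  if (inherits(perturbations, "perturbation_spec"))
    perturbations <- list(perturbations)
  trace <- matrix(NA_real_, n, steps,
                  dimnames = list(rownames(init_state), NULL))
  trace[, seq_len(m)] <- init_state
  state <- init_state
  t <- m
  while (t < steps) {
    t <- t + 1L
    overrides <- NULL
    for (p in perturbations) {
      s <- t - p$start
      if (s >= 0L && s < p$phi_d) {
        v <- perturbation_value(p, s)
        overrides <- c(overrides, stats::setNames(v, p$gene_index))
      }
    }
    res <- step_aes(agents, state, overrides = overrides, clip = clip)
    if (!all(is.finite(res$x)))
      stop(sprintf("non-finite state at simulated step %d", t))
    state <- res$state
    trace[, t] <- res$x
  }
  structure(trace, class = c("simulation_trace", class(trace)),
            perturbations = perturbations, m = m)
}

#' Write a simulation trace as expression TSV
#'
#' The trace is stored in the input dialect (observations x genes, gene-name
#' header); a JSON sidecar (`<path>.json`) records the window length and any
#' perturbation windows.
#'
#' @param trace a `simulation_trace`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  ds <- expression_dataset(list(t(unclass(trace))),
                           gene_names = rownames(trace) %||%
                             paste0("G", seq_len(nrow(trace))))
  write_expression(ds, path)
  perts <- lapply(attr(trace, "perturbations"), function(p)
    p[c("kind", "gene_index", "phi_b", "phi_w", "phi_d", "phi_p", "start")])
  jsonlite::write_json(list(m = attr(trace, "m"), perturbations = perts),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
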