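#' Run the environment to a steady state
#'
#' Simulates the closed loop until every gene's range over the last `window`
#' values falls below `eps`, then verifies stability for m further steps
#' (each moving by less than `eps`); a candidate that still drifts resumes
#' the search from the probed state. The returned snapshot is the state
#' matrix at the convergence time t_f, so a subsequent recording that starts
#' at t_f replays the verification steps deterministically.
#'
#' @param agents list of `aes_agent`, one per gene.
#' @param init_state n x m initial state matrix.
#' @param eps convergence tolerance on the per-gene range (default 1e-3).
#' @param window number of trailing values over which the range is taken
#'   (default m).
#' @param t_max maximum simulated steps before giving up (default 500).
#' @param clip see [step_aes()].
#' @return A list: `state` (n x m snapshot at t_f), `t_f` (steps simulated),
#'   `converged` (logical; `FALSE` when `t_max` was hit, with a warning).
#' @export
run_to_steady_state <- function(agents, init_state, eps = 1e-3,
                                window = ncol(init_state), t_max = 500L,
                                clip = c(0, 1.5)) {
  stopifnot(eps > 0, window >= 2L)
  m <- ncol(init_state)
  state <- init_state
  recent <- init_state  # last max(window, m) values per gene
  keep <- max(window, m)
  t <- m
  converged <- FALSE
  advance <- function(state, t) {
    res <- step_aes(agents, state, clip = clip)
    if (!all(is.finite(res$x)))
      stop(sprintf("divergent trajectory at step %d", t))
    res$state
  }
  while (t < t_max) {
    rng <- apply(recent[, (ncol(recent) - window + 1L):ncol(recent),
                        drop = FALSE], 1L, function(v) diff(range(v)))
    if (max(rng) < eps) {
      # candidate steady state: verify that m further steps each move by
      # less than eps; if the environment still drifts, keep searching from
      # the probed state
      probe <- state
      stable <- TRUE
      taken <- 0L
      for (s in seq_len(m)) {
        if (t + s > t_max) { stable <- FALSE; break }
        nxt <- advance(probe, t + s)
        taken <- s
        if (max(abs(nxt[, m] - probe[, m])) >= eps) stable <- FALSE
        probe <- nxt
        if (!stable) break
      }
      if (stable) { converged <- TRUE; break }
      if (taken > 0L) {
        state <- probe
        t <- t + taken
        recent <- cbind(recent, probe[, (m - taken + 1L):m, drop = FALSE])
        recent <- recent[, (ncol(recent) - keep + 1L):ncol(recent), drop = FALSE]
      }
      if (t >= t_max) break
      next
    }
    t <- t + 1L
    state <- advance(state, t)
    recent <- cbind(recent, state[, m])
    if (ncol(recent) > keep)
      recent <- recent[, (ncol(recent) - keep + 1L):ncol(recent), drop = FALSE]
  }
  if (!converged)
    warning(sprintf("no steady state within t_max = %d steps", t_max))
  list(state = state, t_f = t, converged = converged)
}

#' Perturb one gene and record the response
#'
#' From a stabilized snapshot, simulates m unperturbed steps (the stability
#' window), phi_d perturbed steps during which the gene's value is forced by
#' the perturbation function, and m recovery steps, recording all genes over
#' the whole instability interval of `2m + phi_d` steps.
#'
#' @param agents list of `aes_agent`.
#' @param snapshot n x m state matrix from [run_to_steady_state()].
#' @param spec a [perturbation_spec()]; its `start` is set internally so the
#'   perturbation begins after the stability window.
#' @param clip see [step_aes()].
#' @return A `(2m + phi_d) x n` matrix of recorded expression (rows = steps
#'   after t_f, columns = genes).
#' @export
perturb_and_record <- function(agents, snapshot, spec, clip = c(0, 1.5)) {
  stopifnot(inherits(spec, "perturbation_spec"))
  m <- ncol(snapshot)
  dt_r <- 2L * m + spec$phi_d
  spec$start <- as.integer(m + m + 1L)  # seed columns + stability window
  trace <- simulate_aes(agents, snapshot, m + dt_r, perturbations = list(spec),
                        clip = clip)
  Xr <- t(unclass(trace)[, (m + 1L):(m + dt_r), drop = FALSE])
  colnames(Xr) <- rownames(snapshot)
  Xr
}

#' Regulatory value of a response trajectory
#'
#' The arctangent of the ordinary-least-squares slope of the recorded
#' expression against the step index `0..length-1`. A constant trajectory
#' gives exactly 0; all values lie in (-pi/2, pi/2).
#'
#' @param x numeric vector: one gene's recorded response over the
#'   instability interval.
#' @return The regulatory value in radians.
#' @export
regulatory_value <- function(x) {
  stopifnot(length(x) >= 2L)
  t_idx <- seq_along(x) - 1
  slope <- sum((t_idx - mean(t_idx)) * (x - mean(x))) / sum((t_idx - mean(t_idx))^2)
  atan(slope)
}

#' Build the regulatory matrix by perturbing every gene
#'
#' Runs the environment to a steady state once, then, for each gene i,
#' restarts from that same snapshot, applies the perturbation, and condenses
#' gene j's recorded response into the regulatory value `r[i, j]` (row =
#' perturbed gene, column = responder). Per-gene perturbation defaults: the
#' baseline `phi_b` is the gene's value at the snapshot, the width `phi_w`
#' is half its maximum observed expression (capped so the peak stays within
#' the observed maximum), and the duration `phi_d` is m.
#'
#' @param agents list of `aes_agent`.
#' @param init_state n x m initial state matrix (typically the evaluation
#'   target's first m observations).
#' @param g_max per-gene maximum observed expression (length n).
#' @param kind perturbation shape, `"trapezium"` (default) or `"instant"`.
#' @param phi_p trapezium peak-hold steps (default 2).
#' @param phi_d perturbation duration (default m).
#' @param eps,t_max steady-state controls, see [run_to_steady_state()].
#' @param clip see [step_aes()].
#' @return A list of class `regulatory_matrix_result`: `R` (n x n signed
#'   matrix in radians), `snapshot`, `t_f`, `converged`, `specs` (the
#'   perturbation used per gene).
#' @export
build_regulatory_matrix <- function(agents, init_state, g_max,
                                    kind = c("trapezium", "instant"),
                                    phi_p = 2L, phi_d = ncol(init_state),
                                    eps = 1e-3, t_max = 500L,
                                    clip = c(0, 1.5)) {
  kind <- match.arg(kind)
  n <- nrow(init_state)
  stopifnot(length(g_max) == n)
  ss <- run_to_steady_state(agents, init_state, eps = eps, t_max = t_max,
                            clip = clip)
  baseline <- ss$state[, ncol(ss$state)]
  R <- matrix(NA_real_, n, n,
              dimnames = list(rownames(init_state), rownames(init_state)))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    phi_b <- min(max(baseline[i], 0), g_max[i])
    phi_w <- min(g_max[i] / 2, g_max[i] - phi_b)
    specs[[i]] <- perturbation_spec(kind, gene_index = i, phi_b = phi_b,
                                    phi_w = phi_w, phi_d = phi_d,
                                    phi_p = if (kind == "trapezium") phi_p else NULL,
                                    g_max = g_max[i])
    Xr <- perturb_and_record(agents, ss$state, specs[[i]], clip = clip)
    R[i, ] <- apply(Xr, 2L, regulatory_value)
  }
  structure(list(R = R, snapshot = ss$state, t_f = ss$t_f,
                 converged = ss$converged, specs = specs),
            class = "regulatory_matrix_result")
}

#' Per-gene activation/inhibition thresholds
#'
#' For each responder gene j (column of the regulatory matrix): the
#' activation threshold is the median of the strictly positive regulatory
#' values in that column, the inhibition threshold the median of the
#' strictly negative ones, and the column max/min bound the outer linear
#' pieces of the probability transform. A column with no positive (or no
#' negative) entries gets a degenerate placeholder threshold and the
#' corresponding side of the transform collapses to probability 0, with a
#' warning.
#'
#' @param R n x n regulatory matrix (signed, radians).
#' @return A list of class `threshold_set` with per-column vectors `tau_p`,
#'   `tau_n`, `r_max`, `r_min`, and logical vectors `pos_degenerate`,
#'   `neg_degenerate`.
#' @export
thresholds <- function(R) {
  stopifnot(is.matrix(R), all(is.finite(R)))
  n <- ncol(R)
  tau_p <- tau_n <- r_max <- r_min <- numeric(n)
  pos_deg <- neg_deg <- logical(n)
  for (j in seq_len(n)) {
    col <- R[, j]
    pos <- col[col > 0]; neg <- col[col < 0]
    pos_deg[j] <- length(pos) == 0L
    neg_deg[j] <- length(neg) == 0L
    tau_p[j] <- if (pos_deg[j]) .Machine$double.eps else stats::median(pos)
    tau_n[j] <- if (neg_deg[j]) -.Machine$double.eps else stats::median(neg)
    # when the extremum coincides with the threshold the outer linear branch
    # would be degenerate; fall back to the arctangent's range bound
    r_max[j] <- if (max(col) > tau_p[j]) max(col) else pi / 2
    r_min[j] <- if (min(col) < tau_n[j]) min(col) else -pi / 2
  }
  if (any(pos_deg | neg_deg))
    warning(sprintf("degenerate threshold column(s): %s",
                    paste(which(pos_deg | neg_deg), collapse = ", ")))
  structure(list(tau_p = tau_p, tau_n = tau_n, r_max = r_max, r_min = r_min,
                 pos_degenerate = pos_deg, neg_degenerate = neg_deg,
                 gene_names = colnames(R)),
            class = "threshold_set")
}

#' Transform a regulatory value into an edge probability
#'
#' Piecewise map calibrated by the responder gene's thresholds: linear from
#' 1 at `r_min` down to 1/2 at the inhibition threshold `tau_n`; a quadratic
#' through 1/2 at both thresholds and 0 at r = 0 in between; linear from 1/2
#' at the activation threshold `tau_p` up to 1 at `r_max`. When
#' `|tau_p| != |tau_n|` the quadratic dips below zero on part of the inner
#' interval, so the value is clamped to \[0, 1\]. Values of r outside
#' `[r_min, r_max]` are clamped with a warning.
#'
#' @param r regulatory value(s), vectorized.
#' @param tau_p,tau_n activation (> 0) / inhibition (< 0) thresholds.
#' @param r_max,r_min outer calibration bounds
#'   (`r_min <= tau_n < 0 < tau_p <= r_max`).
#' @return Probability value(s) in \[0, 1\].
#' @export
edge_probability <- function(r, tau_p, tau_n, r_max, r_min) {
  stopifnot(tau_n < 0, tau_p > 0, r_min <= tau_n, tau_p <= r_max)
  if (any(r < r_min - 1e-12 | r > r_max + 1e-12))
    warning("regulatory value outside [r_min, r_max]; clamped")
  r <- pmin(pmax(r, r_min), r_max)
  p <- ifelse(r <= tau_n,
              0.5 + 0.5 * (r - tau_n) / (r_min - tau_n),
       ifelse(r >= tau_p,
              0.5 + 0.5 * (r - tau_p) / (r_max - tau_p),
              -r^2 / (2 * tau_p * tau_n) + (tau_p + tau_n) * r / (2 * tau_p * tau_n)))
  pmin(pmax(p, 0), 1)
}

#' Build the edge-probability matrix
#'
#' Applies [edge_probability()] element-wise, calibrating each column j with
#' responder gene j's thresholds. On a column with no positive (respectively
#' negative) regulatory values, positive (negative) entries map to 0, since
#' that side of the transform has no calibration data; r = 0 always maps
#' to 0.
#'
#' @param R n x n signed regulatory matrix.
#' @param th a [thresholds()] result computed from the same R.
#' @return n x n probability matrix (class `probability_matrix`), entries in
#'   \[0, 1\], orientation `P[i, j]` = probability that gene i regulates
#'   gene j.
#' @export
build_probability_matrix <- function(R, th) {
  stopifnot(inherits(th, "threshold_set"), ncol(R) == length(th$tau_p))
  P <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
  for (j in seq_len(ncol(R))) {
    pj <- edge_probability(R[, j], th$tau_p[j], th$tau_n[j],
                           th$r_max[j], th$r_min[j])
    if (th$pos_degenerate[j]) pj[R[, j] > 0] <- 0
    if (th$neg_degenerate[j]) pj[R[, j] < 0] <- 0
    P[, j] <- pj
  }
  structure(P, class = c("probability_matrix", class(P)))
}

#' Area under the ROC curve for an edge ranking
#'
#' The probability that a randomly chosen true edge receives a higher score
#' than a randomly chosen non-edge, with ties counted one half (equivalent
#' to trapezoidal integration of the ROC curve). Computed from average
#' ranks (the Mann-Whitney statistic).
#'
#' @param P n x n probability matrix (or any score matrix).
#' @param gold a [gold_network()] over the same genes.
#' @param include_self_loops include diagonal pairs in the evaluation
#'   vector; defaults to the gold network's flag (DREAM convention: off).
#' @return AUC-ROC in \[0, 1\].
#' @export
auc_roc <- function(P, gold, include_self_loops = gold$include_self_loops) {
  stopifnot(inherits(gold, "gold_network"))
  P <- unclass(P)
  if (!all(dim(P) == dim(gold$adjacency)))
    stop("probability and gold matrices differ in size")
  mask <- if (include_self_loops) rep(TRUE, length(P))
          else as.vector(row(P) != col(P))
  scores <- as.vector(P)[mask]
  labels <- as.vector(gold$adjacency)[mask]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: gold standard has a single class")
  rk <- rank(scores)  # average ranks handle ties as 1/2
  (sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Ranked edge list from a probability matrix
#'
#' @param P n x n probability matrix.
#' @param include_self_loops keep diagonal pairs (default FALSE).
#' @return data frame `regulator`, `target`, `probability`, sorted
#'   descending.
#' @export
rank_edges <- function(P, include_self_loops = FALSE) {
  P <- unclass(P)
  genes <- rownames(P) %||% paste0("G", seq_len(nrow(P)))
  idx <- which(include_self_loops | row(P) != col(P), arr.ind = TRUE)
  out <- data.frame(regulator = genes[idx[, 1L]], target = genes[idx[, 2L]],
                    probability = P[idx])
  out[order(-out$probability, out$regulator, out$target), , drop = FALSE]
}
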