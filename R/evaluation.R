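#' Similarity and error metrics for trajectory comparison
#'
#' Per-gene metrics between a predicted trajectory `dx` and a target
#' trajectory `dy`: Pearson correlation, cosine similarity, mean-squared
#' error, and mean absolute error. `metric_pearson` returns 0 with a warning
#' when either vector has zero variance (the correlation is undefined);
#' `metric_cosine` returns 0 with a warning when either vector has zero norm.
#'
#' @param dx,dy equal-length numeric vectors (predicted / target).
#' @return A scalar metric value.
#' @export
metric_pearson <- function(dx, dy) {
  stopifnot(length(dx) == length(dy), length(dx) >= 2L)
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
    warning("zero variance: Pearson correlation undefined, returning 0")
    return(0)
  }
  stats::cor(dx, dy)
}

#' @rdname metric_pearson
#' @export
metric_cosine <- function(dx, dy) {
  stopifnot(length(dx) == length(dy))
  nx <- sqrt(sum(dx^2)); ny <- sqrt(sum(dy^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm vector: cosine similarity undefined, returning 0")
    return(0)
  }
  sum(dx * dy) / (nx * ny)
}

#' @rdname metric_pearson
#' @export
metric_mse <- function(dx, dy) {
  stopifnot(length(dx) == length(dy), length(dx) >= 1L)
  mean((dy - dx)^2)
}

#' @rdname metric_pearson
#' @export
metric_mae <- function(dx, dy) {
  stopifnot(length(dx) == length(dy), length(dx) >= 1L)
  mean(abs(dy - dx))
}

#' Average all experiments into the evaluation target
#'
#' The target trajectory the simulator is judged against is the element-wise
#' mean over all k experiments (training and held-out alike), giving one
#' n x b matrix.
#'
#' @param ds an `expression_dataset`.
#' @return n x b numeric matrix (genes x observations).
#' @export
evaluation_target <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  bs <- n_obs(ds)
  if (length(unique(bs)) != 1L)
    stop("experiments must share the same number of observations to be averaged")
  t(Reduce(`+`, ds$experiments) / n_experiments(ds))
}

#' Evaluate simulator fidelity against a target dataset
#'
#' Compares a simulated trace column-for-column with the evaluation target
#' (mean over all experiments), excluding the first m columns, which are the
#' shared initial conditions rather than predictions. Per-gene reliabilities
#' (Pearson, cosine) and errors (MSE, MAE) are averaged arithmetically into
#' the aggregate values.
#'
#' @param trace `simulation_trace` or n x b matrix of predicted expression.
#' @param target an `expression_dataset` (averaged internally) or an n x b
#'   matrix.
#' @param m number of leading seeded columns to exclude.
#' @return A list of class `evaluation_report`: aggregates `r_pearson`,
#'   `r_cosine`, `err_mse`, `err_mae` and a per-gene data frame `per_gene`.
#' @export
evaluate_aes <- function(trace, target, m) {
  dx_all <- unclass(trace)
  dy_all <- if (inherits(target, "expression_dataset")) evaluation_target(target)
            else as.matrix(target)
  if (!all(dim(dx_all) == dim(dy_all)))
    stop(sprintf("trace is %d x %d but target is %d x %d",
                 nrow(dx_all), ncol(dx_all), nrow(dy_all), ncol(dy_all)))
  b <- ncol(dx_all)
  if (m >= b) stop("m must be smaller than the trace length")
  cols <- (m + 1L):b
  n <- nrow(dx_all)
  per <- data.frame(gene = rownames(dx_all) %||% paste0("G", seq_len(n)),
                    pearson = NA_real_, cosine = NA_real_,
                    mse = NA_real_, mae = NA_real_)
  for (i in seq_len(n)) {
    dx <- dx_all[i, cols]; dy <- dy_all[i, cols]
    per$pearson[i] <- metric_pearson(dx, dy)
    per$cosine[i] <- metric_cosine(dx, dy)
    per$mse[i] <- metric_mse(dx, dy)
    per$mae[i] <- metric_mae(dx, dy)
  }
  structure(list(r_pearson = mean(per$pearson), r_cosine = mean(per$cosine),
                 err_mse = mean(per$mse), err_mae = mean(per$mae),
                 n_compared = length(cols), per_gene = per),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("AES evaluation over %d time points:\n",
                     "  R_pearson %7.3f%%   R_cosine %7.3f%%\n",
                     "  Err_MSE  %9.3e   Err_MAE  %9.3e\n"),
              x$n_compared, 100 * x$r_pearson, 100 * x$r_cosine,
              x$err_mse, x$err_mae))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path; per-gene metrics go to `<path>` with
#'   aggregates, as one JSON object.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(r_pearson = report$r_pearson, r_cosine = report$r_cosine,
         err_mse = report$err_mse, err_mae = report$err_mae,
         n_compared = report$n_compared, per_gene = report$per_gene),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
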