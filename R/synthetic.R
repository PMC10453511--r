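#' Sample a random regulatory system
#'
#' Draws an Erdos-Renyi directed network without self-loops over n genes and
#' equips it with signed interaction weights (uniform in magnitude over
#' \[0.3, 0.8\], random sign) rescaled so the weight matrix has spectral
#' radius 0.9, plus a first-order decay rate of 0.5 per step. The gold
#' standard is exactly the support of the weight matrix.
#'
#' @param n number of genes.
#' @param density edge probability in (0, 1).
#' @param seed RNG seed.
#' @return An object of class `synthetic_system`: `W` (n x n weight matrix,
#'   `W[i, j]` = effect of gene i on gene j), `decay`, `gold`
#'   (a [gold_network()]), `gene_names`, `seed`.
#' @export
sample_network <- function(n, density, seed = 1L) {
  stopifnot(n >= 2L, density > 0, density < 1)
  set.seed(seed)
  genes <- paste0("G", seq_len(n))
  for (attempt in 1:20) {
    adj <- matrix(stats::runif(n * n) < density, n, n)
    diag(adj) <- FALSE
    if (any(adj)) break
  }
  if (!any(adj)) stop("density too low: no edges after 20 attempts")
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  ne <- sum(adj)
  W[adj] <- stats::runif(ne, 0.3, 0.8) * sample(c(-1, 1), ne, replace = TRUE)
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0) W <- W * 0.9 / rho
  structure(list(W = W, decay = 0.5,
                 gold = gold_network((W != 0) * 1),
                 gene_names = genes, seed = as.integer(seed)),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf("synthetic_system: %d genes, %d edges, decay %.2f\n",
              length(x$gene_names), sum(x$W != 0), x$decay))
  invisible(x)
}

#' Simulate expression time series from a synthetic system
#'
#' Discrete-time dynamics
#' `x(t+1) = clip01((1 - decay) * x(t) + W' tanh(x(t)) + noise)`,
#' with Gaussian noise of standard deviation `sigma` and an independent
#' uniform random initial state per experiment. The saturating tanh
#' nonlinearity bounds each gene's input, and clipping keeps all values in
#' \[0, 1\], so generated datasets satisfy the normalized-expression
#' contract of the downstream pipeline while each trajectory carries
#' information about its regulators.
#'
#' @param sys a [sample_network()] system.
#' @param b observations per experiment (>= 2).
#' @param k number of experiments.
#' @param sigma noise standard deviation (expression units).
#' @param seed RNG seed (independent of the network seed).
#' @return An unnormalized `expression_dataset` (values already in \[0, 1\])
#'   with attribute `gold`, the system's gold network.
#' @export
simulate_dataset <- function(sys, b = 21L, k = 5L, sigma = 0.02, seed = 1L) {
  stopifnot(inherits(sys, "synthetic_system"), b >= 2L, k >= 1L, sigma >= 0)
  set.seed(seed)
  n <- length(sys$gene_names)
  Wt <- t(sys$W)  # x(t+1)_j sums incoming effects W[i, j] * s(x_i)
  experiments <- vector("list", k)
  for (e in seq_len(k)) {
    X <- matrix(NA_real_, b, n, dimnames = list(NULL, sys$gene_names))
    x <- stats::runif(n)
    X[1L, ] <- x
    for (t in 2:b) {
      x <- (1 - sys$decay) * x + as.vector(Wt %*% tanh(x)) +
        stats::rnorm(n, 0, sigma)
      x <- pmin(pmax(x, 0), 1)
      X[t, ] <- x
    }
    experiments[[e]] <- X
  }
  ds <- expression_dataset(experiments, gene_names = sys$gene_names)
  attr(ds, "gold") <- sys$gold
  ds
}
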