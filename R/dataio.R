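#' Expression time-series dataset
#'
#' Container for gene-expression time series grouped into experiments. Each
#' experiment is a numeric matrix with one row per observation (time point)
#' and one column per gene; all experiments share the same genes in the same
#' order. Values are arbitrary expression units before normalization and lie
#' in \[0, 1\] (for the experiments that defined the constants) afterwards.
#'
#' @param experiments list of numeric matrices, each b x n (observations x
#'   genes). Column names, when present, must agree across experiments.
#' @param gene_names character vector of gene identifiers; defaults to the
#'   column names of the first experiment, or `G1..Gn`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `gene_names`, `experiments`, `normalized`, `norm_min`, `norm_max`.
#' @export
expression_dataset <- function(experiments, gene_names = NULL) {
  if (!is.list(experiments) || length(experiments) == 0L)
    stop("`experiments` must be a non-empty list of matrices")
  experiments <- lapply(experiments, function(e) {
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    e
  })
  n <- ncol(experiments[[1L]])
  if (is.null(gene_names)) {
    gene_names <- colnames(experiments[[1L]])
    if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  }
  if (length(gene_names) != n)
    stop("length(gene_names) must equal the number of columns")
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    if (ncol(e) != n)
      stop(sprintf("experiment %d has %d genes; expected %d", i, ncol(e), n))
    cn <- colnames(e)
    if (!is.null(cn) && !identical(cn, gene_names))
      stop(sprintf("experiment %d has mismatched gene headers", i))
    colnames(experiments[[i]]) <- gene_names
  }
  structure(
    list(gene_names = gene_names, experiments = experiments,
         normalized = FALSE, norm_min = NULL, norm_max = NULL),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  b <- vapply(x$experiments, nrow, integer(1))
  cat(sprintf("expression_dataset: %d genes, %d experiment(s), %s observations%s\n",
              length(x$gene_names), length(x$experiments),
              paste(unique(b), collapse = "/"),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Number of genes / experiments / observations
#'
#' @param ds an `expression_dataset`.
#' @return integer scalar (`n_obs` returns the per-experiment row counts).
#' @export
n_genes <- function(ds) length(ds$gene_names)

#' @rdname n_genes
#' @export
n_experiments <- function(ds) length(ds$experiments)

#' @rdname n_genes
#' @export
n_obs <- function(ds) vapply(ds$experiments, nrow, integer(1))

#' Read an expression time-series TSV
#'
#' Expects a UTF-8 tab-separated file with a header row of gene names and one
#' row per observation. An optional leading `Time` column (case-insensitive)
#' is checked for strict monotonicity and dropped. Blank lines separate
#' experiments within one file; alternatively several files (one experiment
#' each) may be given, in which case gene headers must agree.
#'
#' @param path character vector of one or more file paths.
#' @return An (unnormalized) [expression_dataset()].
#' @export
read_expression <- function(path) {
  blocks <- list()
  header <- NULL
  for (p in path) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    lines <- readLines(p, encoding = "UTF-8")
    # split into blank-line-separated blocks
    grp <- cumsum(!nzchar(trimws(lines)))
    keep <- nzchar(trimws(lines))
    for (g in split(lines[keep], grp[keep])) {
      parsed <- parse_expression_block(g, p)
      if (is.null(header)) {
        header <- parsed$genes
      } else if (!identical(header, parsed$genes)) {
        stop(sprintf("mismatched gene headers in %s: expected [%s], found [%s]",
                     p, paste(header, collapse = ", "),
                     paste(parsed$genes, collapse = ", ")))
      }
      blocks[[length(blocks) + 1L]] <- parsed$values
    }
  }
  if (length(blocks) == 0L) stop("no data rows found")
  expression_dataset(blocks, gene_names = header)
}

parse_expression_block <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows in %s: row widths %s", path,
                 paste(unique(widths), collapse = ", ")))
  genes <- fields[[1L]]
  rows <- fields[-1L]
  if (length(rows) == 0L) stop(sprintf("block with header only in %s", path))
  vals <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                 nrow = length(rows), byrow = TRUE)
  if (anyNA(vals)) stop(sprintf("non-numeric expression value in %s", path))
  has_time <- tolower(genes[1L]) == "time"
  if (has_time) {
    tm <- vals[, 1L]
    if (length(tm) > 1L && any(diff(tm) <= 0))
      stop(sprintf("Time column not strictly increasing in %s", path))
    vals <- vals[, -1L, drop = FALSE]
    genes <- genes[-1L]
  }
  colnames(vals) <- genes
  list(genes = genes, values = vals)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [read_expression()]: gene-name header, one row per observation,
#' experiments separated by a single blank line. Values are written at full
#' precision so that a read/write cycle round-trips exactly.
#'
#' @param ds an `expression_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  out <- character(0)
  for (i in seq_along(ds$experiments)) {
    e <- ds$experiments[[i]]
    rows <- apply(e, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    out <- c(out, paste(ds$gene_names, collapse = "\t"), rows,
             if (i < length(ds$experiments)) "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Min-max normalize an expression dataset
#'
#' Rescales each gene to \[0, 1\] with `x' = (x - min) / (max - min)`, where
#' min and max are taken per gene over the designated training experiments
#' only. All experiments (training and evaluation alike) are transformed with
#' the same constants, so evaluation values can fall slightly outside
#' \[0, 1\]. The constants are stored on the returned object so the transform
#' can be inverted with [denormalize()]. A gene that is constant over the
#' training experiments is mapped to all zeros, with a warning.
#'
#' @param ds an unnormalized `expression_dataset`.
#' @param train_experiments integer indices of the experiments that define the
#'   normalization constants (default: all).
#' @return The normalized `expression_dataset`.
#' @export
min_max_normalize <- function(ds, train_experiments = seq_along(ds$experiments)) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$normalized) stop("dataset is already normalized")
  train <- do.call(rbind, ds$experiments[train_experiments])
  mins <- apply(train, 2L, min)
  maxs <- apply(train, 2L, max)
  const <- maxs == mins
  if (any(const)) {
    warning(sprintf("constant gene(s) mapped to zero: %s",
                    paste(ds$gene_names[const], collapse = ", ")))
  }
  span <- ifelse(const, 1, maxs - mins)
  ds$experiments <- lapply(ds$experiments, function(e) {
    e <- sweep(e, 2L, mins, "-")
    e <- sweep(e, 2L, span, "/")
    e[, const] <- 0
    e
  })
  ds$normalized <- TRUE
  ds$norm_min <- stats::setNames(mins, ds$gene_names)
  ds$norm_max <- stats::setNames(maxs, ds$gene_names)
  ds
}

#' @rdname min_max_normalize
#' @export
denormalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$normalized) stop("dataset is not normalized")
  span <- ifelse(ds$norm_max == ds$norm_min, 1, ds$norm_max - ds$norm_min)
  ds$experiments <- lapply(ds$experiments, function(e) {
    e <- sweep(e, 2L, span, "*")
    sweep(e, 2L, ds$norm_min, "+")
  })
  ds$normalized <- FALSE
  ds$norm_min <- NULL
  ds$norm_max <- NULL
  ds
}

#' Build the supervised set for one agent
#'
#' Converts a normalized dataset into the sliding-window regression problem
#' that trains gene `gene_index`'s forecaster: each input row is the state
#' matrix over a window of `m` consecutive observations, flattened gene-major
#' (gene 1's m lags oldest-first, then gene 2's, ...), and the target is that
#' gene's value one step after the window. Each experiment of b observations
#' contributes `b - m` rows; windows never straddle experiment boundaries.
#'
#' @param ds a normalized `expression_dataset`.
#' @param gene_index integer in `1..n`: the gene whose next value is the target.
#' @param m window length (number of time steps the agents see).
#' @param experiments which experiments to use (default: all).
#' @return A list of class `supervised_set`: `inputs` ((b-m)k x nm matrix),
#'   `targets` (numeric), `gene_index`, `m`, `n`.
#' @export
make_supervised <- function(ds, gene_index, m,
                            experiments = seq_along(ds$experiments)) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$normalized) stop("normalize the dataset before windowing")
  n <- n_genes(ds)
  if (gene_index < 1L || gene_index > n) stop("gene_index out of range")
  bs <- n_obs(ds)[experiments]
  if (m < 1L || any(m >= bs))
    stop(sprintf("window m=%d must satisfy 1 <= m < b for every experiment", m))
  X <- list(); y <- list()
  for (e in ds$experiments[experiments]) {
    b <- nrow(e)
    rows <- t(vapply(seq_len(b - m), function(t0)
      as.vector(e[t0:(t0 + m - 1L), , drop = FALSE]), numeric(n * m)))
    X[[length(X) + 1L]] <- rows
    y[[length(y) + 1L]] <- e[(m + 1L):b, gene_index]
  }
  structure(list(inputs = do.call(rbind, X), targets = unlist(y, use.names = FALSE),
                 gene_index = as.integer(gene_index), m = as.integer(m),
                 n = as.integer(n)),
            class = "supervised_set")
}

#' Gold-standard regulatory network
#'
#' A directed 0/1 adjacency over named genes: `adjacency[i, j] == 1` means
#' gene i regulates gene j. Unlisted pairs are absent (0).
#'
#' @param adjacency n x n 0/1 matrix, dimnames = gene names.
#' @param include_self_loops logical; whether diagonal entries take part in
#'   evaluation (DREAM gold standards exclude them).
#' @return An object of class `gold_network`.
#' @export
gold_network <- function(adjacency, include_self_loops = FALSE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("labels must be 0 or 1")
  if (is.null(rownames(adjacency)))
    rownames(adjacency) <- colnames(adjacency) <- paste0("G", seq_len(nrow(adjacency)))
  structure(list(adjacency = adjacency,
                 gene_names = rownames(adjacency),
                 include_self_loops = isTRUE(include_self_loops)),
            class = "gold_network")
}

#' Read a gold-standard network edge list
#'
#' Reads the 3-column DREAM layout `regulator<TAB>target<TAB>label` with
#' labels in \{0, 1\}. Pairs not listed default to 0. Self-loop rows are kept
#' in the adjacency but excluded from evaluation unless
#' `include_self_loops = TRUE` (a warning notes their presence).
#'
#' @param path edge-list file path.
#' @param gene_names the full gene universe; rows naming unknown genes are an
#'   error.
#' @param include_self_loops logical, see [gold_network()].
#' @return A `gold_network`.
#' @export
read_gold_network <- function(path, gene_names, include_self_loops = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("regulator", "target", "label"),
                           colClasses = c("character", "character", "numeric"))
  unknown <- setdiff(unique(c(tab$regulator, tab$target)), gene_names)
  if (length(unknown))
    stop(sprintf("unknown gene name(s) in gold network: %s",
                 paste(unknown, collapse = ", ")))
  if (!all(tab$label %in% c(0, 1)))
    stop("gold-network labels must be 0 or 1")
  n <- length(gene_names)
  adj <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  adj[cbind(match(tab$regulator, gene_names), match(tab$target, gene_names))] <- tab$label
  if (!include_self_loops && any(diag(adj) != 0))
    warning("self-loop labels present; retained but excluded from evaluation")
  gold_network(adj, include_self_loops = include_self_loops)
}

#' Write a gold-standard network edge list
#'
#' @param gold a `gold_network`.
#' @param path output file path.
#' @param positives_only write only label-1 rows (default), matching the
#'   DREAM convention that absent pairs are negatives.
#' @return `path`, invisibly.
#' @export
write_gold_network <- function(gold, path, positives_only = TRUE) {
  stopifnot(inherits(gold, "gold_network"))
  idx <- which(if (positives_only) gold$adjacency == 1 else !is.na(gold$adjacency),
               arr.ind = TRUE)
  tab <- data.frame(regulator = gold$gene_names[idx[, 1L]],
                    target = gold$gene_names[idx[, 2L]],
                    label = gold$adjacency[idx])
  tab <- tab[order(tab$regulator, tab$target), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
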