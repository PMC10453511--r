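#' Agent architecture specification
#'
#' Describes one per-gene forecaster: which of the three architectures it
#' uses and the tunable hyperparameters of that architecture. The fixed
#' skeletons are:
#'
#' * `FCNN` - three dense+activation blocks (widths/activations tunable) with
#'   one dropout layer after the first block, then a scalar output.
#' * `CNN` - Conv1D (64 filters, kernel 2, over the m time steps with genes
#'   as channels; left zero-padding preserves the sequence length),
#'   activation, MaxPool1D (pool 2), two dense blocks with dropout, scalar
#'   output.
#' * `RNN` - an LSTM block (last hidden state), activation, two dense blocks
#'   with dropout, scalar output.
#'
#' @param architecture one of `"FCNN"`, `"CNN"`, `"RNN"`.
#' @param widths integer vector of dense-layer widths (3 for FCNN, 2 for
#'   CNN/RNN).
#' @param activations character vector of activation names (`relu`, `tanh`,
#'   `sigmoid`), recycled to the number of activation slots.
#' @param dropout dropout rate in \[0, 0.5\].
#' @param lstm_units LSTM state size (RNN only).
#' @param learning_rate Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without held-out
#'   improvement).
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(architecture = c("FCNN", "CNN", "RNN"),
                       widths = NULL,
                       activations = "relu",
                       dropout = 0.1,
                       lstm_units = 32L,
                       learning_rate = 1e-2,
                       epochs = 300L,
                       patience = 20L) {
  architecture <- match.arg(architecture)
  n_dense <- if (architecture == "FCNN") 3L else 2L
  if (is.null(widths)) widths <- c(64L, 32L, 16L)[seq_len(n_dense)]
  if (length(widths) != n_dense)
    stop(sprintf("%s needs %d dense widths, got %d", architecture, n_dense,
                 length(widths)))
  n_act <- if (architecture == "FCNN") 3L else 3L  # CNN/RNN: 1 post-feature + 2 dense
  activations <- rep_len(activations, n_act)
  bad <- setdiff(activations, setdiff(ACTIVATIONS, "linear"))
  if (length(bad)) stop(sprintf("unknown activation(s): %s", paste(bad, collapse = ", ")))
  if (dropout < 0 || dropout > 0.5) stop("dropout must lie in [0, 0.5]")
  structure(list(architecture = architecture,
                 widths = as.integer(widths),
                 activations = activations,
                 dropout = dropout,
                 lstm_units = as.integer(lstm_units),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience)),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("agent_spec: %s | widths %s | act %s | dropout %.3f | lr %.2g%s\n",
              x$architecture, paste(x$widths, collapse = "/"),
              paste(x$activations, collapse = "/"), x$dropout, x$learning_rate,
              if (x$architecture == "RNN") sprintf(" | lstm %d", x$lstm_units) else ""))
  invisible(x)
}

#' Build an untrained network for a spec
#'
#' Instantiates the layer stack for `spec` with freshly initialized weights
#' (Glorot-uniform; draws from the current RNG stream, so call behind
#' `set.seed()` for reproducibility).
#'
#' @param spec an [agent_spec()].
#' @param n number of genes (input channels).
#' @param m window length (time steps seen by the agent).
#' @return A model object accepted by the internal forward/backward engine.
#' @export
build_model <- function(spec, n, m) {
  stopifnot(inherits(spec, "agent_spec"))
  input_dim <- n * m
  layers <- switch(spec$architecture,
    FCNN = list(
      layer_dense(input_dim, spec$widths[1L]),
      layer_act(spec$activations[1L]),
      layer_dropout(spec$dropout),
      layer_dense(spec$widths[1L], spec$widths[2L]),
      layer_act(spec$activations[2L]),
      layer_dense(spec$widths[2L], spec$widths[3L]),
      layer_act(spec$activations[3L]),
      layer_dense(spec$widths[3L], 1L)),
    CNN = {
      if (m < 2L) stop("CNN requires a window of at least 2 steps")
      t_pool <- m %/% 2L  # left-padded kernel-2 conv preserves length; pool 2
      list(
        layer_reshape3d(m, n),
        layer_pad1d(1L),
        layer_conv1d(n, 64L, 2L),
        layer_act(spec$activations[1L]),
        layer_maxpool1d(2L),
        layer_flatten(),
        layer_dense(t_pool * 64L, spec$widths[1L]),
        layer_act(spec$activations[2L]),
        layer_dropout(spec$dropout),
        layer_dense(spec$widths[1L], spec$widths[2L]),
        layer_act(spec$activations[3L]),
        layer_dense(spec$widths[2L], 1L))
    },
    RNN = list(
      layer_reshape3d(m, n),
      layer_lstm(n, spec$lstm_units),
      layer_act(spec$activations[1L]),
      layer_dense(spec$lstm_units, spec$widths[1L]),
      layer_act(spec$activations[2L]),
      layer_dropout(spec$dropout),
      layer_dense(spec$widths[1L], spec$widths[2L]),
      layer_act(spec$activations[3L]),
      layer_dense(spec$widths[2L], 1L)),
    stop(sprintf("unknown architecture '%s'", spec$architecture)))
  list(arch = spec$architecture, layers = layers, n = n, m = m,
       input_dim = input_dim)
}

#' Train one agent
#'
#' Fits the network described by `spec` to a supervised set with full-batch
#' Adam on the mean-squared error, using a chronological 80/20 train/test
#' split and early stopping on the held-out error (the weights with the best
#' held-out error are kept). Training is deterministic given `seed`.
#'
#' @param spec an [agent_spec()].
#' @param supervised a `supervised_set` from [make_supervised()].
#' @param seed integer RNG seed controlling initialization and dropout.
#' @return An object of class `aes_agent` with elements `spec`, `gene_index`,
#'   `model`, `train_error`, `test_error`.
#' @export
train_agent <- function(spec, supervised, seed = 1L) {
  stopifnot(inherits(spec, "agent_spec"), inherits(supervised, "supervised_set"))
  X <- supervised$inputs
  y <- supervised$targets
  if (nrow(X) < 2L) stop("supervised set needs at least 2 samples")
  n_train <- max(1L, floor(0.8 * nrow(X)))
  if (n_train == nrow(X)) n_train <- nrow(X) - 1L
  idx_tr <- seq_len(n_train)
  idx_te <- (n_train + 1L):nrow(X)
  set.seed(seed)
  model <- build_model(spec, supervised$n, supervised$m)
  state <- adam_init(model)
  best <- list(model = model, test = Inf, train = Inf)
  stale <- 0L
  for (ep in seq_len(spec$epochs)) {
    lg <- nn_loss_grads(model, X[idx_tr, , drop = FALSE], y[idx_tr],
                        training = TRUE)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite training loss at epoch %d (gene %d, %s)",
                   ep, supervised$gene_index, spec$architecture))
    upd <- adam_step(model, lg$grads, state, spec$learning_rate, ep)
    model <- upd$model
    state <- upd$state
    pred_te <- nn_predict(model, X[idx_te, , drop = FALSE])
    test_mse <- mean((pred_te - y[idx_te])^2)
    if (test_mse < best$test) {
      best <- list(model = model, test = test_mse, train = lg$loss)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= spec$patience) break
    }
  }
  structure(list(spec = spec, gene_index = supervised$gene_index,
                 model = best$model,
                 train_error = best$train, test_error = best$test),
            class = "aes_agent")
}

#' @export
print.aes_agent <- function(x, ...) {
  cat(sprintf("aes_agent: gene %d, %s, test MSE %.3g\n",
              x$gene_index, x$spec$architecture, x$test_error))
  invisible(x)
}

#' Stub agent with a user-supplied forecast rule
#'
#' Builds an agent whose prediction is an arbitrary function of the state
#' matrix instead of a trained network. Used for closed-form tests of the
#' simulator and of the inference pipeline.
#'
#' @param gene_index gene the stub regulates.
#' @param fun function of one argument, the n x m state matrix, returning a
#'   scalar.
#' @return An `aes_agent`.
#' @export
stub_agent <- function(gene_index, fun) {
  structure(list(spec = NULL, gene_index = as.integer(gene_index),
                 model = NULL, fun = fun,
                 train_error = NA_real_, test_error = NA_real_),
            class = "aes_agent")
}

#' Forecast one gene's next expression value
#'
#' Applies the agent's learned map to a state matrix (n genes x m time
#' steps, columns oldest to newest), flattened gene-major. Deterministic:
#' dropout is inactive at prediction time.
#'
#' @param object an `aes_agent`.
#' @param state n x m numeric state matrix.
#' @param ... unused.
#' @return A finite scalar: the predicted expression at the next step.
#' @export
predict.aes_agent <- function(object, state, ...) {
  if (!is.null(object$fun)) return(object$fun(state))
  if (!is.matrix(state) ||
      nrow(state) != object$model$n || ncol(state) != object$model$m)
    stop(sprintf("state matrix must be %d x %d, got %d x %d",
                 object$model$n, object$model$m,
                 NROW(state), NCOL(state)))
  nn_predict(object$model, matrix(flatten_state(state), 1L))
}

# gene-major, oldest lag first: gene 1's m values, then gene 2's, ...
flatten_state <- function(state) as.vector(t(state))

#' The declared hyperparameter search space
#'
#' Dense widths are drawn from \{16, 32, 64, 128\}, activations from
#' \{relu, tanh, sigmoid\}, dropout uniformly from \[0, 0.5\], LSTM units
#' from \{16, 32, 64\}, and the learning rate log-uniformly from
#' \[1e-4, 1e-2\].
#'
#' @param architecture architecture to sample a spec for.
#' @return A randomly drawn [agent_spec()] (uses the current RNG stream).
#' @export
sample_agent_spec <- function(architecture = c("FCNN", "CNN", "RNN")) {
  architecture <- match.arg(architecture)
  n_dense <- if (architecture == "FCNN") 3L else 2L
  agent_spec(architecture,
             widths = sample(c(16L, 32L, 64L, 128L), n_dense, replace = TRUE),
             activations = sample(c("relu", "tanh", "sigmoid"), 3L, replace = TRUE),
             dropout = stats::runif(1, 0, 0.5),
             lstm_units = sample(c(16L, 32L, 64L), 1L),
             learning_rate = 10^stats::runif(1, -4, -2))
}

#' Random-search hyperparameter tuning
#'
#' Draws `budget` specs from the declared search space, trains each on the
#' supervised set, and returns the spec with the lowest held-out error (ties
#' broken in favor of the first evaluated). With `budget = 0` the default
#' spec for the architecture is returned untrained.
#'
#' @param architecture one of `"FCNN"`, `"CNN"`, `"RNN"`.
#' @param supervised a `supervised_set`.
#' @param budget number of random trials (>= 1; 0 short-circuits to the
#'   default spec).
#' @param seed integer RNG seed; trial t trains with seed `seed + t`.
#' @return A list: `spec` (winning [agent_spec()]), `agent` (its trained
#'   agent, `NULL` when `budget = 0`), `trials` (data frame of the search
#'   history).
#' @export
tune_hyperparameters <- function(architecture, supervised, budget = 10L,
                                 seed = 1L) {
  if (budget == 0L)
    return(list(spec = agent_spec(architecture), agent = NULL,
                trials = data.frame()))
  if (budget < 0L) stop("budget must be >= 0")
  specs <- vector("list", budget)
  set.seed(seed)
  for (t in seq_len(budget)) specs[[t]] <- sample_agent_spec(architecture)
  agents <- vector("list", budget)
  errs <- numeric(budget)
  for (t in seq_len(budget)) {
    agents[[t]] <- train_agent(specs[[t]], supervised, seed = seed + t)
    errs[t] <- agents[[t]]$test_error
  }
  best <- which.min(errs)  # which.min takes the first minimum: ties -> first
  list(spec = specs[[best]], agent = agents[[best]],
       trials = data.frame(trial = seq_len(budget),
                           architecture = architecture,
                           test_error = errs))
}
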