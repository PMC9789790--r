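#' Train a single-bottleneck autoencoder on spot expression profiles
#'
#' A three-layer network (input, one hidden bottleneck, output) trained to
#' reconstruct its input under mean-squared error:
#' hidden = act(x W1 + b1), reconstruction = hidden W2 + b2. The default
#' activation is ReLU on the hidden layer with a linear output; `"linear"`
#' makes the whole map linear (then the optimum coincides with the leading
#' principal subspace, which is what the SVD ablation uses directly).
#' Optimization is mini-batched Adam with deterministic, seeded shuffling.
#'
#' @param x Numeric matrix of rows to reconstruct (all spots, normalized).
#' @param hidden_dim Bottleneck width `g_a`.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the data; `0` returns untrained
#'   weights and an empty loss log.
#' @param learning_rate Adam step size.
#' @param activation `"relu"` or `"linear"` hidden activation.
#' @param seed Integer seed controlling init and shuffling.
#' @return Object of class `autoencoder`: weights `W1, b1, W2, b2`,
#'   `activation`, `input_dim`, `hidden_dim`, and `loss_log` (tibble with
#'   `epoch` and full-data reconstruction `mse` after that epoch).
#' @export
train_autoencoder <- function(x, hidden_dim = 200, batch_size = 300,
                              epochs = 5, learning_rate = 1e-3,
                              activation = c("relu", "linear"), seed = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to train")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  d <- ncol(x)
  if (hidden_dim >= d) {
    warning("hidden_dim (", hidden_dim, ") >= input dimension (", d,
            "); the embedding is not compressive")
  }

  model <- withr::with_seed(seed, {
    r1 <- sqrt(6 / (d + hidden_dim))
    params <- list(
      W1 = matrix(stats::runif(d * hidden_dim, -r1, r1), d, hidden_dim),
      b1 = rep(0, hidden_dim),
      W2 = matrix(stats::runif(hidden_dim * d, -r1, r1), hidden_dim, d),
      b2 = rep(0, d)
    )
    opt <- adam_state(params, learning_rate)
    losses <- numeric(0)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(nrow(x))
        for (start in seq(1, nrow(x), by = batch_size)) {
          ix <- ord[start:min(start + batch_size - 1, nrow(x))]
          xb <- x[ix, , drop = FALSE]
          z1 <- sweep(xb %*% params$W1, 2, params$b1, "+")
          h <- if (activation == "relu") pmax(z1, 0) else z1
          xhat <- sweep(h %*% params$W2, 2, params$b2, "+")
          # d(MSE)/d(xhat), MSE averaged over all batch entries
          g_out <- 2 * (xhat - xb) / length(xb)
          grads <- list(
            W2 = crossprod(h, g_out),
            b2 = colSums(g_out),
            W1 = NULL, b1 = NULL
          )
          g_h <- g_out %*% t(params$W2)
          if (activation == "relu") g_h[z1 <= 0] <- 0
          grads$W1 <- crossprod(xb, g_h)
          grads$b1 <- colSums(g_h)
          upd <- adam_step(opt, params, grads)
          params <- upd$params
          opt <- upd$state
        }
        losses[ep] <- mean((reconstruct_ae(params, x, activation) - x)^2)
      }
    }
    list(params = params, losses = losses)
  })

  structure(
    c(model$params,
      list(activation = activation, input_dim = d, hidden_dim = hidden_dim,
           loss_log = tibble::tibble(epoch = seq_along(model$losses),
                                     mse = model$losses))),
    class = "autoencoder"
  )
}

reconstruct_ae <- function(params, x, activation) {
  z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  h <- if (activation == "relu") pmax(z1, 0) else z1
  sweep(h %*% params$W2, 2, params$b2, "+")
}

#' Embed rows with a trained autoencoder
#'
#' Applies the encoder half only: `act(x W1 + b1)`.
#'
#' @param model An `autoencoder`.
#' @param m Matrix with `model$input_dim` columns.
#' @return Matrix with `model$hidden_dim` columns; row names preserved.
#' @export
embed <- function(model, m) {
  m <- as.matrix(m)
  if (ncol(m) != model$input_dim) {
    stop("input has ", ncol(m), " columns but the model expects ",
         model$input_dim)
  }
  z1 <- sweep(m %*% model$W1, 2, model$b1, "+")
  out <- if (model$activation == "relu") pmax(z1, 0) else z1
  rownames(out) <- rownames(m)
  out
}

#' @export
print.autoencoder <- function(x, ...) {
  cat("<autoencoder> ", x$input_dim, " -> ", x$hidden_dim, " -> ",
      x$input_dim, " (", x$activation, " hidden); ",
      nrow(x$loss_log), " epochs trained\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.autoencoder <- function(x, ...) x$loss_log

#' @exportS3Method generics::glance
glance.autoencoder <- function(x, ...) {
  tibble::tibble(input_dim = x$input_dim, hidden_dim = x$hidden_dim,
                 activation = x$activation,
                 epochs = nrow(x$loss_log),
                 final_mse = if (nrow(x$loss_log)) {
                   x$loss_log$mse[nrow(x$loss_log)]
                 } else {
                   NA_real_
                 })
}

#' Linear embedding via truncated SVD
#'
#' The linear stand-in for the autoencoder used by the `"svd"` embedding
#' mode: projects rows onto the top `hidden_dim` right-singular directions
#' of the stacked data.
#'
#' @param x Matrix whose rows define the subspace.
#' @param hidden_dim Number of singular directions kept.
#' @return A list of class `svd_embedder` with the projection matrix `V`.
#' @export
fit_svd_embedder <- function(x, hidden_dim = 200) {
  k <- min(hidden_dim, ncol(x), nrow(x))
  s <- svd(x, nu = 0, nv = k)
  structure(list(V = s$v, input_dim = ncol(x), hidden_dim = k),
            class = "svd_embedder")
}

#' @rdname fit_svd_embedder
#' @param model A fitted `svd_embedder`.
#' @param m Matrix of rows to project.
#' @export
embed_svd <- function(model, m) {
  out <- as.matrix(m) %*% model$V
  rownames(out) <- rownames(m)
  out
}

# Adam optimizer over a named list of parameter arrays.
adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- state$beta1 * state$m[[nm]] +
      (1 - state$beta1) * grads[[nm]]
    state$v[[nm]] <- state$beta2 * state$v[[nm]] +
      (1 - state$beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - state$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - state$beta2^state$t)
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}
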