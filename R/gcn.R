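#' Forward pass of the graph convolutional deconvolver
#'
#' Three graph-convolution layers over the normalized adjacency:
#' \deqn{H^{(l+1)} = ReLU(\tilde A H^{(l)} W^{(l)})}
#' for the first two layers, with the third layer's output passed through a
#' row-wise softmax so each node's output is a composition over the T cell
#' types (every row sums to 1).
#'
#' @param model A `gcn_model` (weights `W0`, `W1`, `W2`).
#' @param graph A `deconvolution_graph`.
#' @return A [proportion_matrix()] over all N nodes (pseudo then real).
#' @export
gcn_forward <- function(model, graph) {
  act <- gcn_activations(model, graph)
  ids <- c(rownames(graph$labels), graph$real_ids)
  proportion_matrix(act$Yhat, ids, colnames(graph$labels))
}

# Full forward pass keeping intermediates for backprop.
gcn_activations <- function(model, graph) {
  An <- graph$A_norm
  Z1 <- as.matrix(An %*% (graph$X %*% model$W0))
  H1 <- pmax(Z1, 0)
  Z2 <- as.matrix(An %*% (H1 %*% model$W1))
  H2 <- pmax(Z2, 0)
  Z3 <- as.matrix(An %*% (H2 %*% model$W2))
  list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, Z3 = Z3, Yhat = row_softmax(Z3))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Soft-label cross-entropy, mean over the given node rows.
soft_ce <- function(yhat, y, rows, eps = 1e-9) {
  if (!length(rows)) return(NA_real_)
  -mean(rowSums(y[rows, , drop = FALSE] *
                  log(yhat[rows, , drop = FALSE] + eps)))
}

#' Train the GCN semi-supervised on pseudo-spot labels
#'
#' Full-batch training on the whole graph: the loss is the mean soft-label
#' cross-entropy \eqn{-\sum_t y_t \log(\hat y_t + \epsilon)} over the
#' labeled training pseudo-nodes (labels are proportions, not classes).
#' Adam updates, early stopping on the validation-mask loss with the given
#' patience, restoring the best weights.
#'
#' @param graph A `deconvolution_graph` with at least one training node.
#' @param lr Adam learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without a new best validation loss.
#' @param hidden_dims Widths of the two hidden graph-convolution layers.
#' @param seed Seed for weight initialization.
#' @return Object of class `gcn_model`: weights `W0..W2`, `dims`, `log`
#'   (tibble `epoch`, `train_loss`, `val_loss`), `best_epoch`.
#' @export
train_gcn <- function(graph, lr = 0.005, max_epochs = 200, patience = 10,
                      hidden_dims = c(64, 32), seed = 1) {
  if (!length(graph$masks$train)) stop("graph has no labeled training nodes")
  Tn <- ncol(graph$labels)
  d0 <- ncol(graph$X)
  dims <- c(d0, hidden_dims, Tn)
  Y <- matrix(0, nrow(graph$X), Tn)
  Y[seq_len(graph$n_pseudo), ] <- unclass(graph$labels)
  train <- graph$masks$train
  val <- graph$masks$val
  if (!length(val)) val <- train  # tiny graphs: monitor training loss

  params <- withr::with_seed(seed, {
    glorot <- function(a, b) {
      r <- sqrt(6 / (a + b))
      matrix(stats::runif(a * b, -r, r), a, b)
    }
    list(W0 = glorot(dims[1], dims[2]),
         W1 = glorot(dims[2], dims[3]),
         W2 = glorot(dims[3], dims[4]))
  })
  opt <- adam_state(params, lr)
  An <- graph$A_norm
  log_rows <- vector("list", max_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L

  for (ep in seq_len(max_epochs)) {
    model <- structure(params, class = "gcn_model")
    act <- gcn_activations(model, graph)
    n_tr <- length(train)
    # d loss / d Z3 of mean soft-label CE: (yhat - y) / n on labeled rows
    dZ3 <- matrix(0, nrow(Y), Tn)
    dZ3[train, ] <- (act$Yhat[train, , drop = FALSE] -
                       Y[train, , drop = FALSE]) / n_tr
    dZ3 <- as.matrix(An %*% dZ3)  # An is symmetric: t(An) %*% g
    grads <- list()
    grads$W2 <- crossprod(act$H2, dZ3)
    dH2 <- dZ3 %*% t(params$W2)
    dH2[act$Z2 <= 0] <- 0
    dH2 <- as.matrix(An %*% dH2)
    grads$W1 <- crossprod(act$H1, dH2)
    dH1 <- dH2 %*% t(params$W1)
    dH1[act$Z1 <= 0] <- 0
    dH1 <- as.matrix(An %*% dH1)
    grads$W0 <- crossprod(graph$X, dH1)

    train_loss <- soft_ce(act$Yhat, Y, train)
    val_loss <- soft_ce(act$Yhat, Y, val)
    if (!is.finite(train_loss)) {
      stop("non-finite training loss at epoch ", ep,
           "; check features and learning rate")
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, train_loss = train_loss,
                                     val_loss = val_loss)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    upd <- adam_step(opt, params, grads)
    params <- upd$params
    opt <- upd$state
  }

  structure(
    c(best$params,
      list(dims = dims, log = dplyr::bind_rows(log_rows),
           best_epoch = best$epoch, trained = TRUE)),
    class = "gcn_model"
  )
}

#' Initialize an untrained GCN (for inspection or manual weights)
#'
#' @param dims Layer widths `c(input, d1, d2, T)`.
#' @param seed Seed for initialization.
#' @return A `gcn_model` with empty training log.
#' @export
init_gcn <- function(dims, seed = 1) {
  params <- withr::with_seed(seed, {
    glorot <- function(a, b) {
      r <- sqrt(6 / (a + b))
      matrix(stats::runif(a * b, -r, r), a, b)
    }
    list(W0 = glorot(dims[1], dims[2]),
         W1 = glorot(dims[2], dims[3]),
         W2 = glorot(dims[3], dims[4]))
  })
  structure(c(params, list(dims = dims,
                           log = tibble::tibble(epoch = integer(0),
                                                train_loss = numeric(0),
                                                val_loss = numeric(0)),
                           best_epoch = 0L, trained = FALSE)),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat("<gcn_model> layers ", paste(x$dims, collapse = " -> "),
      if (isTRUE(x$trained)) {
        paste0("; trained ", nrow(x$log), " epochs (best ", x$best_epoch, ")")
      } else {
        "; untrained"
      }, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gcn_model <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.gcn_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log), best_epoch = x$best_epoch,
    best_val_loss = if (nrow(x$log)) min(x$log$val_loss) else NA_real_,
    final_train_loss = if (nrow(x$log)) {
      x$log$train_loss[nrow(x$log)]
    } else {
      NA_real_
    }
  )
}

#' Predict cell-type proportions for the real spots
#'
#' @param model A trained `gcn_model` (an untrained model triggers a warning;
#'   outputs are then near-uniform).
#' @param graph The `deconvolution_graph` the model was trained on.
#' @return A [proportion_matrix()] with one row per real spot.
#' @export
predict_real_proportions <- function(model, graph) {
  if (!isTRUE(model$trained)) {
    warning("model is untrained; predictions will be near-uniform")
  }
  all_props <- gcn_forward(model, graph)
  proportion_matrix(unclass(all_props)[graph$masks$real, , drop = FALSE],
                    graph$real_ids, colnames(graph$labels))
}

#' Remove implausibly small cell-type fractions
#'
#' A spot covers on the order of 10-20 cells, so a predicted fraction below
#' `threshold` (default 5%) corresponds to less than one expected cell and
#' is zeroed; each row is then renormalized to sum to 1. If every entry of a
#' row falls below the threshold, the row's maximum entry (first index on
#' ties) is kept at 1.
#'
#' @param c_mat A [proportion_matrix()].
#' @param threshold Fraction in `[0, 1)`.
#' @return The filtered [proportion_matrix()].
#' @export
filter_low_proportions <- function(c_mat, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)")
  }
  v <- unclass(c_mat)
  keep <- v >= threshold
  out <- v * keep
  rs <- rowSums(out)
  dead <- rs == 0
  if (any(dead)) {
    for (i in which(dead)) {
      out[i, which.max(v[i, ])] <- 1
    }
    rs[dead] <- 1
  }
  out <- out / rs
  proportion_matrix(out, rownames(v), colnames(v))
}
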