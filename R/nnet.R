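# Internal feed-forward machinery: a one-hidden-layer head
# (affine -> ReLU -> affine -> sigmoid), masked binary cross-entropy,
# analytic gradients, Adam, and the linear warmup/decay learning-rate
# schedule. Written with base-R matrix algebra; deliberately small, since the
# heavy lifting of representation is delegated to the encoder contract.

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style initialization for ReLU hidden layers; "zero" gives the untrained
# head whose sigmoid outputs are exactly 0.5 everywhere.
mlp_init <- function(d_in, hidden, d_out, seed = 1L, init = c("he", "zero")) {
  init <- match.arg(init)
  if (init == "zero") {
    return(list(W1 = matrix(0, d_in, hidden), b1 = numeric(hidden),
                W2 = matrix(0, hidden, d_out), b2 = numeric(d_out)))
  }
  with_seed(seed, {
    list(
      W1 = matrix(rnorm(d_in * hidden, sd = sqrt(2 / d_in)), d_in, hidden),
      b1 = numeric(hidden),
      W2 = matrix(rnorm(hidden * d_out, sd = sqrt(2 / hidden)), hidden, d_out),
      b2 = numeric(d_out)
    )
  })
}

# forward pass; X is n x d_in. Returns hidden pre-activation, hidden, probs.
mlp_forward <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  H <- pmax(Z1, 0)
  Z2 <- sweep(H %*% params$W2, 2, params$b2, `+`)
  list(Z1 = Z1, H = H, P = sigmoid(Z2))
}

# masked mean binary cross-entropy; mask is n x k of 0/1, loss averaged over
# observed entries only (absent label sources contribute exactly nothing)
bce_loss_masked <- function(P, Y, mask = NULL) {
  if (is.null(mask)) mask <- matrix(1, nrow(P), ncol(P))
  eps <- 1e-12
  n_obs <- sum(mask)
  if (n_obs == 0) return(0)
  ll <- Y * log(P + eps) + (1 - Y) * log(1 - P + eps)
  -sum(ll * mask) / n_obs
}

# analytic gradients of the masked BCE w.r.t. all parameters
mlp_grads <- function(params, X, Y, mask = NULL) {
  if (is.null(mask)) mask <- matrix(1, nrow(X), ncol(Y))
  fw <- mlp_forward(params, X)
  n_obs <- sum(mask)
  if (n_obs == 0) n_obs <- 1
  dZ2 <- (fw$P - Y) * mask / n_obs
  gW2 <- crossprod(fw$H, dZ2)
  gb2 <- colSums(dZ2)
  dH <- dZ2 %*% t(params$W2)
  dZ1 <- dH * (fw$Z1 > 0)
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       loss = bce_loss_masked(fw$P, Y, mask))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Linear warmup / linear decay learning-rate schedule
#'
#' The rate rises linearly from 0 to `base_lr` over the first
#' `warmup_frac` of training steps, peaks exactly at the warmup boundary,
#' then decays linearly to 0 at the final step.
#'
#' @param step Current step, `1..total_steps`.
#' @param total_steps Total number of optimization steps.
#' @param base_lr Peak learning rate.
#' @param warmup_frac Fraction of steps used for warmup, in (0, 1).
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, base_lr, warmup_frac) {
  stopifnot(total_steps >= 1, warmup_frac > 0, warmup_frac < 1)
  w <- max(1L, ceiling(warmup_frac * total_steps))
  if (step <= w) return(base_lr * step / w)
  if (total_steps == w) return(0)
  base_lr * (total_steps - step) / (total_steps - w)
}

# shared minibatch training loop with checkpoint-on-improvement.
# eval_fn(params) -> validation metric (higher is better) or NA to skip.
# Returns best params (by metric; final params if never evaluated), history.
train_mlp_loop <- function(params, X, Y, mask, config, eval_fn = NULL) {
  n <- nrow(X)
  epochs <- config$epochs
  bs <- config$batch_size
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- max(1L, epochs * steps_per_epoch)
  state <- adam_init(params)
  best_metric <- -Inf
  best_params <- params
  history <- list()
  step <- 0L
  if (epochs == 0) {
    return(list(params = params, best_params = params,
                history = tibble::tibble(step = integer(0), epoch = integer(0),
                                         lr = numeric(0), loss = numeric(0),
                                         val_metric = numeric(0))))
  }
  with_seed(derive_seed(config$seed, "shuffle"), {
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        idx <- perm[((b - 1L) * bs + 1L):min(b * bs, n)]
        step <- step + 1L
        lr <- lr_schedule(step, total_steps, config$learning_rate, config$warmup_frac)
        g <- mlp_grads(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                       mask[idx, , drop = FALSE])
        if (!is.finite(g$loss)) {
          abort(sprintf("non-finite training loss at step %d", step),
                class = "newswatch_training_error")
        }
        upd <- adam_step(params, g, state, lr)
        params <- upd$params
        state <- upd$state
        at_eval <- (step %% config$eval_every == 0L) ||
          (b == steps_per_epoch && epoch == epochs)
        val <- NA_real_
        if (at_eval && !is.null(eval_fn)) {
          val <- eval_fn(params)
          if (!is.na(val) && val > best_metric) {
            best_metric <- val
            best_params <- params
          }
        }
        if (at_eval || step == 1L) {
          history[[length(history) + 1L]] <-
            tibble::tibble(step = step, epoch = epoch, lr = lr,
                           loss = g$loss, val_metric = val)
        }
      }
    }
  })
  if (!is.finite(best_metric)) best_params <- params
  list(params = params, best_params = best_params,
       history = dplyr::bind_rows(history))
}
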