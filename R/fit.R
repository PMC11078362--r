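#' Trajectory training data
#'
#' Training data are snapshots of an observable field on a regular
#' time grid: an array with axes (time, batch, row, col, channel),
#' i.e. shape (M+1) x R x S x S x C_obs, where consecutive snapshots
#' are separated by `t` NCA steps (prediction step n aligns with data
#' frame m at n = m * t).
#'
#' @param y numeric 5-D array (time, batch, row, col, channel); a
#'   4-D array (time, row, col, channel) is promoted to R = 1.
#' @param t NCA steps per data interval (>= 1).
#' @param boundary boundary mode of the underlying lattice.
#' @return `y` with class `nca_training_data` and attributes `t` and
#'   `boundary`.
#' @export
training_data <- function(y, t, boundary = c("periodic", "fixed-zero")) {
  boundary <- match.arg(boundary)
  if (length(dim(y)) == 4L) {
    d <- dim(y)
    y <- array(y, c(d[1], 1L, d[2], d[3], d[4]))
    y <- aperm(y, c(1, 2, 3, 4, 5))
  }
  d <- dim(y)
  if (length(d) != 5L || d[3] != d[4])
    stop("y must have shape (M+1) x R x S x S x C_obs")
  if (d[1] < 2L) stop("need at least two time points (M >= 1)")
  t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  structure(y, t = t, boundary = boundary, class = "nca_training_data")
}

#' @export
print.nca_training_data <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("NCA training data: M = %d transitions, R = %d trajectories, %d x %d lattice, %d channel(s), t = %d steps/frame, %s boundary\n",
              d[1] - 1L, d[2], d[3], d[4], d[5], attr(x, "t"),
              attr(x, "boundary")))
  invisible(x)
}

data_frame_mat <- function(y, m, r) {
  d <- dim(y)
  f <- y[m, r, , , , drop = TRUE]
  dim(f) <- c(d[3] * d[4], d[5])
  f
}

#' Fit a neural cellular automaton to trajectory data
#'
#' Trains the per-cell update network by backpropagation through
#' time over the set of observed transitions y(m-1) -> y(m), each
#' spanning `t` NCA steps.  Per epoch, the (m, r) transition grid is
#' shuffled and split into `B` mini-batches; gradients of the mean
#' Euclidean loss are accumulated over all mini-batches, normalised
#' to unit global norm, and applied in a single Nadam step.  Stored
#' intermediate states are then propagated forward (predictions
#' replace them), except for one designated batch whose observable
#' channels are re-initialised from the data each epoch — a form of
#' data augmentation that speeds early training while the propagated
#' batches learn long-term (hidden-channel) dynamics.
#'
#' Hidden channels are appended to the data (zero at m = 0) and are
#' never overwritten by data afterwards.  The returned model carries
#' the parameters of the epoch with minimal training loss.
#'
#' @param data an `nca_training_data` array (see [training_data()]),
#'   or a 5-D array plus `t`.
#' @param t NCA steps per data interval (defaults to the data's own).
#' @param kernels kernel bank or character vector of kernel names.
#' @param channels total channel count C (>= the data's observable
#'   count); the excess are hidden channels.
#' @param activation hidden-layer activation (`"relu"`, `"linear"`,
#'   `"tanh"`).
#' @param hidden_width H; defaults to `4 * channels`.
#' @param p stochastic mask-off probability during training rollouts.
#' @param granularity mask granularity (see [sample_mask()]).
#' @param epochs number of training epochs.
#' @param B number of mini-batches the transition grid is split into.
#' @param lr Nadam learning rate.
#' @param reinit_batch index of the trajectory batch re-initialised
#'   from data each epoch.
#' @param propagate if `FALSE`, every batch is reset to data each
#'   epoch (no state propagation) — mainly for gradient diagnostics.
#' @param loss loss kind; only `"euclidean"` supports gradient-based
#'   training.
#' @param seed integer seed governing initialisation, shuffling and
#'   mask draws.
#' @param theta optional warm-start [nca_parameters].
#' @param verbose print progress every `verbose` epochs (0 = quiet).
#' @return an object of class `nca`; see [predict.nca()],
#'   [coef.nca()], [residuals.nca()], [plot.nca()].
#' @examples
#' \donttest{
#' y <- simulate_gray_scott(S = 24, steps = 64, sample_every = 16, seed = 1)
#' fit <- nca_fit(y, kernels = c("identity", "laplacian"), channels = 4,
#'                epochs = 20, seed = 1)
#' plot(fit)
#' }
#' @export
nca_fit <- function(data, t = attr(data, "t"),
                    kernels = c("identity", "laplacian"),
                    channels = dim(data)[5],
                    activation = c("relu", "linear", "tanh"),
                    hidden_width = 4L * channels,
                    p = 0, granularity = c("per-element", "per-pixel"),
                    epochs = 100L, B = 1L, lr = 1e-3,
                    reinit_batch = 1L, propagate = TRUE,
                    loss = "euclidean",
                    seed = 1L, theta = NULL, verbose = 0L) {
  activation <- match.arg(activation)
  granularity <- match.arg(granularity)
  kernels <- as_kernel_set(kernels)
  if (!identical(loss, "euclidean"))
    stop("gradient-based training supports only the euclidean loss; ",
         "other loss kinds are available for evaluation via state_loss()")
  d <- dim(data)
  if (length(d) != 5L) stop("data must be a 5-D (time, batch, row, col, channel) array")
  M <- d[1] - 1L; R <- d[2]; S <- d[3]; C_obs <- d[5]
  boundary <- attr(data, "boundary")
  if (is.null(boundary)) boundary <- "periodic"
  t <- as.integer(t)
  C <- as.integer(channels); K <- kernels$K; H <- as.integer(hidden_width)
  if (C < C_obs) stop("channels must be >= the data's channel count (", C_obs, ")")
  B <- as.integer(B)
  if (B < 1L || B > M * R) stop("B must satisfy 1 <= B <= M * R")
  if (reinit_batch < 1L || reinit_batch > R) stop("reinit_batch out of range")

  plan <- conv_plan(S, boundary)
  S2 <- S * S

  # data frames as (S^2 x C_obs) matrices, indexed [[m + 1]][[r]]
  Y <- lapply(seq_len(M + 1L), function(mi)
    lapply(seq_len(R), function(r) data_frame_mat(data, mi, r)))

  init_state <- function(mi, r) {
    X <- matrix(0, S2, C)
    X[, seq_len(C_obs)] <- Y[[mi]][[r]]
    X
  }
  # stored states x(m, r), m = 0..M; hidden channels start at zero
  Xs <- lapply(seq_len(M + 1L), function(mi)
    lapply(seq_len(R), function(r) init_state(mi, r)))

  history <- numeric(epochs)
  best_loss <- Inf; best_theta <- NULL; best_epoch <- NA_integer_

  with_seed(seed, {
    if (is.null(theta))
      theta <- init_parameters(C, K, H, activation)
    else if (theta$C != C || theta$K != K)
      stop("warm-start parameters do not match C and K")
    opt <- nadam(lr = lr)
    pairs <- as.matrix(expand.grid(m = seq_len(M), r = seq_len(R)))

    splans <- list()   # stacked conv plans, keyed by chunk size

    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(pairs))
      chunk_of <- rep(seq_len(B), length.out = nrow(pairs))[order(ord)]
      grads <- zero_grads(theta)
      pair_losses <- numeric(nrow(pairs))
      Xhat <- lapply(seq_len(M + 1L), function(mi) vector("list", R))
      for (b in seq_len(B)) {
        sel <- which(chunk_of == b)
        nb <- length(sel)
        key <- as.character(nb)
        if (is.null(splans[[key]])) splans[[key]] <- stack_plan(plan, nb)
        X0stack <- do.call(rbind, lapply(sel, function(pi)
          Xs[[pairs[pi, "m"]]][[pairs[pi, "r"]]]))
        Ystack <- do.call(rbind, lapply(sel, function(pi)
          Y[[pairs[pi, "m"] + 1L]][[pairs[pi, "r"]]]))
        masks <- if (p > 0)
          lapply(seq_len(t), function(i)
            sample_mask_mat(nb * S2, C, p, granularity))
        else NULL
        res <- chunk_loss_grad(X0stack, Ystack, theta, kernels,
                               splans[[key]], t, C_obs, nb, masks,
                               weight = 1 / (M * R))
        if (!all(is.finite(res$losses)))
          stop(sprintf("divergent loss at epoch %d, chunk %d", ep, b))
        pair_losses[sel] <- res$losses
        grads <- add_grads(grads, res$grads)
        for (q in seq_len(nb)) {
          pi <- sel[q]
          Xhat[[pairs[pi, "m"] + 1L]][[pairs[pi, "r"]]] <-
            res$Xhat[(q - 1L) * S2 + seq_len(S2), , drop = FALSE]
        }
      }
      if (!all(is.finite(grads$W1), is.finite(grads$W2), is.finite(grads$v)))
        stop(sprintf("divergent gradient at epoch %d", ep))
      history[ep] <- mean(pair_losses)
      if (history[ep] < best_loss) {
        best_loss <- history[ep]; best_theta <- theta; best_epoch <- ep
      }
      upd <- nadam_update(opt, theta, normalise_gradient(grads))
      theta <- upd$theta; opt <- upd$opt
      # state propagation / re-initialisation
      for (m in seq_len(M)) for (r in seq_len(R)) {
        xh <- Xhat[[m + 1L]][[r]]
        if (!propagate) {
          Xs[[m + 1L]][[r]] <- init_state(m + 1L, r)
        } else if (r == reinit_batch) {
          xh[, seq_len(C_obs)] <- Y[[m + 1L]][[r]]
          Xs[[m + 1L]][[r]] <- xh
        } else {
          Xs[[m + 1L]][[r]] <- xh
        }
      }
      if (verbose > 0L && ep %% verbose == 0L)
        message(sprintf("epoch %4d: loss = %.6g", ep, history[ep]))
    }
  })
  # the final (post-update) parameters are also evaluated implicitly
  # at the next fit; reported parameters are the best seen
  structure(list(theta = best_theta, final_theta = theta,
                 kernels = kernels, C = C, C_obs = C_obs, H = H,
                 K = K, activation = activation, p = p,
                 granularity = granularity, boundary = boundary,
                 t = t, S = S,
                 loss_history = history, best_epoch = best_epoch,
                 config = list(epochs = epochs, B = B, lr = lr,
                               reinit_batch = reinit_batch,
                               propagate = propagate, loss = loss,
                               seed = seed),
                 data_dim = d, call = match.call()),
            class = "nca")
}

#' Construct an untrained NCA model
#'
#' Wraps freshly initialised (identity-map) parameters in the same
#' `nca` object that [nca_fit()] returns, so the prediction,
#' stability and serialisation tools apply uniformly to untrained
#' models.
#'
#' @inheritParams nca_fit
#' @param C total channel count.
#' @param C_obs observable channel count.
#' @param boundary boundary mode.
#' @param seed seed for the hidden-layer weight draw.
#' @return an object of class `nca`.
#' @export
nca_model <- function(kernels = c("identity", "laplacian"), C = 2L,
                      C_obs = C, activation = c("relu", "linear", "tanh"),
                      hidden_width = 4L * C, p = 0,
                      granularity = c("per-element", "per-pixel"),
                      boundary = c("periodic", "fixed-zero"),
                      t = 1L, seed = 1L, theta = NULL) {
  activation <- match.arg(activation)
  granularity <- match.arg(granularity)
  boundary <- match.arg(boundary)
  kernels <- as_kernel_set(kernels)
  if (is.null(theta))
    theta <- init_parameters(C, kernels$K, hidden_width, activation, seed = seed)
  structure(list(theta = theta, final_theta = theta, kernels = kernels,
                 C = as.integer(C), C_obs = as.integer(C_obs),
                 H = theta$H, K = kernels$K, activation = activation,
                 p = p, granularity = granularity, boundary = boundary,
                 t = as.integer(t), S = NA_integer_,
                 loss_history = numeric(0), best_epoch = NA_integer_,
                 config = list(seed = seed), data_dim = NULL,
                 call = match.call()),
            class = "nca")
}

# promote an S x S x C_obs observation to a full C-channel state
full_state <- function(model, x0) {
  if (is.matrix(x0)) x0 <- array(x0, c(dim(x0), 1L))
  d <- dim(x0)
  if (d[3] == model$C) {
    return(lattice_state(x0, C_obs = model$C_obs, boundary = model$boundary))
  }
  if (d[3] != model$C_obs)
    stop("x0 must have either C = ", model$C, " or C_obs = ",
         model$C_obs, " channels")
  full <- array(0, c(d[1], d[2], model$C))
  full[, , seq_len(model$C_obs)] <- x0
  lattice_state(full, C_obs = model$C_obs, boundary = model$boundary)
}

#' @export
print.nca <- function(x, ...) {
  cat("Neural cellular automaton\n")
  cat(sprintf("  kernels   : %s\n", paste(names(x$kernels$kernels), collapse = ", ")))
  cat(sprintf("  channels  : %d (%d observable), hidden width H = %d\n",
              x$C, x$C_obs, x$H))
  cat(sprintf("  activation: %s;  mask p = %g (%s);  boundary = %s\n",
              x$activation, x$p, x$granularity, x$boundary))
  if (length(x$loss_history)) {
    cat(sprintf("  trained   : %d epochs, best loss %.6g at epoch %d\n",
                length(x$loss_history), min(x$loss_history), x$best_epoch))
  } else {
    cat("  untrained (identity map at initialisation)\n")
  }
  invisible(x)
}

#' @export
summary.nca <- function(object, ...) {
  out <- list(model = object,
              n_parameters = length(object$theta$W1) +
                length(object$theta$W2) + length(object$theta$v),
              loss_initial = if (length(object$loss_history))
                object$loss_history[1] else NA_real_,
              loss_best = if (length(object$loss_history))
                min(object$loss_history) else NA_real_)
  class(out) <- "summary.nca"
  out
}

#' @export
print.summary.nca <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters: %d trainable weights\n", x$n_parameters))
  if (!is.na(x$loss_initial))
    cat(sprintf("  loss      : %.6g (epoch 1) -> %.6g (best)\n",
                x$loss_initial, x$loss_best))
  invisible(x)
}

#' @export
coef.nca <- function(object, ...) {
  object$theta[c("W1", "W2", "v")]
}

#' Roll an NCA model forward from an initial state
#'
#' @param object an `nca` model.
#' @param x0 initial state: either a full S x S x C array or an
#'   observable S x S x C_obs array (hidden channels are appended as
#'   zeros).
#' @param steps number of NCA steps (defaults to `t`, one data
#'   interval).
#' @param p mask-off probability (defaults to the model's own; set 0
#'   for a deterministic rollout).
#' @param seed RNG seed for the mask stream.
#' @param trajectory if `TRUE` return the full list of states,
#'   otherwise just the final state.
#' @param ... unused.
#' @return final [lattice_state] or list of states.
#' @export
predict.nca <- function(object, x0, steps = object$t, p = object$p,
                        seed = NULL, trajectory = FALSE, ...) {
  x0 <- full_state(object, x0)
  traj <- nca_rollout(x0, object$theta, object$kernels, steps, p = p,
                      granularity = object$granularity,
                      boundary = object$boundary, seed = seed)
  if (trajectory) traj else traj[[length(traj)]]
}

#' Simulate stochastic NCA trajectories
#'
#' Draws `nsim` independent stochastic rollouts (mask streams) from
#' the model, each `steps` NCA steps from `x0`.
#'
#' @inheritParams predict.nca
#' @param nsim number of independent rollouts.
#' @param seed integer seed; rollout i uses `seed + i - 1`.
#' @return list of `nsim` trajectories (each a list of states).
#' @export
simulate.nca <- function(object, nsim = 1, seed = 1L, x0, steps = object$t,
                         ...) {
  x0 <- full_state(object, x0)
  lapply(seq_len(nsim), function(i)
    nca_rollout(x0, object$theta, object$kernels, steps, p = object$p,
                granularity = object$granularity,
                boundary = object$boundary, seed = seed + i - 1L))
}

#' One-interval prediction residuals against training data
#'
#' For each transition (m, r) of the supplied data, rolls the model
#' deterministically (p = 0) for `t` steps from frame m - 1 (hidden
#' channels zero) and returns the observable-channel residuals
#' against frame m, as an array of shape M x R x S x S x C_obs.
#'
#' @param object an `nca` model.
#' @param data an `nca_training_data` array.
#' @param ... unused.
#' @export
residuals.nca <- function(object, data, ...) {
  d <- dim(data)
  M <- d[1] - 1L; R <- d[2]
  out <- array(NA_real_, c(M, R, d[3], d[4], d[5]))
  for (m in seq_len(M)) for (r in seq_len(R)) {
    x0 <- array(data[m, r, , , ], c(d[3], d[4], d[5]))
    xh <- predict(object, x0, steps = object$t, p = 0)
    out[m, r, , , ] <- obs_channels(unclass_arr(xh), d[5]) -
      array(data[m + 1L, r, , , ], c(d[3], d[4], d[5]))
  }
  out
}

#' Plot an NCA training history
#'
#' @param x an `nca` model with a loss history.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nca <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("model has no training history to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "NCA training loss", log = "y", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
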