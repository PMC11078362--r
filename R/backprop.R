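# Analytic backpropagation through time for the NCA update map.
#
# The update x' = x + sigma * (u(Z W2') W1' + v), Z = g * x, is a
# residual recurrent map whose Jacobians are all simple linear or
# elementwise operations, so the loss gradient with respect to the
# parameters (W1, W2, v) and with respect to the input state can be
# accumulated exactly by reverse sweeps over the cached forward pass.
# Everything is expressed on (S^2) x C matrices; the perception
# adjoint is the scatter dual of the gather in perceive_mat().

# Forward rollout of `steps` steps from matrix state X0, caching what
# the reverse sweep needs.  `masks` is a list of (S^2 x C) 0/1
# matrices or NULL entries (NULL = deterministic step).
forward_cached <- function(X0, theta, kernels, plan, steps, masks = NULL) {
  caches <- vector("list", steps)
  X <- X0
  ring <- plan$ring
  W2t <- t(theta$W2); W1t <- t(theta$W1)
  u <- activation_fun(theta$activation)
  for (n in seq_len(steps)) {
    Z <- perceive_mat(X, kernels, plan)
    A <- u(Z %*% W2t)
    f <- A %*% W1t
    f <- f + rep(theta$v, each = nrow(f))
    if (!all(is.finite(f)))
      stop("non-finite NCA increment at step ", n,
           ": parameters are numerically unstable")
    m <- if (is.null(masks)) NULL else masks[[n]]
    Xn <- if (is.null(m)) X + f else X + m * f
    if (!is.null(ring)) Xn[ring, ] <- 0
    caches[[n]] <- list(X = X, Z = Z, A = A, mask = m)
    X <- Xn
  }
  list(X = X, caches = caches)
}

# Reverse sweep.  dXout is the gradient of the scalar objective with
# respect to the final state (S^2 x C).  Returns parameter gradients
# and the gradient with respect to the input state.
backward_cached <- function(dXout, theta, kernels, plan, caches) {
  dW1 <- matrix(0, nrow(theta$W1), ncol(theta$W1))
  dW2 <- matrix(0, nrow(theta$W2), ncol(theta$W2))
  dv <- numeric(length(theta$v))
  ring <- plan$ring
  g <- dXout
  for (n in rev(seq_along(caches))) {
    cc <- caches[[n]]
    if (!is.null(ring)) g[ring, ] <- 0       # adjoint of the ring clamp
    dF <- if (is.null(cc$mask)) g else cc$mask * g
    dv <- dv + colSums(dF)
    dW1 <- dW1 + crossprod(dF, cc$A)
    dA <- dF %*% theta$W1                    # (S^2) x H
    dH <- dA * activation_grad_from_output(theta$activation, cc$A)
    dW2 <- dW2 + crossprod(dH, cc$Z)
    dZ <- dH %*% theta$W2                    # (S^2) x (C*K)
    g <- g + perceive_mat_adjoint(dZ, kernels, plan)
  }
  list(W1 = dW1, W2 = dW2, v = dv, dX0 = g)
}

# Gradient of the Euclidean loss on observable channels with respect
# to the predicted matrix state; also returns the loss value.
euclidean_loss_grad <- function(Xhat, Ymat, C_obs) {
  diffobs <- Xhat[, seq_len(C_obs), drop = FALSE] - Ymat
  L <- sqrt(sum(diffobs^2))
  dX <- matrix(0, nrow(Xhat), ncol(Xhat))
  if (L > 0) dX[, seq_len(C_obs)] <- diffobs / L
  list(loss = L, dX = dX)
}

zero_grads <- function(theta) {
  list(W1 = matrix(0, nrow(theta$W1), ncol(theta$W1)),
       W2 = matrix(0, nrow(theta$W2), ncol(theta$W2)),
       v = numeric(length(theta$v)))
}

add_grads <- function(a, b, w = 1) {
  list(W1 = a$W1 + w * b$W1, W2 = a$W2 + w * b$W2, v = a$v + w * b$v)
}

grad_global_norm <- function(g) sqrt(sum(g$W1^2) + sum(g$W2^2) + sum(g$v^2))

#' Normalise a parameter gradient to unit global norm
#'
#' Scales the whole gradient (all tensors jointly) to global
#' Euclidean norm one before it is handed to the optimiser; this
#' stabilises training across problem scales.  A zero gradient is
#' returned unchanged (epsilon guard), and a non-finite gradient is
#' an error.
#'
#' @param grads list with elements `W1`, `W2`, `v`.
#' @return the rescaled gradient list.
#' @export
normalise_gradient <- function(grads) {
  if (!all(is.finite(grads$W1), is.finite(grads$W2), is.finite(grads$v)))
    stop("non-finite gradient")
  nrm <- grad_global_norm(grads)
  if (nrm < 1e-30) return(grads)
  list(W1 = grads$W1 / nrm, W2 = grads$W2 / nrm, v = grads$v / nrm)
}

# Loss and parameter gradient for one transition x0 -> y over t NCA
# steps (matrix states).  Used by the trainer and by gradient_check.
transition_loss_grad <- function(X0, Ymat, theta, kernels, plan, t,
                                 C_obs, masks = NULL, weight = 1) {
  fw <- forward_cached(X0, theta, kernels, plan, t, masks)
  lg <- euclidean_loss_grad(fw$X, Ymat, C_obs)
  bw <- backward_cached(weight * lg$dX, theta, kernels, plan, fw$caches)
  list(loss = lg$loss, grads = bw[c("W1", "W2", "v")],
       dX0 = bw$dX0, Xhat = fw$X)
}

# Per-block Euclidean loss and its gradient for `nblocks` vertically
# stacked lattices (the batch-parallel path used by the trainer).
stacked_euclidean_grad <- function(Xhat, Ystack, C_obs, S2, nblocks) {
  diffobs <- Xhat[, seq_len(C_obs), drop = FALSE] - Ystack
  sq <- rowSums(diffobs * diffobs)
  Lb <- sqrt(colSums(matrix(sq, S2, nblocks)))
  inv <- ifelse(Lb > 0, 1 / Lb, 0)
  dX <- matrix(0, nrow(Xhat), ncol(Xhat))
  dX[, seq_len(C_obs)] <- diffobs * rep(inv, each = S2)
  list(loss = Lb, dX = dX)
}

# Losses and accumulated parameter gradient for a chunk of
# transitions rolled out in parallel as stacked blocks.  `weight`
# scales each per-pair gradient (1 / (M * R) in the trainer).
chunk_loss_grad <- function(X0stack, Ystack, theta, kernels, splan, t,
                            C_obs, nblocks, masks = NULL, weight = 1) {
  S2 <- splan$S^2
  fw <- forward_cached(X0stack, theta, kernels, splan, t, masks)
  lg <- stacked_euclidean_grad(fw$X, Ystack, C_obs, S2, nblocks)
  bw <- backward_cached(weight * lg$dX, theta, kernels, splan, fw$caches)
  list(losses = lg$loss, grads = bw[c("W1", "W2", "v")], Xhat = fw$X)
}

# plain loss (no gradient) for finite differencing
transition_loss_only <- function(X0, Ymat, theta, kernels, plan, t,
                                 C_obs, masks = NULL) {
  X <- X0
  ring <- plan$ring
  for (n in seq_len(t)) {
    Z <- perceive_mat(X, kernels, plan)
    f <- increment_mat(Z, theta)$f
    m <- if (is.null(masks)) NULL else masks[[n]]
    X <- if (is.null(m)) X + f else X + m * f
    if (!is.null(ring)) X[ring, ] <- 0
  }
  sqrt(sum((X[, seq_len(C_obs), drop = FALSE] - Ymat)^2))
}

#' Finite-difference check of the analytic BPTT gradient
#'
#' Compares the analytic loss gradient of a t-step transition against
#' central finite differences over a random subset of parameters.
#' Intended for tiny instances (S <= 8, C <= 3, t <= 2); this is the
#' package's correctness contract for its backpropagation engine.
#' With p > 0, supply a frozen mask stream via `masks` so both
#' evaluations see the same realisation.
#'
#' @param theta an [nca_parameters] object.
#' @param x0 initial lattice state (S x S x C array).
#' @param y target for the observable channels (S x S x C_obs array).
#' @param kernels kernel bank.
#' @param t number of NCA steps in the transition.
#' @param boundary boundary mode.
#' @param n_checked number of randomly sampled parameters to test
#'   (at least 50 by default, capped at the parameter count).
#' @param h base finite-difference step.
#' @param masks optional frozen mask stream (list of t masks).
#' @param seed seed for the parameter subsample.
#' @return maximum relative error over the checked parameters
#'   (relative to `max(|analytic|, |numeric|, 1e-8)`).
#' @export
gradient_check <- function(theta, x0, y, kernels, t = 1,
                           boundary = "periodic", n_checked = 60,
                           h = 1e-5, masks = NULL, seed = 1L) {
  kernels <- as_kernel_set(kernels)
  S <- dim(x0)[1]
  plan <- conv_plan(S, boundary)
  X0 <- state_to_matrix(x0)
  C_obs <- dim(y)[3]
  Ymat <- y; dim(Ymat) <- c(S * S, C_obs)
  maskm <- if (is.null(masks)) NULL else lapply(masks, function(m) {
    dim(m) <- dim(X0); m
  })
  ana <- transition_loss_grad(X0, Ymat, theta, kernels, plan, t,
                              C_obs, maskm)$grads
  flat <- c(ana$W1, ana$W2, ana$v)
  npar <- length(flat)
  idx <- with_seed(seed, sample.int(npar, min(n_checked, npar)))
  theta_vec <- c(theta$W1, theta$W2, theta$v)
  rebuild <- function(vec) {
    n1 <- length(theta$W1); n2 <- length(theta$W2)
    nca_parameters(W1 = matrix(vec[seq_len(n1)], nrow(theta$W1)),
                   W2 = matrix(vec[n1 + seq_len(n2)], nrow(theta$W2)),
                   v = vec[n1 + n2 + seq_along(theta$v)],
                   activation = theta$activation)
  }
  max_rel <- 0
  for (i in idx) {
    hi <- h * max(1, abs(theta_vec[i]))
    vp <- theta_vec; vp[i] <- vp[i] + hi
    vm <- theta_vec; vm[i] <- vm[i] - hi
    lp <- transition_loss_only(X0, Ymat, rebuild(vp), kernels, plan, t,
                               C_obs, maskm)
    lm <- transition_loss_only(X0, Ymat, rebuild(vm), kernels, plan, t,
                               C_obs, maskm)
    num <- (lp - lm) / (2 * hi)
    rel <- abs(num - flat[i]) / max(abs(num), abs(flat[i]), 1e-8)
    if (rel > max_rel) max_rel <- rel
  }
  max_rel
}
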