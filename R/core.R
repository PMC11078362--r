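#' NCA parameters
#'
#' The per-cell update network is a single-hidden-layer perceptron
#' applied identically at every lattice site: the C*K perception
#' values at a site are mixed by `W2` (H x C*K) into H hidden units,
#' passed through the activation `u`, and combined by `W1` (C x H)
#' plus bias `v` into a C-vector of state increments.  The default
#' hidden width is H = 4C so network size scales with channel count.
#'
#' `init_parameters()` draws `W2` from a zero-mean uniform
#' distribution scaled by 1/sqrt(C*K) (keeping initial hidden
#' pre-activations of order one regardless of channel/kernel count)
#' and sets `W1` and `v` exactly to zero, so a freshly initialised
#' NCA is exactly the identity map — the natural starting point for a
#' residual update rule.
#'
#' @param C total channel count.
#' @param K number of perception kernels.
#' @param H hidden width; defaults to `4 * C`.
#' @param activation `"relu"` (u(z) = (|z| + z)/2), `"linear"` or
#'   `"tanh"`.
#' @param seed optional integer seed for the `W2` draw.
#' @return An object of class `nca_parameters`: a list with `W1`
#'   (C x H), `W2` (H x C*K), `v` (length C), `activation`, `C`, `K`,
#'   `H`.
#' @examples
#' th <- init_parameters(C = 8, K = 2)
#' dim(th$W2)  # 32 x 16
#' @export
init_parameters <- function(C, K, H = 4L * C,
                            activation = c("relu", "linear", "tanh"),
                            seed = NULL) {
  activation <- match.arg(activation)
  C <- as.integer(C); K <- as.integer(K); H <- as.integer(H)
  if (C < 1L || K < 1L || H < 1L) stop("C, K and H must all be >= 1")
  scale <- 1 / sqrt(C * K)
  W2 <- with_seed(seed, matrix(stats::runif(H * C * K, -scale, scale), H, C * K))
  nca_parameters(W1 = matrix(0, C, H), W2 = W2, v = numeric(C),
                 activation = activation)
}

#' @rdname init_parameters
#' @param W1,W2,v explicit weight matrices / bias vector.
#' @export
nca_parameters <- function(W1, W2, v,
                           activation = c("relu", "linear", "tanh")) {
  activation <- match.arg(activation)
  C <- nrow(W1); H <- ncol(W1)
  if (nrow(W2) != H) stop("W2 must have H = ", H, " rows")
  if (ncol(W2) %% C != 0L)
    stop("ncol(W2) must be a multiple of C = ", C)
  if (length(v) != C) stop("v must have length C = ", C)
  if (!all(is.finite(W1), is.finite(W2), is.finite(v)))
    stop("parameters contain non-finite values")
  structure(list(W1 = W1, W2 = W2, v = as.numeric(v),
                 activation = activation,
                 C = C, K = ncol(W2) %/% C, H = H),
            class = "nca_parameters")
}

#' @export
print.nca_parameters <- function(x, ...) {
  cat(sprintf("NCA parameters: C = %d, K = %d, H = %d, activation = %s (%d weights)\n",
              x$C, x$K, x$H, x$activation,
              length(x$W1) + length(x$W2) + length(x$v)))
  invisible(x)
}

activation_fun <- function(kind) {
  switch(kind,
         relu = function(z) (abs(z) + z) / 2,
         linear = identity,
         tanh = tanh,
         stop("unknown activation: ", kind))
}

# derivative expressed through the activation output (sufficient for
# relu / linear / tanh; relu uses subgradient 0 at z = 0)
activation_grad_from_output <- function(kind, a) {
  switch(kind,
         relu = (a > 0) * 1,
         linear = array(1, dim(a)),
         tanh = 1 - a * a,
         stop("unknown activation: ", kind))
}

#' Perception field
#'
#' Applies every kernel in the bank depthwise to every channel of the
#' state: `z[i,j,c,k] = sum_{di,dj} g_k[di,dj] * x[i+di, j+dj, c]`,
#' with out-of-range reads wrapping (periodic boundary) or returning
#' zero (fixed-zero boundary).  The result is linear in the state and
#' there is no channel mixing at this stage.
#'
#' @param x a [lattice_state] (or S x S x C array).
#' @param kernels a [standard_kernels] bank or character vector of
#'   kernel names.
#' @param boundary boundary mode; defaults to the state's own.
#' @return S x S x C x K numeric array (class `perception_field`).
#' @export
perceive <- function(x, kernels, boundary = state_boundary(x)) {
  kernels <- as_kernel_set(kernels)
  d <- dim(x)
  if (length(d) != 3L || d[1] != d[2])
    stop("state must be an S x S x C array")
  if (!all(is.finite(x))) stop("state contains non-finite values")
  plan <- conv_plan(d[1], boundary)
  Z <- perceive_mat(state_to_matrix(x), kernels, plan)
  zf <- Z
  dim(zf) <- c(d[1], d[1], d[3], kernels$K)
  structure(zf, kernel_names = names(kernels$kernels),
            class = "perception_field")
}

# Each kernel's cross-correlation (with the plan's boundary rule) is
# a sparse S^2 x S^2 matrix acting on the flattened lattice; its
# transpose is the exact adjoint.  The operators are built once per
# (kernel set, plan) and cached on the plan.  Because they act within
# one lattice, a batch of `nb` stacked lattices is handled by
# reinterpreting the (nb*S^2) x C state as an S^2 x (nb*C) matrix —
# a zero-copy reshape in column-major order.
get_conv_ops <- function(kernels, plan) {
  key <- paste(names(kernels$kernels), collapse = "|")
  hit <- plan$cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- conv_plan(plan$S, plan$boundary)
  S2 <- plan$S^2
  P <- lapply(kernels$kernels, function(g) {
    ti <- list(); tj <- list(); tx <- list()
    for (o in base$offsets) {
      w <- g[o$di + 2L, o$dj + 2L]
      if (w == 0) next
      keep <- if (is.null(o$invalid)) seq_len(S2) else which(!o$invalid)
      q <- length(ti) + 1L
      ti[[q]] <- keep
      tj[[q]] <- o$idx[keep]
      tx[[q]] <- rep(w, length(keep))
    }
    Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                         dims = c(S2, S2))
  })
  ops <- list(P = P, Pt = lapply(P, Matrix::t))
  plan$cache[[key]] <- ops
  ops
}

# matrix-form perception: X is (nb*S^2) x C, returns (nb*S^2) x (C*K)
# with column block (k-1)*C + (1:C) holding kernel k's responses
perceive_mat <- function(X, kernels, plan) {
  ops <- get_conv_ops(kernels, plan)
  S2 <- plan$S^2
  n <- nrow(X); C <- ncol(X); K <- kernels$K
  nb <- n %/% S2
  Xr <- X
  dim(Xr) <- c(S2, nb * C)
  Zs <- vector("list", K)
  for (k in seq_len(K)) Zs[[k]] <- as.matrix(ops$P[[k]] %*% Xr)
  Z <- do.call(cbind, Zs)
  dim(Z) <- c(n, C * K)
  Z
}

# adjoint of perceive_mat: map dZ ((nb*S^2) x C*K) back to dX
perceive_mat_adjoint <- function(dZ, kernels, plan) {
  ops <- get_conv_ops(kernels, plan)
  S2 <- plan$S^2
  n <- nrow(dZ); K <- kernels$K
  C <- ncol(dZ) %/% K
  nb <- n %/% S2
  dZr <- dZ
  dim(dZr) <- c(S2, nb * C * K)
  acc <- matrix(0, S2, nb * C)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * nb * C + seq_len(nb * C)
    acc <- acc + as.matrix(ops$Pt[[k]] %*% dZr[, cols, drop = FALSE])
  }
  dim(acc) <- c(n, C)
  acc
}

#' Per-cell network increment
#'
#' Evaluates the update network at every cell of a perception field:
#' `f[i,j,c] = sum_h W1[c,h] * u( sum_{c',k} W2[h,(c',k)] * z[i,j,c',k] ) + v[c]`.
#' The same weights are applied at every cell.
#'
#' @param z a `perception_field` from [perceive()].
#' @param theta an [nca_parameters] object.
#' @return S x S x C numeric array of state increments.
#' @export
nca_increment <- function(z, theta) {
  d <- dim(z)
  if (length(d) != 4L) stop("z must be an S x S x C x K perception field")
  if (d[3] != theta$C || d[4] != theta$K)
    stop(sprintf("parameter shapes (C = %d, K = %d) do not match perception field (C = %d, K = %d)",
                 theta$C, theta$K, d[3], d[4]))
  Z <- z
  dim(Z) <- c(d[1] * d[2], d[3] * d[4])
  f <- increment_mat(Z, theta)$f
  dim(f) <- c(d[1], d[2], d[3])
  f
}

increment_mat <- function(Z, theta) {
  u <- activation_fun(theta$activation)
  A <- u(Z %*% t(theta$W2))                       # (S^2) x H
  f <- A %*% t(theta$W1)                          # (S^2) x C
  f <- sweep(f, 2L, theta$v, "+")
  list(f = f, A = A)
}

#' Stochastic update mask
#'
#' Each increment is gated by an independent Bernoulli variable that
#' is 0 with probability `p` and 1 otherwise, breaking global update
#' synchrony between cells.  `"per-element"` granularity draws one
#' gate per (i, j, c) entry; `"per-pixel"` draws one gate per cell
#' (i, j) and broadcasts it across channels.
#'
#' @param S lattice side; @param C channel count.
#' @param p mask-off probability in [0, 1].
#' @param granularity `"per-element"` or `"per-pixel"`.
#' @param seed optional integer seed (draws are made with the current
#'   RNG stream when `NULL`).
#' @return S x S x C array of 0/1 gates.
#' @export
sample_mask <- function(S, C, p, granularity = c("per-element", "per-pixel"),
                        seed = NULL) {
  granularity <- match.arg(granularity)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  m <- with_seed(seed, {
    if (granularity == "per-element") {
      array(stats::runif(S * S * C) >= p, c(S, S, C)) * 1
    } else {
      pix <- matrix(stats::runif(S * S) >= p, S, S) * 1
      array(rep(pix, C), c(S, S, C))
    }
  })
  m
}

# matrix-form mask: (S^2) x C
sample_mask_mat <- function(S2, C, p, granularity) {
  if (p == 0) return(NULL)                        # NULL means all-ones
  if (granularity == "per-element") {
    matrix(stats::runif(S2 * C) >= p, S2, C) * 1
  } else {
    matrix(rep(stats::runif(S2) >= p, C), S2, C) * 1
  }
}

#' Single NCA update step
#'
#' Computes `x' = x + sigma * F(g * x)`: perception, per-cell network
#' increment, stochastic masking and the residual add, with the
#' fixed-zero boundary ring re-clamped afterwards when that mode is
#' active.  With `p = 0` the step is deterministic; with `p = 1` it
#' is the identity.
#'
#' A non-finite increment raises an error rather than propagating
#' NaNs: it signals numerically unstable parameters and must be
#' detectable.
#'
#' @param x a [lattice_state] (or plain array; then `boundary`
#'   applies).
#' @param theta an [nca_parameters] object.
#' @param kernels kernel bank (see [standard_kernels]).
#' @param p mask-off probability.
#' @param granularity mask granularity, see [sample_mask].
#' @param boundary boundary mode.
#' @param seed optional seed for the mask draw.
#' @param mask optional explicit 0/1 mask (S x S x C) overriding the
#'   random draw — used for frozen-mask analyses.
#' @return the updated state, same class/attributes as the input.
#' @export
nca_step <- function(x, theta, kernels, p = 0,
                     granularity = c("per-element", "per-pixel"),
                     boundary = state_boundary(x), seed = NULL,
                     mask = NULL) {
  granularity <- match.arg(granularity)
  kernels <- as_kernel_set(kernels)
  d <- dim(x)
  plan <- conv_plan(d[1], boundary)
  X <- state_to_matrix(x)
  maskm <- if (!is.null(mask)) {
    m <- mask; dim(m) <- dim(X); m
  } else {
    with_seed(seed, sample_mask_mat(nrow(X), ncol(X), p, granularity))
  }
  Xn <- step_mat(X, theta, kernels, plan, maskm)
  matrix_to_state(Xn, d[1], C_obs = state_C_obs(x), boundary = boundary)
}

# core step on matrix states; mask NULL means deterministic (all ones)
step_mat <- function(X, theta, kernels, plan, mask = NULL, step_index = NA) {
  Z <- perceive_mat(X, kernels, plan)
  f <- increment_mat(Z, theta)$f
  if (!all(is.finite(f)))
    stop("non-finite NCA increment",
         if (!is.na(step_index)) paste0(" at step ", step_index) else "",
         ": parameters are numerically unstable")
  Xn <- if (is.null(mask)) X + f else X + mask * f
  if (!is.null(plan$ring)) Xn[plan$ring, ] <- 0
  Xn
}

#' Iterated NCA rollout
#'
#' Applies [nca_step()] `steps` times and returns the whole
#' trajectory (a list of `steps + 1` states, the first being the
#' input).  Deterministic when `p = 0` or under a fixed seed.
#'
#' @inheritParams nca_step
#' @param x0 initial state.
#' @param steps number of updates (>= 0).
#' @param masks optional list of `steps` explicit masks (frozen mask
#'   stream).
#' @return list of `steps + 1` lattice states.
#' @export
nca_rollout <- function(x0, theta, kernels, steps, p = 0,
                        granularity = c("per-element", "per-pixel"),
                        boundary = state_boundary(x0), seed = NULL,
                        masks = NULL) {
  granularity <- match.arg(granularity)
  if (steps < 0) stop("steps must be >= 0")
  kernels <- as_kernel_set(kernels)
  d <- dim(x0)
  plan <- conv_plan(d[1], boundary)
  C_obs <- state_C_obs(x0)
  X <- state_to_matrix(x0)
  out <- vector("list", steps + 1L)
  out[[1L]] <- matrix_to_state(X, d[1], C_obs, boundary)
  with_seed(seed, {
    for (n in seq_len(steps)) {
      m <- if (!is.null(masks)) {
        mm <- masks[[n]]; dim(mm) <- dim(X); mm
      } else {
        sample_mask_mat(nrow(X), ncol(X), p, granularity)
      }
      X <- step_mat(X, theta, kernels, plan, m, step_index = n)
      out[[n + 1L]] <- matrix_to_state(X, d[1], C_obs, boundary)
    }
  })
  out
}
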