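#' The kappa perturbation functional
#'
#' For a perturbation `xt0` of an initial condition `x0`,
#' `kappa_n = ||xt0|| - ||Phi^n(x0 + xt0) - Phi^n(x0)||` (Euclidean
#' norms over the full state).  Maximising kappa finds large
#' perturbations that leave the future state unchanged; minimising
#' it finds small perturbations that destroy it.  Rollouts are
#' evaluated deterministically (p = 0) or with a frozen mask stream
#' shared between the two trajectories, so the two rollouts are
#' comparable.
#'
#' @param model an `nca` model (or list with `theta`, `kernels`,
#'   `boundary`).
#' @param x0 initial state (full C channels, or observable channels
#'   only — hidden are zero-filled).
#' @param xt0 perturbation field, same shape as the promoted `x0`.
#' @param n rollout length in NCA steps.
#' @param masks optional frozen mask stream (list of `n` masks used
#'   by both rollouts).
#' @return the kappa value (a single number).
#' @export
kappa <- function(model, x0, xt0, n, masks = NULL) {
  x0 <- full_state(model, x0)
  if (!identical(dim(xt0), dim(x0)))
    stop("perturbation shape does not match the state")
  base <- nca_rollout(x0, model$theta, model$kernels, n, p = 0,
                      boundary = model$boundary, masks = masks)
  pert0 <- lattice_state(unclass_arr(x0) + xt0, C_obs = model$C_obs,
                         boundary = model$boundary)
  pert <- nca_rollout(pert0, model$theta, model$kernels, n, p = 0,
                      boundary = model$boundary, masks = masks)
  diff <- unclass_arr(pert[[n + 1L]]) - unclass_arr(base[[n + 1L]])
  sqrt(sum(xt0^2)) - sqrt(sum(diff^2))
}

#' Gradient-based adversarial perturbation search
#'
#' Optimises the [kappa()] functional over the perturbation field by
#' gradient ascent (`mode = "maximise"`: large perturbations that
#' preserve the future state) or descent (`mode = "minimise"`: small
#' perturbations that destroy it), using the package's analytic
#' backpropagation through the deterministic rollout.  Steps are
#' accepted only if they improve the objective in the requested
#' direction; a rejected step halves the step size (backtracking),
#' so the reported trace is monotone.
#'
#' @inheritParams kappa
#' @param mode `"maximise"` or `"minimise"`.
#' @param iterations number of gradient iterations.
#' @param step_size initial gradient step length.
#' @param init_norm Euclidean norm of the random uniform initial
#'   perturbation.
#' @param seed seed for the initial perturbation.
#' @return list of class `nca_adversarial`: `xt0` (best
#'   perturbation), `kappa` (its objective), `mode`, `trace`
#'   (objective after each iteration).
#' @export
adversarial_search <- function(model, x0, n, mode = c("maximise", "minimise"),
                               iterations = 200, step_size = 0.05,
                               init_norm = 1e-2, seed = 1L, masks = NULL) {
  mode <- match.arg(mode)
  sgn <- if (mode == "maximise") 1 else -1
  x0 <- full_state(model, x0)
  d <- dim(x0)
  plan <- conv_plan(d[1], model$boundary)
  X0 <- state_to_matrix(x0)
  maskm <- if (is.null(masks)) NULL else lapply(masks, function(m) {
    dim(m) <- dim(X0); m
  })
  base <- forward_cached(X0, model$theta, model$kernels, plan, n, maskm)$X

  kappa_and_grad <- function(P) {     # P: (S^2) x C perturbation
    fw <- forward_cached(X0 + P, model$theta, model$kernels, plan, n, maskm)
    diff <- fw$X - base
    nd <- sqrt(sum(diff * diff))
    np <- sqrt(sum(P * P))
    gP <- if (np > 0) P / np else matrix(0, nrow(P), ncol(P))
    if (nd > 0) {
      bw <- backward_cached(diff / nd, model$theta, model$kernels, plan,
                            fw$caches)
      gP <- gP - bw$dX0
    }
    list(value = np - nd, grad = gP)
  }

  P <- with_seed(seed, matrix(stats::runif(length(X0), -1, 1), nrow(X0)))
  P <- P * (init_norm / sqrt(sum(P * P)))
  cur <- kappa_and_grad(P)
  if (!is.finite(cur$value)) stop("non-finite kappa objective at start")
  best <- cur$value
  trace <- numeric(iterations)
  step <- step_size
  for (it in seq_len(iterations)) {
    cand <- P + sgn * step * cur$grad
    cv <- kappa_and_grad(cand)
    if (is.finite(cv$value) && sgn * (cv$value - best) > 0) {
      P <- cand; cur <- cv; best <- cv$value
    } else {
      step <- step / 2
    }
    trace[it] <- best
  }
  xt0 <- P; dim(xt0) <- d
  structure(list(xt0 = xt0, kappa = best, mode = mode, trace = trace),
            class = "nca_adversarial")
}

#' @export
print.nca_adversarial <- function(x, ...) {
  cat(sprintf("Adversarial perturbation (%s): kappa = %.6g, ||xt0|| = %.6g after %d iterations\n",
              x$mode, x$kappa, sqrt(sum(x$xt0^2)), length(x$trace)))
  invisible(x)
}

#' Local perturbation map
#'
#' For every lattice site, perturbs that site in the initial
#' condition, rolls the model out `n` deterministic steps, and
#' counts how many pixels of the final state change by more than
#' `threshold` (maximum absolute change over the observable channels
#' at each pixel; the 0.1 default accounts for random fluctuation).
#' For a deterministic NCA the changed pixels necessarily lie within
#' Chebyshev radius `n` of the perturbed site, so counts are bounded
#' by (2n + 1)^2.
#'
#' @inheritParams kappa
#' @param magnitude perturbation added to the observable channels of
#'   the chosen pixel (must exceed `threshold`).
#' @param threshold change cutoff on the final state.
#' @param snapshots optional list of (i, j) sites whose perturbed
#'   final states are returned alongside the counts.
#' @return list of class `nca_perturbation_map`: `heatmap` (S x S
#'   integer counts), `threshold`, `n`, `magnitude`, `snapshots`.
#' @export
local_perturbation_map <- function(model, x0, n, magnitude = 1,
                                   threshold = 0.1, masks = NULL,
                                   snapshots = NULL) {
  if (magnitude <= threshold)
    stop("magnitude must exceed threshold")
  x0 <- full_state(model, x0)
  d <- dim(x0); S <- d[1]; C_obs <- model$C_obs
  plan <- conv_plan(S, model$boundary)
  X0 <- state_to_matrix(x0)
  maskm <- if (is.null(masks)) NULL else lapply(masks, function(m) {
    dim(m) <- dim(X0); m
  })
  roll <- function(X) {
    for (s in seq_len(n))
      X <- step_mat(X, model$theta, model$kernels, plan,
                    if (is.null(maskm)) NULL else maskm[[s]], step_index = s)
    X
  }
  base <- roll(X0)
  heat <- matrix(0L, S, S)
  snaps <- list()
  for (j in seq_len(S)) for (i in seq_len(S)) {
    Xp <- X0
    row <- i + (j - 1L) * S
    Xp[row, seq_len(C_obs)] <- Xp[row, seq_len(C_obs)] + magnitude
    fin <- roll(Xp)
    dobs <- abs(fin[, seq_len(C_obs), drop = FALSE] -
                base[, seq_len(C_obs), drop = FALSE])
    pixmax <- do.call(pmax, c(lapply(seq_len(C_obs), function(c) dobs[, c]),
                              list(0)))
    heat[i, j] <- sum(pixmax > threshold)
    if (!is.null(snapshots)) {
      for (sp in snapshots) if (sp[1] == i && sp[2] == j)
        snaps[[sprintf("%d_%d", i, j)]] <-
          matrix_to_state(fin, S, C_obs, model$boundary)
    }
  }
  structure(list(heatmap = heat, threshold = threshold, n = n,
                 magnitude = magnitude, snapshots = snaps),
            class = "nca_perturbation_map")
}

#' @export
print.nca_perturbation_map <- function(x, ...) {
  cat(sprintf("Local perturbation map: %d x %d sites, n = %d steps, threshold %.3g\n",
              nrow(x$heatmap), ncol(x$heatmap), x$n, x$threshold))
  cat(sprintf("  changed-pixel counts: min %d, median %g, max %d\n",
              min(x$heatmap), stats::median(x$heatmap), max(x$heatmap)))
  invisible(x)
}

#' Symmetry-perturbation evaluation
#'
#' Rolls the model out from transformed initial conditions and
#' scores the final state against the equally transformed target:
#' for each transform T, reports `L(Phi^n(T(x0)), T(target))`.
#' On-lattice transforms (90-degree rotations, axis flips) are exact
#' index permutations; `rot45` uses bilinear interpolation with zero
#' fill.  An NCA built from symmetric kernels (identity, average,
#' Laplacian) commutes with the on-lattice transforms, so its scores
#' are transform-independent up to round-off.
#'
#' @inheritParams kappa
#' @param target target state for the observable channels
#'   (S x S x C_obs array).
#' @param transforms subset of `c("identity", "rot90", "rot180",
#'   "rot270", "rot45", "flip_h", "flip_v")`.
#' @param loss_kind loss used for scoring (see [state_loss()]).
#' @return named numeric vector of per-transform losses.
#' @export
symmetry_eval <- function(model, x0, target, n,
                          transforms = c("identity", "rot90", "rot180",
                                         "rot270", "flip_h", "flip_v"),
                          loss_kind = "euclidean", masks = NULL) {
  known <- c("identity", "rot90", "rot180", "rot270", "rot45",
             "flip_h", "flip_v")
  bad <- setdiff(transforms, known)
  if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "))
  x0 <- full_state(model, x0)
  C_obs <- model$C_obs
  if (length(dim(target)) == 2L) target <- array(target, c(dim(target), 1L))
  tf <- function(arr, name) {
    switch(name,
           identity = arr,
           rot90 = rotate_field(arr, 90),
           rot180 = rotate_field(arr, 180),
           rot270 = rotate_field(arr, 270),
           rot45 = rotate_field(arr, 45),
           flip_h = arr[, dim(arr)[2]:1, , drop = FALSE],
           flip_v = arr[dim(arr)[1]:1, , , drop = FALSE])
  }
  out <- vapply(transforms, function(name) {
    xT <- lattice_state(tf(unclass_arr(x0), name), C_obs = C_obs,
                        boundary = model$boundary)
    fin <- nca_rollout(xT, model$theta, model$kernels, n, p = 0,
                       boundary = model$boundary, masks = masks)[[n + 1L]]
    yT <- tf(target, name)
    state_loss(obs_channels(unclass_arr(fin), C_obs), yT,
               kind = loss_kind, C_obs = C_obs)
  }, numeric(1))
  names(out) <- transforms
  out
}
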