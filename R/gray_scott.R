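#' Gray-Scott reaction-diffusion model
#'
#' Two species A and B on a periodic lattice with cubic autocatalysis
#' A + 2B -> 3B, feed rate `alpha` and kill rate `gamma`:
#'
#' \preformatted{
#'   dA/dt = D_A * lap(A) - A B^2 + alpha (1 - A)
#'   dB/dt = D_B * lap(B) + A B^2 - (gamma + alpha) B
#' }
#'
#' The Laplacian is the same nine-point 3x3 kernel the NCA perceives
#' with (`standard_kernels("laplacian")`), so the PDE solver and the
#' learned update rule share one discrete operator.  With
#' `D_A = 0.1, D_B = 0.05, alpha = 0.06230, gamma = 0.06268` the
#' system develops maze-like Turing patterning.
#'
#' `gray_scott_rhs()` evaluates the right-hand sides; `simulate_gray_scott()`
#' integrates them with an explicit Euler scheme (time step `dt`,
#' default 1) and returns snapshots every `sample_every` steps as
#' two-channel training data.  An explicit-stability heuristic
#' `dt * max(D_A, D_B) <= 1/4` is enforced (the nine-point Laplacian
#' has Gershgorin radius 6 at unit spacing, and the classical bound
#' `dt * D <= h^2/(4 D)` scale is used as a conservative guard).
#'
#' @param A,B numeric S x S matrices of species densities.
#' @param D_A,D_B diffusion constants (lattice^2 per unit time).
#' @param alpha,gamma kinetic rates (per unit time).
#' @return `gray_scott_rhs`: list with matrices `dA` and `dB`.
#' @examples
#' r <- gray_scott_rhs(matrix(1, 8, 8), matrix(0, 8, 8))
#' max(abs(r$dA))  # (1, 0) is a fixed point
#' @export
gray_scott_rhs <- function(A, B, D_A = 0.1, D_B = 0.05,
                           alpha = 0.06230, gamma = 0.06268) {
  if (!identical(dim(A), dim(B)) || nrow(A) != ncol(A))
    stop("A and B must be square matrices of equal size")
  S <- nrow(A)
  plan <- conv_plan(S, "periodic")
  ks <- standard_kernels("laplacian")
  lapA <- matrix(perceive_mat(matrix(A, S * S, 1L), ks, plan), S, S)
  lapB <- matrix(perceive_mat(matrix(B, S * S, 1L), ks, plan), S, S)
  AB2 <- A * B * B
  list(dA = D_A * lapA - AB2 + alpha * (1 - A),
       dB = D_B * lapB + AB2 - (gamma + alpha) * B)
}

#' @rdname gray_scott_rhs
#' @param init list with matrices `A` and `B`, or `NULL` to draw a
#'   seeded-blob initial condition (see [make_initial_condition()]).
#' @param S lattice side (used when `init` is `NULL`).
#' @param steps total number of Euler steps N.
#' @param sample_every record a snapshot every this many steps (must
#'   divide `steps`); becomes the data's `t`.
#' @param dt Euler time step.
#' @param seed seed for the default initial condition.
#' @return `simulate_gray_scott`: an [training_data()] array of shape
#'   (steps/sample_every + 1) x 1 x S x S x 2 with channels (A, B),
#'   periodic boundary, and attribute `params` recording the run.
#' @export
simulate_gray_scott <- function(init = NULL, S = 64, steps = 1024,
                                sample_every = 1, D_A = 0.1, D_B = 0.05,
                                alpha = 0.06230, gamma = 0.06268,
                                dt = 1, seed = 1L) {
  if (any(c(D_A, D_B, alpha, gamma) < 0)) stop("rates must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (dt * max(D_A, D_B) > 0.25)
    stop("explicit Euler scheme unstable: require dt * max(D_A, D_B) <= 1/4")
  if (steps %% sample_every != 0)
    stop("sample_every must divide steps")
  if (is.null(init))
    init <- make_initial_condition("blobs", S, seed = seed)
  A <- init$A; B <- init$B
  S <- nrow(A)
  plan <- conv_plan(S, "periodic")
  ks <- standard_kernels("laplacian")
  lap <- function(M) matrix(perceive_mat(matrix(M, S * S, 1L), ks, plan), S, S)
  M <- steps %/% sample_every
  y <- array(NA_real_, c(M + 1L, 1L, S, S, 2L))
  y[1L, 1L, , , 1L] <- A; y[1L, 1L, , , 2L] <- B
  for (n in seq_len(steps)) {
    AB2 <- A * B * B
    An <- A + dt * (D_A * lap(A) - AB2 + alpha * (1 - A))
    Bn <- B + dt * (D_B * lap(B) + AB2 - (gamma + alpha) * B)
    A <- An; B <- Bn
    if (!all(is.finite(A)) || !all(is.finite(B)))
      stop("Gray-Scott simulation blew up (non-finite field) at step ", n)
    if (n %% sample_every == 0L) {
      mi <- n %/% sample_every + 1L
      y[mi, 1L, , , 1L] <- A; y[mi, 1L, , , 2L] <- B
    }
  }
  out <- training_data(y, t = sample_every, boundary = "periodic")
  attr(out, "params") <- list(D_A = D_A, D_B = D_B, alpha = alpha,
                              gamma = gamma, dt = dt, S = S,
                              steps = steps, seed = seed)
  out
}

#' Initial conditions for reaction-diffusion runs
#'
#' Deterministic (seeded) generators for three families of initial
#' fields on an A = 1, B = 0 background:
#'
#' * `"blobs"` — randomly placed discs seeded with (A, B) =
#'   (0.5, 0.25), the classic Gray-Scott seeding.
#' * `"squares"` — randomly placed axis-aligned squares with the
#'   same seeding.
#' * `"high_frequency"` — disc seeding plus checkerboard patches and
#'   broadband noise, giving substantial spectral energy above half
#'   the Nyquist band; used to probe generalisation to inputs unlike
#'   anything in the training data.
#'
#' @param kind one of `"blobs"`, `"squares"`, `"high_frequency"`.
#' @param S lattice side.
#' @param n_patches number of seeded patches.
#' @param patch_range radius/half-width range of patches, in cells.
#' @param seed integer seed; same seed, same fields.
#' @return list with S x S matrices `A` and `B`.
#' @export
make_initial_condition <- function(kind = c("blobs", "squares", "high_frequency"),
                                   S = 64, n_patches = 6,
                                   patch_range = c(3, 6), seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    A <- matrix(1, S, S); B <- matrix(0, S, S)
    ii <- matrix(seq_len(S), S, S)
    jj <- matrix(seq_len(S), S, S, byrow = TRUE)
    for (q in seq_len(n_patches)) {
      ci <- sample.int(S, 1); cj <- sample.int(S, 1)
      rad <- stats::runif(1, patch_range[1], patch_range[2])
      di <- pmin(abs(ii - ci), S - abs(ii - ci))   # periodic distance
      dj <- pmin(abs(jj - cj), S - abs(jj - cj))
      inside <- if (kind == "squares") {
        di <= rad & dj <= rad
      } else {
        di * di + dj * dj <= rad * rad
      }
      A[inside] <- 0.5; B[inside] <- 0.25
    }
    if (kind == "high_frequency") {
      # checkerboard patches at the lattice Nyquist frequency
      cb <- (ii + jj) %% 2L
      for (q in seq_len(max(2L, n_patches %/% 2L))) {
        ci <- sample.int(S, 1); cj <- sample.int(S, 1)
        hw <- round(stats::runif(1, patch_range[1], patch_range[2]))
        di <- pmin(abs(ii - ci), S - abs(ii - ci))
        dj <- pmin(abs(jj - cj), S - abs(jj - cj))
        inside <- di <= hw & dj <= hw
        B[inside] <- 0.25 * cb[inside]
        A[inside] <- 1 - 0.5 * cb[inside]
      }
      B <- B + matrix(stats::runif(S * S, 0, 0.05), S, S)
    }
    list(A = A, B = B)
  })
}

#' Corrupt trajectory data with interpolated uniform noise
#'
#' Emulates measurement noise by interpolating every data value
#' towards uniform noise: `y~ = (1 - xi) * y + xi * eta` with
#' `eta ~ U(min y, max y)`, the extremes taken globally over the
#' whole trajectory.  `xi = 0` is the exact identity, `xi = 1` pure
#' noise.  The input is not modified.
#'
#' @param data an [training_data()] array (or any numeric array).
#' @param xi corruption intensity in [0, 1].
#' @param seed integer seed for the noise draw.
#' @return the corrupted data, same shape and attributes.
#' @export
corrupt_with_noise <- function(data, xi, seed = 1L) {
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]")
  if (xi == 0) return(data)
  lo <- min(data); hi <- max(data)
  eta <- with_seed(seed, array(stats::runif(length(data), lo, hi), dim(data)))
  out <- (1 - xi) * data + xi * eta
  attributes(out) <- attributes(data)
  out
}
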