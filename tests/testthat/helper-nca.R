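# Shared fixtures and independent oracles for the test suite.
# Everything here is deliberately naive (triple loops, direct sums):
# the oracles must not share code paths with the implementation.

# direct double-sum 3x3 cross-correlation, one kernel, depthwise
brute_conv <- function(x, g, boundary = "periodic") {
  S <- dim(x)[1]; C <- dim(x)[3]
  out <- array(0, dim(x))
  for (i in seq_len(S)) for (j in seq_len(S)) for (c in seq_len(C)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (boundary == "periodic") {
        x[((ii - 1) %% S) + 1, ((jj - 1) %% S) + 1, c]
      } else if (ii >= 1 && ii <= S && jj >= 1 && jj <= S) {
        x[ii, jj, c]
      } else 0
      acc <- acc + g[di + 2, dj + 2] * v
    }
    out[i, j, c] <- acc
  }
  out
}

# hand-built parameters realising f = d_c * laplacian(x_c) with the
# (identity, laplacian) kernel pair and linear activation
diffusion_theta <- function(C, d) {
  H <- C
  W2 <- matrix(0, H, 2 * C)
  W1 <- matrix(0, C, H)
  for (c in seq_len(C)) {
    W2[c, C + c] <- 1          # select the laplacian block
    W1[c, c] <- d[c]
  }
  nca_parameters(W1, W2, numeric(C), activation = "linear")
}

random_state <- function(S, C, seed, boundary = "periodic") {
  set.seed(seed)
  lattice_state(array(stats::rnorm(S * S * C), c(S, S, C)),
                boundary = boundary)
}

# explicit-Euler heat-equation trajectory driven by the brute-force
# stencil (independent of the package's convolution machinery)
heat_data <- function(S = 16, D = c(0.15, 0.08), M = 8, seed = 11) {
  set.seed(seed)
  fields <- lapply(seq_along(D), function(c) matrix(stats::runif(S * S), S, S))
  y <- array(0, c(M + 1, 1, S, S, length(D)))
  for (c in seq_along(D)) y[1, 1, , , c] <- fields[[c]]
  for (m in seq_len(M)) {
    for (c in seq_along(D)) {
      lap <- brute_conv(array(fields[[c]], c(S, S, 1)),
                        matrix(c(1, 2, 1, 2, -12, 2, 1, 2, 1), 3, 3) / 4)[, , 1]
      fields[[c]] <- fields[[c]] + D[c] * lap
      y[m + 1, 1, , , c] <- fields[[c]]
    }
  }
  training_data(y, t = 1)
}

# random small parameters with nonzero output layer (not the identity)
random_theta <- function(C, K, H = 4 * C, seed = 3, w1_sd = 0.1,
                         activation = "relu") {
  th <- init_parameters(C, K, H, activation = activation, seed = seed)
  set.seed(seed + 1000)
  th$W1 <- matrix(stats::rnorm(length(th$W1), sd = w1_sd), nrow(th$W1))
  th$v <- stats::rnorm(length(th$v), sd = w1_sd / 2)
  th
}
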