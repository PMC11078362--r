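test_that("uniform (A, B) = (1, 0) is a fixed point of the kinetics", {
  r <- gray_scott_rhs(matrix(1, 8, 8), matrix(0, 8, 8))
  expect_identical(max(abs(r$dA)), 0)
  expect_identical(max(abs(r$dB)), 0)
  y <- simulate_gray_scott(init = list(A = matrix(1, 8, 8), B = matrix(0, 8, 8)),
                           steps = 100, sample_every = 10)
  for (m in seq_len(dim(y)[1]))
    expect_identical(max(abs(y[m, 1, , , 1] - 1)), 0)
})

test_that("spatially uniform fields reduce to the scalar kinetics", {
  a <- 0.7; b <- 0.3
  D_A <- 0.1; D_B <- 0.05; alpha <- 0.06230; gamma <- 0.06268
  r <- gray_scott_rhs(matrix(a, 6, 6), matrix(b, 6, 6),
                      D_A = D_A, D_B = D_B, alpha = alpha, gamma = gamma)
  # diffusion vanishes; reaction terms equal the scalar evaluation
  expect_equal(max(abs(r$dA - (-a * b^2 + alpha * (1 - a)))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(r$dB - (a * b^2 - (gamma + alpha) * b))), 0,
               tolerance = 1e-12)
})

test_that("with alpha = gamma = 0 the total mass rate vanishes", {
  ic <- make_initial_condition("blobs", S = 16, seed = 3)
  r <- gray_scott_rhs(ic$A, ic$B, alpha = 0, gamma = 0)
  expect_lt(abs(sum(r$dA + r$dB)), 1e-10)
})

test_that("total mass is conserved per Euler step when alpha = gamma = 0", {
  y <- simulate_gray_scott(init = make_initial_condition("blobs", 16, seed = 4),
                           steps = 100, sample_every = 1,
                           alpha = 0, gamma = 0)
  masses <- vapply(seq_len(dim(y)[1]), function(m)
    sum(y[m, 1, , , ]), numeric(1))
  drift <- max(abs(diff(masses))) / abs(masses[1])
  expect_lt(drift, 1e-9)
})

test_that("a single Euler step matches a hand-rolled 3x3 oracle", {
  set.seed(6)
  A0 <- matrix(stats::runif(9, 0.5, 1), 3, 3)
  B0 <- matrix(stats::runif(9, 0, 0.5), 3, 3)
  pars <- list(D_A = 0.1, D_B = 0.05, alpha = 0.0623, gamma = 0.06268)
  y <- simulate_gray_scott(init = list(A = A0, B = B0), steps = 1,
                           sample_every = 1, D_A = pars$D_A, D_B = pars$D_B,
                           alpha = pars$alpha, gamma = pars$gamma)
  lapk <- matrix(c(1, 2, 1, 2, -12, 2, 1, 2, 1), 3, 3) / 4
  lapA <- brute_conv(array(A0, c(3, 3, 1)), lapk)[, , 1]
  lapB <- brute_conv(array(B0, c(3, 3, 1)), lapk)[, , 1]
  wantA <- A0 + pars$D_A * lapA - A0 * B0^2 + pars$alpha * (1 - A0)
  wantB <- B0 + pars$D_B * lapB + A0 * B0^2 - (pars$gamma + pars$alpha) * B0
  expect_equal(matrix(y[2, 1, , , 1], 3, 3), wantA, tolerance = 1e-12)
  expect_equal(matrix(y[2, 1, , , 2], 3, 3), wantB, tolerance = 1e-12)
})

test_that("printed-parameter run develops spatial patterning", {
  # D_A = 0.1, D_B = 0.05, alpha = 0.06230, gamma = 0.06268, N = 1024:
  # the trajectory must leave the uniform state and develop structure
  y <- simulate_gray_scott(S = 64, steps = 1024, sample_every = 1024, seed = 2)
  B_final <- y[2, 1, , , 2]
  expect_gt(stats::sd(B_final), 0.05)
  expect_gt(max(B_final) - min(B_final), 0.2)
})

test_that("generators are pure functions of their seed", {
  i1 <- make_initial_condition("blobs", 16, seed = 9)
  i2 <- make_initial_condition("blobs", 16, seed = 9)
  expect_identical(i1, i2)
  expect_false(identical(i1, make_initial_condition("blobs", 16, seed = 10)))
  expect_error(make_initial_condition("spiral", 16), "arg")
  y1 <- simulate_gray_scott(S = 16, steps = 32, sample_every = 16, seed = 5)
  y2 <- simulate_gray_scott(S = 16, steps = 32, sample_every = 16, seed = 5)
  expect_identical(as.vector(y1), as.vector(y2))
})

test_that("blob ICs sit on an A = 1 background with B inside patches only", {
  ic <- make_initial_condition("blobs", 32, seed = 12)
  outside <- ic$B == 0
  expect_true(all(ic$A[outside] == 1))
  expect_true(any(ic$B > 0))
  expect_true(all(ic$A[ic$B > 0] < 1))
})

test_that("high-frequency ICs carry energy above half the Nyquist band", {
  ic <- make_initial_condition("high_frequency", 32, seed = 13)
  S <- 32
  spec <- Mod(stats::fft(ic$B - mean(ic$B)))^2
  fr <- c(0:(S / 2), (S / 2 - 1):1)     # folded frequency index
  high <- outer(fr, fr, function(a, b) pmax(a, b)) > S / 4
  expect_gt(sum(spec[high]) / sum(spec), 0.10)
})

test_that("noise corruption follows the printed interpolation exactly", {
  y <- simulate_gray_scott(S = 16, steps = 32, sample_every = 16, seed = 7)
  expect_identical(corrupt_with_noise(y, 0), y)
  # xi = 1: pure uniform noise on [min y, max y]
  y1 <- corrupt_with_noise(y, 1, seed = 8)
  expect_gte(min(y1), min(y)); expect_lte(max(y1), max(y))
  n <- length(y1)
  mid <- (min(y) + max(y)) / 2
  sdm <- (max(y) - min(y)) / sqrt(12 * n)
  expect_lt(abs(mean(y1) - mid), 3 * sdm)
  # xi = 0.5 on a constant-zero trajectory with known extremes
  z <- array(0, c(2, 1, 4, 4, 1)); z[1, 1, 1, 1, 1] <- 1   # min 0, max 1
  z5 <- corrupt_with_noise(z, 0.5, seed = 9)
  keep <- as.vector(z) == 0
  expect_true(all(z5[keep] >= 0 & z5[keep] <= 0.5))
  expect_error(corrupt_with_noise(y, 1.5), "\\[0, 1\\]")
  # original untouched, shape and attributes preserved
  expect_identical(dim(y1), dim(y))
  expect_identical(attr(y1, "t"), attr(y, "t"))
})

test_that("the explicit scheme refuses unstable diffusion settings", {
  expect_error(simulate_gray_scott(S = 8, steps = 4, D_A = 0.5),
               "unstable")
  expect_error(simulate_gray_scott(S = 8, steps = 4, dt = -1), "positive")
  expect_error(simulate_gray_scott(S = 8, steps = 5, sample_every = 2),
               "divide")
})
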