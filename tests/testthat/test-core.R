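kern2 <- c("identity", "laplacian")

test_that("increment is zero under a zero output layer and relu is exact", {
  th <- init_parameters(C = 3, K = 2, seed = 1)   # W1 = 0, v = 0
  z <- perceive(random_state(6, 3, seed = 2), kern2)
  f <- nca_increment(z, th)
  expect_true(all(f == 0))
  u <- ncadyn:::activation_fun("relu")
  expect_identical(u(-2), 0)
  expect_identical(u(2), 2)
  expect_identical(u(0), 0)
})

test_that("hand-built diffusion weights reproduce the Laplacian stencil", {
  d <- c(0.2, 0.05)
  th <- diffusion_theta(C = 2, d = d)
  x <- random_state(8, 2, seed = 3)
  z <- perceive(x, kern2)
  f <- nca_increment(z, th)
  lapk <- standard_kernels("laplacian")$kernels[[1]]
  want <- brute_conv(unclass(x), lapk, "periodic")
  want[, , 1] <- d[1] * want[, , 1]; want[, , 2] <- d[2] * want[, , 2]
  expect_equal(f, want, tolerance = 1e-12)
})

test_that("increment validates parameter/perception shape agreement", {
  th <- init_parameters(C = 3, K = 2)
  z <- perceive(random_state(5, 2, seed = 4), kern2)   # C = 2, not 3
  expect_error(nca_increment(z, th), "do not match")
})

test_that("mask sampling respects p, granularity and seeding", {
  expect_true(all(sample_mask(5, 3, p = 0) == 1))
  expect_true(all(sample_mask(5, 3, p = 1) == 0))
  m <- sample_mask(100, 10, p = 0.5, seed = 7)     # 1e5 elements
  n <- length(m)
  frac <- mean(m)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # per-pixel granularity broadcasts across channels
  mp <- sample_mask(20, 4, p = 0.5, granularity = "per-pixel", seed = 8)
  expect_true(all(mp[, , 1] == mp[, , 2] & mp[, , 1] == mp[, , 4]))
  expect_identical(sample_mask(10, 2, p = 0.3, seed = 9),
                   sample_mask(10, 2, p = 0.3, seed = 9))
  expect_error(sample_mask(5, 2, p = 1.5), "\\[0, 1\\]")
})

test_that("a freshly initialised NCA is the identity map, bit-exactly", {
  for (rep in 1:100) {
    C <- sample(1:4, 1); S <- sample(3:10, 1)
    th <- init_parameters(C, K = 2, seed = rep)
    expect_identical(max(abs(th$W1)), 0)
    expect_identical(max(abs(th$v)), 0)
    x <- random_state(S, C, seed = rep)
    x1 <- nca_step(x, th, kern2, p = stats::runif(1), seed = rep)
    expect_identical(unclass(x1), unclass(x))
  }
})

test_that("default hidden width is H = 4C and shapes follow", {
  th <- init_parameters(C = 8, K = 2)
  expect_identical(th$H, 32L)
  expect_identical(dim(th$W2), c(32L, 16L))
  expect_identical(dim(th$W1), c(8L, 32L))
})

test_that("p = 1 masks every increment for any parameters", {
  th <- random_theta(2, 2, seed = 5)
  x <- random_state(6, 2, seed = 6)
  x1 <- nca_step(x, th, kern2, p = 1, seed = 1)
  expect_identical(unclass(x1), unclass(x))
})

test_that("the diffusion NCA performs an explicit Euler heat step", {
  d <- c(0.15, 0.08)
  th <- diffusion_theta(C = 2, d = d)
  x <- random_state(10, 2, seed = 7)
  x1 <- nca_step(x, th, kern2, p = 0)
  lapk <- standard_kernels("laplacian")$kernels[[1]]
  lap <- brute_conv(unclass(x), lapk, "periodic")
  want <- unclass(x)
  want[, , 1] <- want[, , 1] + d[1] * lap[, , 1]
  want[, , 2] <- want[, , 2] + d[2] * lap[, , 2]
  relerr <- max(abs(x1 - want)) / max(abs(want))
  expect_lt(relerr, 1e-12)
})

test_that("rollout composes steps and is deterministic under seed", {
  th <- random_theta(2, 2, seed = 8, w1_sd = 0.02)
  x <- random_state(6, 2, seed = 9)
  expect_length(nca_rollout(x, th, kern2, steps = 0), 1L)
  tr <- nca_rollout(x, th, kern2, steps = 7, p = 0)
  # t = a + b composition (deterministic)
  mid <- nca_rollout(x, th, kern2, steps = 3, p = 0)[[4]]
  tail <- nca_rollout(mid, th, kern2, steps = 4, p = 0)[[5]]
  expect_equal(unclass(tr[[8]]), unclass(tail), tolerance = 1e-14)
  # stochastic reproducibility
  a <- nca_rollout(x, th, kern2, steps = 5, p = 0.4, seed = 3)
  b <- nca_rollout(x, th, kern2, steps = 5, p = 0.4, seed = 3)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
})

test_that("diffusion rollout tracks the Euler oracle over many steps", {
  d <- c(0.15, 0.08)
  th <- diffusion_theta(C = 2, d = d)
  x <- random_state(8, 2, seed = 10)
  tr <- nca_rollout(x, th, kern2, steps = 50, p = 0)
  lapk <- standard_kernels("laplacian")$kernels[[1]]
  want <- unclass(x)
  for (n in 1:50) {
    lap <- brute_conv(want, lapk, "periodic")
    want[, , 1] <- want[, , 1] + d[1] * lap[, , 1]
    want[, , 2] <- want[, , 2] + d[2] * lap[, , 2]
  }
  expect_lt(max(abs(tr[[51]] - want)), 1e-9)
})

test_that("non-finite increments raise a diagnostic error", {
  th <- random_theta(2, 2, seed = 11, w1_sd = 50)   # wildly unstable
  x <- random_state(8, 2, seed = 12)
  expect_error(nca_rollout(x, th, kern2, steps = 200, p = 0),
               "non-finite NCA increment at step")
})

test_that("fixed-zero boundary keeps the outer ring at zero", {
  th <- random_theta(2, 2, seed = 13, w1_sd = 0.05)
  x <- random_state(8, 2, seed = 14, boundary = "fixed-zero")
  expect_true(all(unclass(x)[c(1, 8), , ] == 0))
  x1 <- nca_step(x, th, kern2, p = 0)
  expect_true(all(unclass(x1)[c(1, 8), , ] == 0))
  expect_true(all(unclass(x1)[, c(1, 8), ] == 0))
})
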