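kern2 <- c("identity", "laplacian")

test_that("gradient normalisation yields unit norm, is scale invariant, guards zero", {
  th <- init_parameters(2, 2, seed = 1)
  z <- ncadyn:::zero_grads(th)
  expect_identical(normalise_gradient(z), z)
  set.seed(2)
  g <- list(W1 = matrix(stats::rnorm(8), 2), W2 = matrix(stats::rnorm(32), 8),
            v = stats::rnorm(2))
  n1 <- normalise_gradient(g)
  expect_equal(sqrt(sum(n1$W1^2) + sum(n1$W2^2) + sum(n1$v^2)), 1,
               tolerance = 1e-12)
  g10 <- list(W1 = 10 * g$W1, W2 = 10 * g$W2, v = 10 * g$v)
  n2 <- normalise_gradient(g10)
  expect_equal(n1, n2, tolerance = 1e-12)
  g$W1[1] <- NaN
  expect_error(normalise_gradient(g), "non-finite")
})

test_that("Nadam matches a hand-computed scalar step and accumulates momentum", {
  # scalar parameter theta = 1, gradient g = 0.5, first step:
  # m1 = 0.05, n1 = 2.5e-4; bc1 = 0.1, bc2 = 1e-3
  # step = lr * (0.9*0.05/0.1 + 0.1*0.5/0.1) / (sqrt(2.5e-4/1e-3) + eps)
  lr <- 1e-3; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; g <- 0.5
  m1 <- (1 - b1) * g; n1 <- (1 - b2) * g^2
  want_step <- lr * (b1 * m1 / (1 - b1) + (1 - b1) * g / (1 - b1)) /
    (sqrt(n1 / (1 - b2)) + eps)
  th <- nca_parameters(W1 = matrix(1, 1, 1), W2 = matrix(0, 1, 1),
                       v = 0, activation = "linear")
  opt <- nadam(lr = lr, beta1 = b1, beta2 = b2, eps = eps)
  gr <- list(W1 = matrix(g, 1, 1), W2 = matrix(0, 1, 1), v = 0)
  r1 <- ncadyn:::nadam_update(opt, th, gr)
  expect_equal(r1$theta$W1[1, 1], 1 - want_step, tolerance = 1e-12)
  # zero gradient, zero moments: parameters unchanged
  r0 <- ncadyn:::nadam_update(nadam(), th, ncadyn:::zero_grads(th))
  expect_identical(r0$theta$W1, th$W1)
  # repeated identical gradients: the first moment accumulates towards
  # the gradient, and the step settles at the bias-corrected plateau
  r2 <- ncadyn:::nadam_update(r1$opt, r1$theta, gr)
  expect_gt(r2$opt$m$W1[1, 1], r1$opt$m$W1[1, 1])
  rk <- r2
  for (k in 1:200) rk <- ncadyn:::nadam_update(rk$opt, rk$theta, gr)
  stepk <- -diff(c(ncadyn:::nadam_update(rk$opt, rk$theta, gr)$theta$W1[1, 1],
                   rk$theta$W1[1, 1]))
  expect_equal(abs(stepk), lr, tolerance = 0.05)
})

test_that("analytic BPTT gradient agrees with central finite differences", {
  set.seed(31)
  th <- random_theta(2, 2, seed = 31, w1_sd = 0.1)
  x0 <- array(stats::runif(8 * 8 * 2), c(8, 8, 2))
  y <- array(stats::runif(8 * 8 * 2), c(8, 8, 2))
  err <- gradient_check(th, x0, y, kern2, t = 2)
  expect_lt(err, 1e-4)
  # zero-init parameters on static data: both gradients vanish
  th0 <- init_parameters(2, 2, seed = 1)
  err0 <- gradient_check(th0, x0, x0, kern2, t = 1)
  expect_lt(err0, 1e-4)
  # frozen stochastic mask: same agreement
  masks <- lapply(1:2, function(i) sample_mask(8, 2, p = 0.5, seed = i))
  errm <- gradient_check(th, x0, y, kern2, t = 2, masks = masks)
  expect_lt(errm, 1e-4)
  # fixed-zero boundary path
  x0z <- ncadyn:::zero_boundary_ring(x0)
  errz <- gradient_check(th, x0z, ncadyn:::zero_boundary_ring(y), kern2,
                         t = 2, boundary = "fixed-zero")
  expect_lt(errz, 1e-4)
})

test_that("mini-batched gradients sum to the full-batch gradient", {
  # with state propagation out of the picture (single pass from the
  # data states) and no stochastic masking, splitting the transition
  # grid into chunks must reproduce the full-batch gradient exactly
  set.seed(5)
  S <- 8; M <- 4; R <- 2; C <- 2; C_obs <- 2; tt <- 2
  y <- array(stats::runif((M + 1) * R * S * S * C_obs),
             c(M + 1, R, S, S, C_obs))
  th <- random_theta(C, 2, seed = 6, w1_sd = 0.05)
  ks <- standard_kernels(kern2)
  plan <- ncadyn:::conv_plan(S, "periodic")
  pairs <- expand.grid(m = seq_len(M), r = seq_len(R))
  frames <- function(sel_m, sel_r)
    lapply(seq_along(sel_m), function(q) {
      f <- y[sel_m[q], sel_r[q], , , ]
      dim(f) <- c(S * S, C_obs); f
    })
  grad_for <- function(idx) {
    nb <- length(idx)
    X0 <- do.call(rbind, frames(pairs$m[idx], pairs$r[idx]))
    Ys <- do.call(rbind, frames(pairs$m[idx] + 1L, pairs$r[idx]))
    ncadyn:::chunk_loss_grad(X0, Ys, th, ks,
                             ncadyn:::stack_plan(plan, nb), tt, C_obs,
                             nb, weight = 1 / (M * R))$grads
  }
  full <- grad_for(seq_len(M * R))
  chunks <- split(sample(M * R), rep(1:4, each = 2))
  acc <- ncadyn:::zero_grads(th)
  for (ch in chunks) acc <- ncadyn:::add_grads(acc, grad_for(ch))
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(acc$W1, full$W1), 1e-8)
  expect_lt(rel(acc$W2, full$W2), 1e-8)
  expect_lt(rel(acc$v, full$v), 1e-8)
})
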