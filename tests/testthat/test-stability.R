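kern2 <- c("identity", "laplacian")

toy_model <- function(seed = 1, w1_sd = 0.03, C = 3, S = NA) {
  m <- nca_model(kernels = kern2, C = C, C_obs = 2, seed = seed)
  m$theta <- random_theta(C, 2, seed = seed, w1_sd = w1_sd)
  m
}

test_that("kappa vanishes for zero perturbations and identity NCAs", {
  m <- toy_model(seed = 1)
  x0 <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  expect_identical(kappa(m, x0, array(0, dim(x0)), n = 4), 0)
  ident <- nca_model(kernels = kern2, C = 3, C_obs = 2, seed = 2)
  set.seed(3)
  xt <- array(stats::rnorm(8 * 8 * 3, sd = 0.1), c(8, 8, 3))
  expect_equal(kappa(ident, x0, xt, n = 6), 0, tolerance = 1e-12)
})

test_that("kappa matches a direct two-rollout evaluation", {
  m <- toy_model(seed = 4)
  set.seed(5)
  x0 <- array(stats::runif(6 * 6 * 3), c(6, 6, 3))
  xt <- array(stats::rnorm(6 * 6 * 3, sd = 0.05), c(6, 6, 3))
  n <- 3
  got <- kappa(m, x0, xt, n = n)
  a <- x0; b <- x0 + xt
  for (i in seq_len(n)) {
    a <- unclass(nca_step(lattice_state(a, C_obs = 2), m$theta, kern2, p = 0))
    b <- unclass(nca_step(lattice_state(b, C_obs = 2), m$theta, kern2, p = 0))
  }
  want <- sqrt(sum(xt^2)) - sqrt(sum((b - a)^2))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("adversarial search beats equal-norm random baselines both ways", {
  m <- toy_model(seed = 6, w1_sd = 0.05)
  set.seed(7)
  x0 <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  n <- 4
  for (mode in c("maximise", "minimise")) {
    adv <- adversarial_search(m, x0, n = n, mode = mode, iterations = 40,
                              seed = 8)
    # zero iterations returns the initial perturbation unchanged
    adv0 <- adversarial_search(m, x0, n = n, mode = mode, iterations = 0,
                               seed = 8)
    expect_equal(sqrt(sum(adv0$xt0^2)), 1e-2, tolerance = 1e-10)
    # monotone accepted-step trace
    dtr <- diff(adv$trace)
    if (mode == "maximise") expect_true(all(dtr >= 0)) else
      expect_true(all(dtr <= 0))
    # random baselines of the same norm
    nrm <- sqrt(sum(adv$xt0^2))
    base <- vapply(1:20, function(i) {
      set.seed(100 + i)
      pert <- array(stats::rnorm(length(x0)), dim(x0))
      pert <- pert * nrm / sqrt(sum(pert^2))
      kappa(m, x0, pert, n = n)
    }, numeric(1))
    if (mode == "maximise") expect_gt(adv$kappa, max(base))
    else expect_lt(adv$kappa, min(base))
  }
})

test_that("identity NCA yields a heatmap of exactly one changed pixel per site", {
  ident <- nca_model(kernels = kern2, C = 2, C_obs = 2, seed = 9)
  x0 <- array(stats::runif(6 * 6 * 2), c(6, 6, 2))
  pm <- local_perturbation_map(ident, x0, n = 3, magnitude = 1)
  expect_true(all(pm$heatmap == 1L))
})

test_that("perturbation maps respect the deterministic locality cone", {
  m <- toy_model(seed = 10, w1_sd = 0.05)
  set.seed(11)
  S <- 16; n <- 4
  x0 <- array(stats::runif(S * S * 3), c(S, S, 3))
  pm <- local_perturbation_map(m, x0, n = n, magnitude = 1)
  expect_true(all(pm$heatmap <= (2 * n + 1)^2))
  expect_error(local_perturbation_map(m, x0, n = 2, magnitude = 0.05),
               "exceed")
})

test_that("an input-blind NCA neither spreads nor erases perturbations", {
  # W2 = 0 makes the increment independent of the state, so a residual
  # update can neither propagate the perturbation to neighbours nor
  # decay it at the perturbed site: exactly one changed pixel per site
  m <- nca_model(kernels = kern2, C = 2, C_obs = 2, seed = 12)
  m$theta$W2[] <- 0
  m$theta$v[] <- 0.01
  x0 <- array(stats::runif(6 * 6 * 2), c(6, 6, 2))
  pm <- local_perturbation_map(m, x0, n = 3, magnitude = 1)
  expect_true(all(pm$heatmap == 1L))
})

test_that("symmetry evaluation is exact for identity and equivariant kernels", {
  set.seed(13)
  x0 <- array(stats::runif(10 * 10 * 2), c(10, 10, 2))
  target <- array(stats::runif(10 * 10 * 2), c(10, 10, 2))
  msym <- nca_model(kernels = c("identity", "average", "laplacian"),
                    C = 2, C_obs = 2, seed = 14)
  msym$theta <- random_theta(2, 3, seed = 14, w1_sd = 0.05)
  sc <- symmetry_eval(msym, x0, target, n = 4)
  expect_named(sc, c("identity", "rot90", "rot180", "rot270",
                     "flip_h", "flip_v"))
  # symmetric kernels: every on-lattice transform scores identically
  expect_lt(max(abs(sc - sc["identity"])), 1e-8)
  # asymmetric (gradient) kernels: finite everywhere, not equivariant
  masym <- nca_model(kernels = c("identity", "gradient_x", "gradient_y",
                                 "laplacian"), C = 2, C_obs = 2, seed = 15)
  masym$theta <- random_theta(2, 4, seed = 15, w1_sd = 0.05)
  sc2 <- symmetry_eval(masym, x0, target, n = 4,
                       transforms = c("identity", "rot90", "rot45"))
  expect_true(all(is.finite(sc2)))
  expect_gt(abs(sc2["rot90"] - sc2["identity"]), 1e-8)
  expect_error(symmetry_eval(msym, x0, target, n = 2, transforms = "rot33"),
               "unknown")
})

test_that("stability routines leave their inputs unmodified", {
  m <- toy_model(seed = 16)
  th_before <- m$theta
  set.seed(17)
  x0 <- array(stats::runif(6 * 6 * 3), c(6, 6, 3))
  x0_before <- x0
  invisible(kappa(m, x0, array(0.01, dim(x0)), n = 2))
  invisible(local_perturbation_map(m, x0, n = 2, magnitude = 1))
  invisible(adversarial_search(m, x0, n = 2, iterations = 3, seed = 18))
  expect_identical(m$theta, th_before)
  expect_identical(x0, x0_before)
})
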