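#' Nesterov-Adam (Nadam) optimiser
#'
#' One step of the Nadam update: Adam's bias-corrected first and
#' second moments with a Nesterov look-ahead on the momentum term,
#'
#' \preformatted{
#'   m <- beta1 * m + (1 - beta1) * g
#'   n <- beta2 * n + (1 - beta2) * g^2
#'   mhat <- m / (1 - beta1^t);  nhat <- n / (1 - beta2^t)
#'   theta <- theta - lr * (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t))
#'                       / (sqrt(nhat) + eps)
#' }
#'
#' applied elementwise to every parameter tensor.  Deterministic
#' given its inputs.
#'
#' @param lr learning rate (default 1e-3, the Adam-family standard).
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor inside the square root denominator.
#' @return an optimiser state object of class `nadam`.
#' @export
nadam <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 m = NULL, n = NULL, t = 0L),
            class = "nadam")
}

# one parameter update; theta and grads are lists of W1, W2, v
nadam_update <- function(opt, theta, grads) {
  if (is.null(opt$m)) {
    opt$m <- zero_grads(theta)
    opt$n <- zero_grads(theta)
  }
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  upd <- function(th, m, n, g) {
    m2 <- b1 * m + (1 - b1) * g
    n2 <- b2 * n + (1 - b2) * g * g
    step <- opt$lr * (b1 * m2 / bc1 + (1 - b1) * g / bc1) /
      (sqrt(n2 / bc2) + opt$eps)
    list(theta = th - step, m = m2, n = n2)
  }
  rW1 <- upd(theta$W1, opt$m$W1, opt$n$W1, grads$W1)
  rW2 <- upd(theta$W2, opt$m$W2, opt$n$W2, grads$W2)
  rv <- upd(theta$v, opt$m$v, opt$n$v, grads$v)
  opt$m <- list(W1 = rW1$m, W2 = rW2$m, v = rv$m)
  opt$n <- list(W1 = rW1$n, W2 = rW2$n, v = rv$n)
  theta2 <- nca_parameters(W1 = rW1$theta, W2 = rW2$theta, v = rv$theta,
                           activation = theta$activation)
  list(theta = theta2, opt = opt)
}

#' @export
print.nadam <- function(x, ...) {
  cat(sprintf("Nadam optimiser: lr = %g, beta1 = %g, beta2 = %g (step %d)\n",
              x$lr, x$beta1, x$beta2, x$t))
  invisible(x)
}
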