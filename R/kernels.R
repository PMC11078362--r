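#' Fixed 3x3 convolution kernels
#'
#' The NCA perceives its neighbourhood through a fixed bank of 3x3
#' kernels chosen as discretised differential operators: the identity,
#' a local average, the two Sobel gradient filters and a nine-point
#' Laplacian.  Kernels are applied depthwise (per channel, no channel
#' mixing), so the network's input layer sees one response per
#' (channel, kernel) pair.  At most nine 3x3 kernels can ever be
#' linearly independent, which bounds the useful bank size.
#'
#' Orientation convention: kernels act as cross-correlations in
#' row-major coordinates (index i runs down rows, j across columns),
#' so `gradient_x` responds to variation along i and `gradient_y` is
#' its transpose.  The sign convention of the gradient kernels is
#' immaterial to training (weights absorb it) but is fixed here for
#' reproducibility.
#'
#' @param names character vector of kernel names, each one of
#'   `"identity"`, `"average"`, `"gradient_x"`, `"gradient_y"`,
#'   `"laplacian"`; no duplicates.
#' @return An object of class `kernel_set`: a list with elements
#'   `kernels` (named list of 3x3 matrices, in the requested order)
#'   and `K` (the count).  The order is part of the model definition:
#'   it fixes the layout of the perception field.
#' @examples
#' ks <- standard_kernels(c("identity", "laplacian"))
#' ks$kernels$laplacian
#' @export
standard_kernels <- function(names) {
  if (length(names) < 1L) stop("at least one kernel name is required")
  bad <- setdiff(names, names(.kernel_bank))
  if (length(bad) > 0L)
    stop("unknown kernel name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names))
    stop("duplicate kernel names are not allowed")
  ks <- .kernel_bank[names]
  structure(list(kernels = ks, K = length(ks)), class = "kernel_set")
}

# Exact matrices, including the 1/9, 1/8, 1/8 and 1/4 prefactors.
.kernel_bank <- list(
  identity = matrix(c(0, 0, 0,
                      0, 1, 0,
                      0, 0, 0), 3, 3, byrow = TRUE),
  average = matrix(1 / 9, 3, 3),
  gradient_x = matrix(c( 1,  2,  1,
                         0,  0,  0,
                        -1, -2, -1), 3, 3, byrow = TRUE) / 8,
  gradient_y = matrix(c(1, 0, -1,
                        2, 0, -2,
                        1, 0, -1), 3, 3, byrow = TRUE) / 8,
  laplacian = matrix(c(1,   2, 1,
                       2, -12, 2,
                       1,   2, 1), 3, 3, byrow = TRUE) / 4
)

#' @export
print.kernel_set <- function(x, ...) {
  cat("Kernel set with", x$K, "kernel(s):",
      paste(names(x$kernels), collapse = ", "), "\n")
  invisible(x)
}

is_kernel_set <- function(x) inherits(x, "kernel_set")

as_kernel_set <- function(x) {
  if (is_kernel_set(x)) return(x)
  if (is.character(x)) return(standard_kernels(x))
  stop("expected a kernel_set or a character vector of kernel names")
}

# rank of the stacked flattened kernels must equal K (linear independence)
kernel_set_rank <- function(ks) {
  m <- do.call(rbind, lapply(ks$kernels, as.vector))
  qr(m)$rank
}
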