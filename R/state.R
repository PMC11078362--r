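#' Lattice states
#'
#' The system state is an S x S lattice carrying a vector of C real
#' numbers per cell.  The first `C_obs` channels are observable (they
#' are what loss functions compare to data); the remainder are hidden
#' channels the dynamics may use as latent memory.  Two boundary
#' modes are supported: `"periodic"` (reads wrap around) and
#' `"fixed-zero"` (reads outside the lattice return zero, and the
#' outermost ring of cells is clamped to zero after every update).
#'
#' @param values numeric S x S x C array (a matrix is promoted to one
#'   channel); all entries must be finite.
#' @param C_obs number of observable channels, `1 <= C_obs <= C`.
#' @param boundary `"periodic"` or `"fixed-zero"`.
#' @return An object of class `lattice_state`: the array with
#'   attributes `C_obs` and `boundary`.
#' @examples
#' x <- lattice_state(array(0, c(8, 8, 3)), C_obs = 2)
#' dim(x)
#' @export
lattice_state <- function(values, C_obs = dim(values)[3],
                          boundary = c("periodic", "fixed-zero")) {
  boundary <- match.arg(boundary)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  d <- dim(values)
  if (length(d) != 3L || d[1] != d[2])
    stop("state values must be an S x S x C array")
  S <- d[1]; C <- d[3]
  if (S < 3L) stop("lattice side S must be at least 3")
  if (C_obs < 1L || C_obs > C)
    stop("C_obs must satisfy 1 <= C_obs <= C")
  if (!all(is.finite(values))) stop("state contains non-finite values")
  if (boundary == "fixed-zero") values <- zero_boundary_ring(values)
  structure(values, C_obs = as.integer(C_obs), boundary = boundary,
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Lattice state: %d x %d, %d channel(s) (%d observable), %s boundary\n",
              d[1], d[2], d[3], attr(x, "C_obs"), attr(x, "boundary")))
  invisible(x)
}

state_boundary <- function(x, default = "periodic") {
  b <- attr(x, "boundary")
  if (is.null(b)) default else b
}

state_C_obs <- function(x, default = dim(x)[3]) {
  co <- attr(x, "C_obs")
  if (is.null(co)) default else co
}

# Clamp the outermost ring of cells to zero (all channels).
zero_boundary_ring <- function(values) {
  S <- dim(values)[1]
  values[c(1L, S), , ] <- 0
  values[, c(1L, S), ] <- 0
  values
}

# ---- internal matrix representation -------------------------------------
# Internally a state is an (S^2) x C matrix in column-major cell order
# (cell (i, j) maps to row i + (j - 1) * S).

state_to_matrix <- function(x) {
  d <- dim(x)
  m <- as.vector(x)          # drop class and extra attributes
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

matrix_to_state <- function(m, S, C_obs = ncol(m), boundary = "periodic") {
  a <- m
  dim(a) <- c(S, S, ncol(m))
  structure(a, C_obs = as.integer(C_obs), boundary = boundary,
            class = "lattice_state")
}

# Row indices of the outer boundary ring within the S^2 cell ordering.
ring_index <- function(S) {
  idx <- matrix(seq_len(S * S), S, S)
  unique(c(idx[1, ], idx[S, ], idx[, 1], idx[, S]))
}

# ---- shift plans ---------------------------------------------------------
# A "conv plan" precomputes, for each of the 9 Moore-neighbourhood
# offsets, the source-row permutation of the S^2 cell ordering and
# (for fixed-zero boundaries) the rows whose reads fall outside the
# lattice.  perceive() and its adjoint are then pure gathers/scatters.

conv_plan <- function(S, boundary) {
  offs <- expand.grid(di = -1:1, dj = -1:1)
  plan <- vector("list", nrow(offs))
  for (q in seq_len(nrow(offs))) {
    di <- offs$di[q]; dj <- offs$dj[q]
    if (boundary == "periodic") {
      ii <- ((seq_len(S) - 1L + di) %% S) + 1L
      jj <- ((seq_len(S) - 1L + dj) %% S) + 1L
      idx <- as.vector(outer(ii, (jj - 1L) * S, "+"))
      plan[[q]] <- list(di = di, dj = dj, idx = idx, invalid = NULL)
    } else {
      ii_raw <- seq_len(S) + di
      jj_raw <- seq_len(S) + dj
      vi <- ii_raw >= 1L & ii_raw <= S
      vj <- jj_raw >= 1L & jj_raw <= S
      ii <- pmin(pmax(ii_raw, 1L), S)
      jj <- pmin(pmax(jj_raw, 1L), S)
      idx <- as.vector(outer(ii, (jj - 1L) * S, "+"))
      valid <- as.vector(outer(vi, vj, "&"))
      plan[[q]] <- list(di = di, dj = dj, idx = idx,
                        invalid = if (all(valid)) NULL else !valid)
    }
  }
  structure(list(S = S, boundary = boundary, offsets = plan,
                 nblocks = 1L,
                 ring = if (boundary == "fixed-zero") ring_index(S) else NULL,
                 cache = new.env(parent = emptyenv())),
            class = "conv_plan")
}

# Replicate a conv plan across `nblocks` vertically stacked lattices
# (batch parallelism): shifts act within each S^2 block.
stack_plan <- function(plan, nblocks) {
  if (nblocks == 1L) return(plan)
  S2 <- plan$S^2
  shift <- rep.int((seq_len(nblocks) - 1L) * S2, rep.int(S2, nblocks))
  offs <- lapply(plan$offsets, function(o) {
    list(di = o$di, dj = o$dj,
         idx = rep.int(o$idx, nblocks) + shift,
         invalid = if (is.null(o$invalid)) NULL
                   else rep.int(o$invalid, nblocks))
  })
  ring <- if (is.null(plan$ring)) NULL
          else as.vector(outer(plan$ring, (seq_len(nblocks) - 1L) * S2, "+"))
  structure(list(S = plan$S, boundary = plan$boundary, offsets = offs,
                 nblocks = nblocks, ring = ring,
                 cache = plan$cache),
            class = "conv_plan")
}
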