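#' Synthetic RGBA shape rasters
#'
#' Licence-free programmatic stand-ins for image assets: simple
#' coloured shapes on a transparent background, returned as
#' size x size x 4 RGBA arrays in [0, 1] with alpha 1 inside the
#' shape and 0 outside (colour is zero wherever alpha is zero).
#' Deterministic for a given seed; distinct kinds are pairwise
#' different.
#'
#' @param kinds character vector from `"disc"`, `"ring"`, `"cross"`,
#'   `"star"`, `"glider"`.
#' @param size raster side length in pixels.
#' @param seed integer seed (fixes the per-shape colour jitter).
#' @return named list of RGBA arrays, one per requested kind.
#' @examples
#' imgs <- synthetic_shapes(c("disc", "cross"), size = 32)
#' dim(imgs$disc)
#' @export
synthetic_shapes <- function(kinds, size = 60, seed = 1L) {
  known <- c("disc", "ring", "cross", "star", "glider")
  bad <- setdiff(kinds, known)
  if (length(bad)) stop("unknown shape kind(s): ", paste(bad, collapse = ", "))
  base_cols <- list(disc = c(0.9, 0.2, 0.2), ring = c(0.2, 0.6, 0.9),
                    cross = c(0.2, 0.8, 0.3), star = c(0.95, 0.8, 0.1),
                    glider = c(0.6, 0.3, 0.8))
  cx <- (size + 1) / 2
  ii <- matrix(seq_len(size), size, size)
  jj <- matrix(seq_len(size), size, size, byrow = TRUE)
  r2 <- (ii - cx)^2 + (jj - cx)^2
  rmax <- size * 0.38
  with_seed(seed, {
    out <- list()
    for (kind in kinds) {
      mask <- switch(kind,
        disc = r2 <= rmax^2,
        ring = r2 <= rmax^2 & r2 >= (0.55 * rmax)^2,
        cross = (abs(ii - cx) <= size * 0.12 & abs(jj - cx) <= rmax) |
                (abs(jj - cx) <= size * 0.12 & abs(ii - cx) <= rmax),
        star = {
          th <- atan2(jj - cx, ii - cx)
          r2 <= (rmax * (0.55 + 0.45 * cos(5 * th)))^2
        },
        glider = {
          # the 5-cell glider motif, scaled to ~1/5 of the raster
          cell <- max(2L, round(size / 5))
          gi <- pmin(pmax(ceiling((ii - cx + 1.5 * cell) / cell), 0L), 4L)
          gj <- pmin(pmax(ceiling((jj - cx + 1.5 * cell) / cell), 0L), 4L)
          on <- matrix(FALSE, 3, 3)
          on[cbind(c(1, 2, 3, 3, 3), c(2, 3, 1, 2, 3))] <- TRUE
          ok <- gi >= 1 & gi <= 3 & gj >= 1 & gj <= 3
          m <- matrix(FALSE, size, size)
          m[ok] <- on[cbind(gi[ok], gj[ok])]
          m
        })
      col <- pmin(1, pmax(0, base_cols[[kind]] + stats::runif(3, -0.05, 0.05)))
      img <- array(0, c(size, size, 4))
      for (ch in 1:3) img[, , ch][mask] <- col[ch]
      img[, , 4][mask] <- 1
      out[[kind]] <- img
    }
    out
  })
}

# Exact area-average resampling of an image (rows x cols x C) to
# (new x new): output pixel value = mean of the input intensity over
# its footprint, via interval-overlap weight matrices.  Deterministic
# and alias-resistant.
area_resample <- function(img, new) {
  d <- dim(img)
  Wr <- overlap_weights(d[1], new)
  Wc <- overlap_weights(d[2], new)
  out <- array(0, c(new, new, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Wr %*% img[, , c] %*% t(Wc)
  out
}

# new x old matrix of fractional overlaps between output and input
# pixel intervals on [0, 1]; rows sum to 1
overlap_weights <- function(old, new) {
  W <- matrix(0, new, old)
  for (a in seq_len(new)) {
    lo <- (a - 1) / new; hi <- a / new
    for (b in seq_len(old)) {
      blo <- (b - 1) / old; bhi <- b / old
      ov <- min(hi, bhi) - max(lo, blo)
      if (ov > 0) W[a, b] <- ov
    }
  }
  W * new
}

#' Build image-morphing training data
#'
#' Turns an ordered image sequence into NCA training data with fixed
#' (zero) boundaries: each image is downsampled by area averaging to
#' `resolution`, embedded in a zero-padded lattice of side
#' `resolution + 2 * pad` (reducing boundary influence on the
#' dynamics), and the final image is repeated so the end state is
#' trained as an attractor.  `R` batch copies are produced, each
#' displaced by a random integer shift (discouraging the NCA from
#' learning boundary-anchored rules), and small-amplitude uniform
#' noise is added to every data frame, which regularises the
#' stable-final-state transition (without it, gradients there
#' diverge).
#'
#' @param images list of RGBA arrays (all the same size, values in
#'   [0, 1]), e.g. from [synthetic_shapes()].
#' @param resolution downsampled image side (default 60).
#' @param pad zero-padding width in cells (default 16).
#' @param R number of randomly shifted batch copies.
#' @param max_shift maximum absolute shift, in cells, per axis.
#' @param repeat_final number of times the final image appears in the
#'   frame sequence (default 2: once as the morph target, once as the
#'   stability target).
#' @param noise_amp amplitude of the uniform stability noise added to
#'   the data frames.
#' @param t NCA steps per frame interval recorded in the data.
#' @param rotate_augment if `TRUE`, each batch copy is additionally
#'   rotated by a random angle (symmetry data augmentation).
#' @param seed integer seed.
#' @return an [training_data()] array of shape
#'   (n_frames) x R x S x S x 4 with fixed-zero boundary, where
#'   `n_frames = length(images) + repeat_final - 1`; shifts are
#'   recorded in `attr(, "shifts")`.
#' @export
make_morph_sequence <- function(images, resolution = 60, pad = 16, R = 4,
                                max_shift = 8, repeat_final = 2,
                                noise_amp = 0.005, t = 64,
                                rotate_augment = FALSE, seed = 1L) {
  if (length(images) < 2L) stop("need at least two images")
  dims <- vapply(images, function(im) dim(im)[1:2], integer(2))
  if (any(dims != dims[1, 1])) stop("images must all have the same (square) size")
  if (min(vapply(images, min, numeric(1))) < 0 ||
      max(vapply(images, max, numeric(1))) > 1)
    stop("image values must lie in [0, 1]")
  S <- resolution + 2L * pad
  if (S <= resolution) stop("padded lattice must be strictly larger than the image")
  if (max_shift > pad)
    stop("max_shift may not exceed pad (content would leave the lattice)")
  small <- lapply(images, area_resample, new = resolution)
  frames <- c(small, rep(small[length(small)], repeat_final - 1L))
  Mp1 <- length(frames)
  Cimg <- dim(small[[1L]])[3]
  y <- array(0, c(Mp1, R, S, S, Cimg))
  shifts <- matrix(0L, R, 2L)
  with_seed(seed, {
    for (r in seq_len(R)) {
      sh <- if (max_shift > 0) sample(seq(-max_shift, max_shift), 2L, replace = TRUE)
            else c(0L, 0L)
      shifts[r, ] <- sh
      ang <- if (rotate_augment) stats::runif(1, 0, 360) else 0
      i0 <- pad + sh[1]; j0 <- pad + sh[2]
      for (mi in seq_len(Mp1)) {
        fr <- frames[[mi]]
        if (ang != 0) fr <- rotate_field(fr, ang)
        y[mi, r, i0 + seq_len(resolution), j0 + seq_len(resolution), ] <- fr
      }
    }
    if (noise_amp > 0)
      y <- y + array(stats::runif(length(y), -noise_amp, noise_amp), dim(y))
  })
  out <- training_data(y, t = t, boundary = "fixed-zero")
  attr(out, "shifts") <- shifts
  out
}

# rotate a (rows x cols x C) field about its centre; multiples of 90
# degrees are exact index permutations, other angles use bilinear
# interpolation with zero fill
rotate_field <- function(f, angle) {
  a <- angle %% 360
  if (isTRUE(all.equal(a %% 90, 0))) {
    q <- round(a / 90) %% 4
    if (q == 0) return(f)
    out <- f
    for (k in seq_len(q)) {
      d <- dim(out)
      # 90 degrees anticlockwise in (row, col): (i, j) <- (j, S+1-i)
      rot <- array(0, c(d[2], d[1], d[3]))
      for (ch in seq_len(d[3]))
        rot[, , ch] <- t(out[, , ch])[, d[1]:1]
      out <- rot
    }
    return(out)
  }
  d <- dim(f)
  S1 <- d[1]; S2 <- d[2]
  th <- a * pi / 180
  ci <- (S1 + 1) / 2; cj <- (S2 + 1) / 2
  ii <- matrix(seq_len(S1), S1, S2)
  jj <- matrix(seq_len(S2), S1, S2, byrow = TRUE)
  # inverse map: rotate output coordinates by -theta
  si <- ci + cos(th) * (ii - ci) + sin(th) * (jj - cj)
  sj <- cj - sin(th) * (ii - ci) + cos(th) * (jj - cj)
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  out <- array(0, d)
  at <- function(ch, i, j) {
    ok <- i >= 1 & i <= S1 & j >= 1 & j <= S2
    v <- numeric(length(i))
    v[ok] <- ch[cbind(i[ok], j[ok])]
    v
  }
  for (c in seq_len(d[3])) {
    ch <- f[, , c]
    v <- (1 - wi) * (1 - wj) * at(ch, i0, j0) +
         wi * (1 - wj) * at(ch, i0 + 1L, j0) +
         (1 - wi) * wj * at(ch, i0, j0 + 1L) +
         wi * wj * at(ch, i0 + 1L, j0 + 1L)
    out[, , c] <- v
  }
  out
}

#' Rotate every frame of a trajectory
#'
#' Applies [rotate_field()]'s rotation to the spatial axes of a
#' (time, batch, row, col, channel) data array.  Multiples of 90
#' degrees are exact index permutations; other angles use bilinear
#' interpolation with zero fill.
#'
#' @param data an [training_data()] array.
#' @param angle rotation angle in degrees (anticlockwise).
#' @return the rotated data, attributes preserved.
#' @export
rotate_trajectory <- function(data, angle) {
  d <- dim(data)
  out <- array(0, d)
  for (mi in seq_len(d[1])) for (r in seq_len(d[2])) {
    fr <- array(data[mi, r, , , ], c(d[3], d[4], d[5]))
    out[mi, r, , , ] <- rotate_field(fr, angle)
  }
  attributes(out) <- attributes(data)
  out
}
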