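#' Distances between lattice states
#'
#' Loss functions compare the observable channels of a predicted
#' state to data; hidden channels are never penalised.  Four kinds
#' are available:
#'
#' * `"euclidean"` — the flat Euclidean norm
#'   `sqrt(sum((x - y)^2))` over all observable entries.  This is the
#'   default, and the only loss used for gradient-based training.
#' * `"hellinger"`, `"bhattacharyya"` — probability-mass distances.
#'   Real-valued fields are made admissible by, per observable
#'   channel, subtracting the channel minimum, adding 1e-9 and
#'   normalising to sum one; the textbook Hellinger distance
#'   `sqrt(1 - BC)` or Bhattacharyya distance `-log(BC)` (with
#'   `BC = sum(sqrt(p * q))`) is then averaged over channels.
#' * `"spectral"` — per observable channel, the Euclidean distance
#'   between the 2-D magnitude spectra of the two fields (periodic
#'   interpretation), summed over channels.  Magnitude (not complex)
#'   spectra are used: a phase-sensitive version would reduce to the
#'   Euclidean loss by Parseval's theorem.
#'
#' @param x,y lattice states (or arrays) of matching shape.
#' @param kind loss kind, see above.
#' @param C_obs number of observable channels compared (defaults to
#'   the states' own setting).
#' @return a single non-negative number.
#' @examples
#' a <- array(runif(32), c(4, 4, 2)); b <- array(runif(32), c(4, 4, 2))
#' state_loss(a, b)                  # euclidean
#' state_loss(a, b, kind = "spectral")
#' @export
state_loss <- function(x, y,
                       kind = c("euclidean", "hellinger",
                                "bhattacharyya", "spectral"),
                       C_obs = min(state_C_obs(x), state_C_obs(y))) {
  kind <- match.arg(kind)
  if (!identical(dim(x)[1:2], dim(y)[1:2]))
    stop("state shapes do not match")
  xo <- obs_channels(unclass_arr(x), C_obs)
  yo <- obs_channels(unclass_arr(y), C_obs)
  if (!identical(dim(xo), dim(yo))) stop("observable channel counts differ")
  switch(kind,
         euclidean = sqrt(sum((xo - yo)^2)),
         hellinger = mass_distance(xo, yo, "hellinger"),
         bhattacharyya = mass_distance(xo, yo, "bhattacharyya"),
         spectral = spectral_distance(xo, yo))
}

unclass_arr <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

# shift-normalise a channel to a probability mass
channel_mass <- function(ch) {
  m <- ch - min(ch) + 1e-9
  tot <- sum(m)
  if (tot <= 0) stop("all-zero mass after normalisation")
  m / tot
}

mass_distance <- function(xo, yo, kind) {
  C <- dim(xo)[3]
  vals <- vapply(seq_len(C), function(c) {
    p <- channel_mass(xo[, , c]); q <- channel_mass(yo[, , c])
    bc <- sum(sqrt(p * q))
    if (kind == "hellinger") sqrt(max(0, 1 - bc)) else -log(max(bc, .Machine$double.xmin))
  }, numeric(1))
  mean(vals)
}

spectral_distance <- function(xo, yo) {
  C <- dim(xo)[3]
  sum(vapply(seq_len(C), function(c) {
    mx <- Mod(stats::fft(xo[, , c]))
    my <- Mod(stats::fft(yo[, , c]))
    sqrt(sum((mx - my)^2))
  }, numeric(1)))
}

#' Aggregate per-pair losses
#'
#' Combines the losses of all compared (time, batch) pairs by an
#' unweighted arithmetic mean.
#'
#' @param losses numeric vector (or matrix) of per-pair losses.
#' @return their mean.
#' @export
aggregate_loss <- function(losses) {
  losses <- as.numeric(losses)
  if (length(losses) == 0L) stop("no losses to aggregate")
  mean(losses)
}
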