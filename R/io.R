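#' Save and load NCA models
#'
#' A model is stored as a directory containing `manifest.json` (the
#' architecture: C, C_obs, kernel names in order, H, activation, p,
#' mask granularity, boundary, t, seed) and `weights.bin`, a flat
#' little-endian float64 dump of W1, W2 and v in that order.  The
#' binary dump makes save -> load -> rollout bit-identical to the
#' original model's rollout under equal seeds.
#'
#' @param model an `nca` object.
#' @param path directory to create/overwrite.
#' @return `save_nca` returns `path` invisibly; `load_nca` returns
#'   the reconstructed `nca` object.
#' @export
save_nca <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  th <- model$theta
  manifest <- list(
    format = "ncadyn-model-1",
    C = model$C, C_obs = model$C_obs, H = model$H,
    kernels = names(model$kernels$kernels),
    activation = model$activation,
    p = model$p, granularity = model$granularity,
    boundary = model$boundary, t = model$t,
    seed = model$config$seed,
    array_lengths = list(W1 = length(th$W1), W2 = length(th$W2),
                         v = length(th$v)),
    loss_history = model$loss_history,
    best_epoch = model$best_epoch)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(c(as.vector(th$W1), as.vector(th$W2), th$v), con,
           size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_nca
#' @export
load_nca <- function(path) {
  mf <- file.path(path, "manifest.json")
  wf <- file.path(path, "weights.bin")
  if (!file.exists(mf) || !file.exists(wf))
    stop("not a saved NCA model directory: ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$format, "ncadyn-model-1"))
    stop("unrecognised model format: ", man$format)
  C <- man$C; H <- man$H
  ks <- standard_kernels(man$kernels)
  K <- ks$K
  lens <- man$array_lengths
  want <- C * H + H * C * K + C
  got <- file.info(wf)$size / 8
  if (lens$W1 != C * H || lens$W2 != H * C * K || lens$v != C || got != want)
    stop(sprintf("weight array shape mismatch: manifest expects %d values, file holds %g",
                 want, got))
  con <- file(wf, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = want, size = 8L, endian = "little")
  W1 <- matrix(vals[seq_len(C * H)], C, H)
  W2 <- matrix(vals[C * H + seq_len(H * C * K)], H, C * K)
  v <- vals[C * H + H * C * K + seq_len(C)]
  theta <- nca_parameters(W1, W2, v, activation = man$activation)
  m <- nca_model(kernels = ks, C = C, C_obs = man$C_obs,
                 activation = man$activation, hidden_width = H,
                 p = man$p, granularity = man$granularity,
                 boundary = man$boundary, t = man$t,
                 seed = if (is.null(man$seed)) 1L else man$seed,
                 theta = theta)
  m$loss_history <- as.numeric(man$loss_history)
  m$best_epoch <- if (is.null(man$best_epoch)) NA_integer_ else man$best_epoch
  m
}

#' Trajectory array container
#'
#' Trajectories are exchanged as a flat little-endian float64 binary
#' file plus a JSON sidecar recording the axis order
#' (time, batch, row, col, channel), the dimensions, the steps-per-
#' frame `t`, the boundary mode and any generation parameters.
#' Re-import reproduces the array bit-exactly.
#'
#' @param data a (time, batch, row, col, channel) array.
#' @param path file stem; writes `<path>.bin` and `<path>.json`.
#' @export
write_trajectory <- function(data, path) {
  d <- dim(data)
  if (length(d) != 5L) stop("trajectory must be a 5-D array")
  sidecar <- list(format = "ncadyn-trajectory-1",
                  axes = c("time", "batch", "row", "col", "channel"),
                  dim = d,
                  t = attr(data, "t"),
                  boundary = attr(data, "boundary"),
                  params = attr(data, "params"),
                  finite = all(is.finite(data)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "ncadyn-trajectory-1"))
    stop("unrecognised trajectory format")
  d <- as.integer(side$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  if (length(vals) != prod(d)) stop("trajectory binary is truncated")
  y <- array(vals, d)
  if (is.numeric(side$t) && length(side$t) == 1L)
    y <- training_data(y, t = side$t,
                       boundary = if (is.character(side$boundary))
                                    side$boundary else "periodic")
  y
}

#' Export a rollout as image frames plus the array container
#'
#' Writes the observable channels of each state as 8-bit PNG frames
#' (RGB/RGBA when there are 3 or 4 observable channels, otherwise
#' one grayscale PNG per channel), the full state to the binary
#' array container, and a JSON sidecar with indices and flags.
#' Values are clipped to [0, 1] for the PNGs only; the container
#' keeps full precision.
#'
#' @param trajectory list of lattice states (from [nca_rollout()] or
#'   [predict.nca()]) or a 5-D data array.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
export_trajectory <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.list(trajectory)) {
    C_obs <- state_C_obs(trajectory[[1L]])
    d <- dim(trajectory[[1L]])
    arr <- array(NA_real_, c(length(trajectory), 1L, d[1], d[2], d[3]))
    for (n in seq_along(trajectory)) arr[n, 1L, , , ] <- trajectory[[n]]
  } else {
    arr <- trajectory
    C_obs <- dim(arr)[5]
  }
  d <- dim(arr)
  for (n in seq_len(d[1])) {
    fr <- array(arr[n, 1L, , , ], d[3:5])
    obs <- fr[, , seq_len(min(C_obs, d[5])), drop = FALSE]
    obs[obs < 0] <- 0; obs[obs > 1] <- 1
    if (dim(obs)[3] %in% c(3L, 4L)) {
      png::writePNG(obs, file.path(dir, sprintf("frame_%04d.png", n - 1L)))
    } else {
      for (c in seq_len(dim(obs)[3]))
        png::writePNG(obs[, , c],
                      file.path(dir, sprintf("frame_%04d_ch%d.png", n - 1L, c)))
    }
  }
  write_trajectory(arr, file.path(dir, "trajectory"))
  invisible(dir)
}

#' Run configurations
#'
#' Experiment runs are described by a YAML/JSON configuration with a
#' `task` (`"gray_scott"` or `"morph"`), a `model` block (channels,
#' observable channels, kernel names, activation, hidden width, mask
#' p and granularity, boundary), a `training` block (t, epochs, B,
#' lr, loss, seed, reinit_batch) and a task-specific `data` block.
#' Every field has a recorded default; `read_run_config()` fills
#' defaults, validates types and ranges, and round-trips losslessly
#' through [write_run_config()].
#'
#' @param path YAML (or JSON) file.
#' @return a validated config list of class `nca_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

default_run_config <- function() {
  list(
    task = "gray_scott",
    model = list(channels = 8L, observable = 2L,
                 kernels = c("identity", "laplacian"),
                 activation = "relu",
                 p = 0, granularity = "per-element",
                 boundary = "periodic"),
    training = list(t = 16L, epochs = 100L, B = 1L, lr = 1e-3,
                    loss = "euclidean", seed = 1L, reinit_batch = 1L),
    data = list(S = 32L, steps = 512L, seed = 1L, xi = 0,
                shapes = c("disc", "cross", "ring"),
                resolution = 60L, pad = 16L, R = 4L, max_shift = 8L))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(cfg) {
  def <- default_run_config()
  cfg <- utils::modifyList(def, cfg)
  if (!cfg$task %in% c("gray_scott", "morph"))
    stop("config: task must be 'gray_scott' or 'morph'")
  m <- cfg$model
  if (!is.numeric(m$channels) || m$channels < 1)
    stop("config: model$channels must be a positive integer")
  if (m$observable > m$channels)
    stop("config: model$observable may not exceed model$channels")
  standard_kernels(unlist(m$kernels))   # validates names
  if (!m$activation %in% c("relu", "linear", "tanh"))
    stop("config: unknown activation ", m$activation)
  if (m$p < 0 || m$p > 1) stop("config: model$p must lie in [0, 1]")
  if (!m$granularity %in% c("per-element", "per-pixel"))
    stop("config: unknown mask granularity")
  tr <- cfg$training
  for (f in c("t", "epochs", "B", "seed", "reinit_batch"))
    if (!is.numeric(tr[[f]]) || tr[[f]] < 1)
      stop("config: training$", f, " must be a positive integer")
  if (!is.numeric(tr$lr) || tr$lr <= 0)
    stop("config: training$lr must be positive")
  structure(cfg, class = "nca_run_config")
}
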