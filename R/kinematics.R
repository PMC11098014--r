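#' Savitzky-Golay smoothing configuration
#'
#' Smoothing is applied after each finite-difference stage to temper
#' keypoint estimation noise, which differencing amplifies. The filter fits
#' a local least-squares polynomial, so any polynomial trend of degree at
#' most \code{polyorder} passes through unchanged (including at the series
#' edges, which are handled by polynomial extrapolation, preserving length).
#'
#' The default window of 31 frames is about half a second at 60 fps: long
#' enough to suppress per-frame jitter, short enough to keep beat-scale
#' movement (dance accents at up to ~4 Hz) intact.
#'
#' @param enabled Apply smoothing at all? \code{FALSE} gives raw differences.
#' @param window Odd window length in frames, >= 5.
#' @param polyorder Polynomial degree, >= 2 and < window.
#' @return An object of class \code{smoothing_config}.
#' @export
smoothing_config <- function(enabled = TRUE, window = 31L, polyorder = 3L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 5L || window %% 2L == 0L) {
    stop("config error: window must be an odd integer >= 5", call. = FALSE)
  }
  if (polyorder < 2L || polyorder >= window) {
    stop("config error: polyorder must be >= 2 and < window", call. = FALSE)
  }
  structure(list(enabled = isTRUE(enabled), window = window,
                 polyorder = polyorder),
            class = "smoothing_config")
}

#' Estimate the sacrum trajectory
#'
#' The COCO skeleton omits the spine, so the sacrum -- the mechanical hub of
#' full-body movement -- is approximated as the per-frame midpoint of the
#' two hip joints.
#'
#' @param pose A [pose_sequence()].
#' @return Numeric matrix \code{[frames x 3]} of sacrum positions (class
#'   \code{sacrum_track}).
#' @export
estimate_sacrum <- function(pose) {
  lh <- role_idx(pose$layout, "left_hip")
  rh <- role_idx(pose$layout, "right_hip")
  sp <- (pose$positions[, lh, , drop = FALSE] +
         pose$positions[, rh, , drop = FALSE]) / 2
  out <- matrix(sp, nrow = n_frames(pose), ncol = 3)
  class(out) <- c("sacrum_track", class(out))
  out
}

#' Savitzky-Golay smoothing of a multi-column series
#'
#' @param series Numeric matrix \code{[N x d]} (a vector is treated as one
#'   column).
#' @param config A [smoothing_config()]. Identity when disabled.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_series <- function(series, config = smoothing_config()) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (!config$enabled) return(series)
  if (nrow(series) < config$window) {
    stop("length error: series shorter than smoothing window", call. = FALSE)
  }
  # the projection matrix depends only on (polyorder, window): build once
  F <- sgolay_matrix(config$polyorder, config$window)
  apply(series, 2, function(col) signal::sgolayfilt(col, F))
}

# Memoized Savitzky-Golay projection matrix.
sgolay_cache <- new.env(parent = emptyenv())
sgolay_matrix <- function(polyorder, window) {
  key <- paste(polyorder, window)
  if (is.null(sgolay_cache[[key]])) {
    sgolay_cache[[key]] <- signal::sgolay(p = polyorder, n = window)
  }
  sgolay_cache[[key]]
}

# Forward difference along frames of an [N x J x 3] array; drops last frame.
forward_diff <- function(arr, dt) {
  n <- dim(arr)[1]
  (arr[2:n, , , drop = FALSE] - arr[1:(n - 1), , , drop = FALSE]) / dt
}

smooth_array <- function(arr, config) {
  if (!config$enabled) return(arr)
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1])
  array(smooth_series(flat, config), dim = d)
}

#' Smoothed finite-difference kinematics
#'
#' Computes per-joint velocity, acceleration and jerk by forward finite
#' differences, \eqn{V_i = (P_{i+1} - P_i)/\Delta T}, with Savitzky-Golay
#' smoothing applied after each differencing stage. All three arrays are
#' trimmed to the common valid range \eqn{N' = N - 3} so every downstream
#' feature averages over an identical set of frames.
#'
#' @param positions Numeric array \code{[N x J x 3]} (a \code{[N x 3]} matrix
#'   is promoted to one joint).
#' @param fps Frame rate in Hz.
#' @param config A [smoothing_config()].
#' @return An object of class \code{derivative_stack}: list with
#'   \code{velocity}, \code{acceleration}, \code{jerk} (each
#'   \code{[N' x J x 3]}), \code{valid_frames}, \code{fps}, \code{smoothing}.
#' @export
differentiate <- function(positions, fps, config = smoothing_config()) {
  if (length(dim(positions)) == 2) {
    positions <- array(positions, c(nrow(positions), 1, ncol(positions)))
  }
  n <- dim(positions)[1]
  if (n < 4) stop("length error: need at least 4 frames", call. = FALSE)
  if (config$enabled && n < config$window + 3) {
    stop("length error: need at least window + 3 frames when smoothing",
         call. = FALSE)
  }
  dt <- 1 / fps
  vel <- smooth_array(forward_diff(positions, dt), config)
  acc <- smooth_array(forward_diff(vel, dt), config)
  jrk <- smooth_array(forward_diff(acc, dt), config)
  np <- n - 3L
  trim <- function(a) a[seq_len(np), , , drop = FALSE]
  structure(
    list(velocity = trim(vel), acceleration = trim(acc), jerk = jrk,
         valid_frames = np, fps = fps, smoothing = config),
    class = "derivative_stack"
  )
}

# Derivative stack restricted to a subset of joints.
stack_joints <- function(stack, joints) {
  structure(
    list(velocity = stack$velocity[, joints, , drop = FALSE],
         acceleration = stack$acceleration[, joints, , drop = FALSE],
         jerk = stack$jerk[, joints, , drop = FALSE],
         valid_frames = stack$valid_frames, fps = stack$fps,
         smoothing = stack$smoothing),
    class = "derivative_stack"
  )
}

# Row-wise Euclidean norms of an [N x 3] matrix or [N x J x 3] array
# (the latter returns an [N x J] matrix).
vector_norms <- function(a) {
  if (length(dim(a)) == 3) {
    sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2)
  } else {
    sqrt(rowSums(a^2))
  }
}

# Population standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
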