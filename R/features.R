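#' The interpretable movement-feature registry
#'
#' The encoding summarizes a pose sequence as 17 named scalars in four
#' categories: movement of the sacrum (5), movement of the extremities (4),
#' sacrum-centred angular momentum (6), and body expandedness (2). The
#' augmented registry appends 3 rhythm features counting prominent peaks of
#' the autocorrelation of angular momentum along each spatial axis.
#'
#' Counts of sharp movements and autocorrelation peaks are emitted as
#' per-second rates, not raw counts, so that sequence duration (which varies
#' several-fold between basic and advanced pieces) does not leak into the
#' encoding.
#'
#' @param augmented Append the 3 autocorrelation rhythm features?
#' @return An object of class \code{feature_registry}: list with a
#'   \code{specs} data frame (name, category, units, description) and the
#'   \code{augmented} flag.
#' @export
feature_registry <- function(augmented = FALSE) {
  specs <- data.frame(
    name = c("sacrum_xz_speed_mean", "sacrum_height_sd", "sacrum_jerkiness",
             "bounce_frequency", "bounce_regularity",
             "wrist_accel_mean", "ankle_accel_mean",
             "ankle_height_mean", "ankle_height_sd",
             "angmom_mean_mag", "angmom_sd_mag", "horizontal_rotation",
             "sharp_rate_x", "sharp_rate_y", "sharp_rate_z",
             "expandedness_mean", "expandedness_sd"),
    category = c(rep("sacrum", 5), rep("extremities", 4),
                 rep("angular_momentum", 6), rep("expandedness", 2)),
    units = c("m/s", "m", "m/s^3", "Hz", "unitless",
              "m/s^2", "m/s^2", "m", "m",
              "m^2/s", "m^2/s", "m^2/s", "peaks/s", "peaks/s", "peaks/s",
              "m", "m"),
    description = c(
      "mean horizontal (floor-plane) speed of the sacrum",
      "SD of the sacrum's vertical position",
      "mean magnitude of sacrum jerk",
      "dominant frequency of the sacrum's vertical oscillation",
      "first-peak height of the vertical bounce autocorrelation",
      "mean wrist acceleration magnitude",
      "mean ankle acceleration magnitude",
      "mean ankle height above the inferred floor",
      "SD of ankle height above the inferred floor",
      "mean magnitude of joint angular momentum about the sacrum",
      "SD of joint angular momentum magnitude",
      "mean vertical-axis angular momentum magnitude (horizontal rotation)",
      "prominent peaks per second of x-axis summed angular momentum",
      "prominent peaks per second of y-axis summed angular momentum",
      "prominent peaks per second of z-axis summed angular momentum",
      "mean distance of joints from the sacrum",
      "SD of joint-to-sacrum distance"),
    stringsAsFactors = FALSE
  )
  if (augmented) {
    specs <- rbind(specs, data.frame(
      name = c("autocorr_peak_rate_x", "autocorr_peak_rate_y",
               "autocorr_peak_rate_z"),
      category = "angular_momentum",
      units = "peaks/s",
      description = paste("prominent autocorrelation peaks per second of",
                          c("x", "y", "z"), "axis angular momentum"),
      stringsAsFactors = FALSE
    ))
  }
  structure(list(specs = specs, augmented = isTRUE(augmented)),
            class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("feature_registry: %d features (%saugmented)\n",
              nrow(x$specs), if (x$augmented) "" else "not "))
  print(table(x$specs$category))
  invisible(x)
}

# Broadcast an [N x 3] track to an [N x J x 3] array ([i, j, a] = track[i, a]).
broadcast_track <- function(track, J) {
  n <- nrow(track)
  out <- array(0, c(n, J, 3))
  for (a in 1:3) out[, , a] <- track[, a]  # recycles down columns
  out
}

# ---------------------------------------------------------------------------
# Peak detection with topographic prominence (lowest contour line): for each
# local maximum, walk outward on each side to the nearest strictly higher
# sample (or the boundary), take the minimum en route, and subtract the
# higher of the two side minima from the peak height.
find_prominent_peaks <- function(x, prominence_min, height_min = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(is_peak))
  for (k in seq_along(is_peak)) {
    i <- is_peak[k]
    h <- x[i]
    if (h < height_min) next
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (h - max(lmin, rmin) >= prominence_min) keep[k] <- TRUE
  }
  is_peak[keep]
}

# ---------------------------------------------------------------------------

#' Sacrum jerkiness
#'
#' Mean magnitude of the sacrum's jerk over the valid frame range: how
#' abrupt the dancer's core movement is.
#'
#' @param sacrum_stack A [differentiate()] stack computed on the sacrum
#'   track (one joint).
#' @return Scalar, m/s^3.
#' @export
sacrum_jerkiness <- function(sacrum_stack) {
  if (sacrum_stack$valid_frames < 1) stop("length error: empty valid range",
                                          call. = FALSE)
  mean(vector_norms(sacrum_stack$jerk))
}

#' Ankle height statistics
#'
#' The floor is inferred as the minimum over all frames of the lower of the
#' two ankles' vertical coordinates; per-frame ankle height is the mean of
#' the two ankles' vertical coordinates above that floor.
#'
#' @param pose A [pose_sequence()].
#' @return List with \code{mean} and \code{sd} (population SD), metres.
#' @export
ankle_height_stats <- function(pose) {
  va <- pose$layout$vertical_axis
  la <- pose$positions[, role_idx(pose$layout, "left_ankle"), va]
  ra <- pose$positions[, role_idx(pose$layout, "right_ankle"), va]
  floor_y <- min(pmin(la, ra))
  h <- (la + ra) / 2 - floor_y
  list(mean = mean(h), sd = pop_sd(h))
}

#' Mean extremity acceleration
#'
#' Mean over frames and over the two named joints of the Euclidean norm of
#' acceleration.
#'
#' @param stack Full-skeleton [differentiate()] stack.
#' @param layout The skeleton layout.
#' @param role_pair \code{"wrists"} or \code{"ankles"}.
#' @return Scalar, m/s^2.
#' @export
extremity_acceleration <- function(stack, layout, role_pair = c("wrists", "ankles")) {
  role_pair <- match.arg(role_pair)
  roles <- if (role_pair == "wrists") c("left_wrist", "right_wrist")
           else c("left_ankle", "right_ankle")
  idx <- vapply(roles, function(r) role_idx(layout, r), integer(1))
  mean(vector_norms(stack$acceleration[, idx, , drop = FALSE]))
}

#' Angular momentum of every joint about the sacrum
#'
#' Per joint and frame, the relative position \eqn{R_{ij} = P_{ij} - SP_i}
#' is crossed with the joint's velocity vector, \eqn{L_{ij} = R_{ij} \times
#' V_{ij}} (unit mass). All skeleton joints (hips included) enter; the
#' synthetic sacrum itself does not.
#'
#' @param pose A [pose_sequence()].
#' @param sacrum Sacrum track from [estimate_sacrum()].
#' @param stack Full-skeleton [differentiate()] stack for the pose.
#' @return Object of class \code{angmom_trace}: list with \code{L} and
#'   \code{R} arrays \code{[N' x J x 3]} plus \code{fps}.
#' @export
angular_momentum_trace <- function(pose, sacrum, stack) {
  np <- stack$valid_frames
  if (nrow(sacrum) != n_frames(pose)) {
    stop("alignment error: sacrum track length mismatch", call. = FALSE)
  }
  J <- dim(pose$positions)[2]
  P <- pose$positions[seq_len(np), , , drop = FALSE]
  R <- P - broadcast_track(sacrum[seq_len(np), , drop = FALSE], J)
  V <- stack$velocity
  L <- array(0, dim = c(np, J, 3))
  L[, , 1] <- R[, , 2] * V[, , 3] - R[, , 3] * V[, , 2]
  L[, , 2] <- R[, , 3] * V[, , 1] - R[, , 1] * V[, , 3]
  L[, , 3] <- R[, , 1] * V[, , 2] - R[, , 2] * V[, , 1]
  structure(list(L = L, R = R, fps = stack$fps), class = "angmom_trace")
}

#' Summary statistics of the angular-momentum trace
#'
#' Horizontal rotation -- turning in the floor plane -- physically produces
#' angular momentum along the vertical axis, so the default reports the mean
#' magnitude of the vertical (y) component. The variant \code{"xz"} instead
#' averages the magnitude of the (x, z) components.
#'
#' @param trace An [angular_momentum_trace()] result.
#' @param rotation_variant \code{"vertical"} (default) or \code{"xz"}.
#' @param vertical_axis Vertical axis index (default 2 = y).
#' @return List with \code{mean_mag}, \code{sd_mag},
#'   \code{horizontal_rotation} (all m^2/s, unit mass).
#' @export
angular_momentum_stats <- function(trace, rotation_variant = c("vertical", "xz"),
                                   vertical_axis = 2L) {
  rotation_variant <- match.arg(rotation_variant)
  if (length(trace$L) == 0) stop("length error: empty trace", call. = FALSE)
  mags <- vector_norms(trace$L)
  hv <- if (rotation_variant == "vertical") {
    mean(abs(trace$L[, , vertical_axis]))
  } else {
    ha <- setdiff(1:3, vertical_axis)
    mean(sqrt(trace$L[, , ha[1]]^2 + trace$L[, , ha[2]]^2))
  }
  list(mean_mag = mean(mags), sd_mag = pop_sd(mags), horizontal_rotation = hv)
}

# Joint-summed angular momentum, [N' x 3].
summed_angmom <- function(trace) {
  apply(trace$L, c(1, 3), sum)
}

#' Sharp-movement rates
#'
#' Sharp dance movements register as prominent peaks in the joint-summed
#' angular-momentum trace. For each spatial axis, local maxima of the
#' absolute summed series with topographic prominence of at least
#' \code{prominence} times the series' population SD are counted and
#' divided by the duration of the valid range.
#'
#' @param trace An [angular_momentum_trace()] result.
#' @param fps Frame rate, Hz.
#' @param prominence Prominence threshold as a fraction of the series SD.
#' @return Named numeric \code{c(rate_x, rate_y, rate_z)}, peaks per second.
#' @export
sharp_movement_counts <- function(trace, fps = trace$fps, prominence = 1.0) {
  s <- summed_angmom(trace)
  n <- nrow(s)
  if (n < 3) stop("length error: need at least 3 valid frames", call. = FALSE)
  dur <- n / fps
  rates <- vapply(1:3, function(a) {
    sd_a <- pop_sd(s[, a])
    if (sd_a == 0) return(0)
    length(find_prominent_peaks(abs(s[, a]), prominence * sd_a)) / dur
  }, numeric(1))
  names(rates) <- c("rate_x", "rate_y", "rate_z")
  rates
}

#' Expandedness statistics
#'
#' Mean and population SD, pooled over joints and frames, of each joint's
#' Euclidean distance from the sacrum: how spread-out the body is, and how
#' much that varies.
#'
#' @param pose A [pose_sequence()].
#' @param sacrum Sacrum track from [estimate_sacrum()].
#' @return List with \code{mean} and \code{sd}, metres.
#' @export
expandedness_stats <- function(pose, sacrum) {
  J <- dim(pose$positions)[2]
  R <- pose$positions - broadcast_track(sacrum, J)
  d <- vector_norms(R)
  list(mean = mean(d), sd = pop_sd(d))
}

#' Sacrum translation statistics
#'
#' Mean floor-plane (horizontal) speed of the sacrum, and the population SD
#' of its vertical position (how much the dancer rises and falls).
#'
#' @param sacrum Sacrum track from [estimate_sacrum()].
#' @param sacrum_stack [differentiate()] stack of the sacrum track.
#' @param vertical_axis Vertical axis index (default 2 = y).
#' @return List with \code{xz_speed_mean} (m/s) and \code{height_sd} (m).
#' @export
sacrum_translation_stats <- function(sacrum, sacrum_stack, vertical_axis = 2L) {
  ha <- setdiff(1:3, vertical_axis)
  v <- sacrum_stack$velocity
  xz_speed <- sqrt(v[, 1, ha[1]]^2 + v[, 1, ha[2]]^2)
  list(xz_speed_mean = mean(xz_speed),
       height_sd = pop_sd(sacrum[, vertical_axis]))
}

# Normalized autocorrelation at lags 1..lag_max. With unbiased = TRUE the
# standard estimator's (1 - k/N) taper is undone, so peak heights do not
# depend on sequence length (a tiled periodic sequence would otherwise look
# "more regular"); the biased form keeps the noise variance stationary
# across lags, which suits significance-thresholded peak counting.
norm_acf <- function(x, lag_max, unbiased = FALSE) {
  n <- length(x)
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf
  r <- as.numeric(a)[-1]
  if (unbiased) r <- r * n / (n - seq_len(lag_max))
  r
}

#' Vertical bounce frequency and regularity
#'
#' On the mean-removed vertical sacrum series: the bounce frequency is the
#' location (Hz) of the largest magnitude-spectrum bin (excluding the zero
#' bin); bounce regularity is the height of the first prominent peak of the
#' normalized autocorrelation over positive lags, clipped to \eqn{[0, 1]}.
#' A periodic bounce gives regularity near 1; aperiodic noise gives values
#' near 0; a constant series returns \code{(0, 0)}.
#'
#' @param sacrum Sacrum track from [estimate_sacrum()].
#' @param fps Frame rate, Hz.
#' @param vertical_axis Vertical axis index (default 2 = y).
#' @param prominence_min Minimum autocorrelation peak prominence (correlation
#'   units) for a peak to count as "prominent".
#' @return List with \code{frequency} (Hz) and \code{regularity} (unitless).
#' @export
bounce_features <- function(sacrum, fps, vertical_axis = 2L,
                            prominence_min = 0.1) {
  y <- sacrum[, vertical_axis]
  n <- length(y)
  if (n < 2 * fps) stop("length error: need at least 2 s of frames", call. = FALSE)
  if (pop_sd(y) == 0) return(list(frequency = 0, regularity = 0))
  y <- y - mean(y)
  spec <- Mod(stats::fft(y))[seq_len(floor(n / 2) + 1)]
  k <- which.max(spec[-1])  # exclude zero-frequency bin
  frequency <- k * fps / n
  r <- norm_acf(y, lag_max = floor(n / 2), unbiased = TRUE)
  peaks <- find_prominent_peaks(r, prominence_min)
  regularity <- if (length(peaks) == 0) 0 else min(max(r[peaks[1]], 0), 1)
  list(frequency = frequency, regularity = regularity)
}

#' Autocorrelation peak counts of the angular-momentum trace
#'
#' A rhythmically uniform dance revisits similar rotational states at regular
#' intervals, producing prominent peaks in the autocorrelation of its
#' angular-momentum trace. For each axis, the joint-summed series'
#' normalized autocorrelation over positive lags (up to half the sequence)
#' is scanned with the same prominence rule as [sharp_movement_counts()];
#' peaks must additionally clear a white-noise significance band sized for
#' the maximum over all scanned lags (Bonferroni-corrected 5% level), so
#' that unstructured motion yields counts near zero.
#'
#' @param trace An [angular_momentum_trace()] result.
#' @param fps Frame rate, Hz.
#' @param prominence Prominence threshold as a fraction of the
#'   autocorrelation series' SD.
#' @return Named integer-ish numeric \code{c(n_x, n_y, n_z)}.
#' @export
autocorr_peak_counts <- function(trace, fps = trace$fps, prominence = 1.0) {
  s <- summed_angmom(trace)
  n <- nrow(s)
  if (n < 4 * fps) stop("length error: need at least 4 s of frames", call. = FALSE)
  lag_max <- floor(n / 2)
  # white-noise band for the *largest* of lag_max correlations (Bonferroni
  # at the 5% level), not the pointwise band: scanning hundreds of lags at
  # 2/sqrt(N) would count several spurious noise peaks
  band <- stats::qnorm(1 - 0.05 / (2 * lag_max)) / sqrt(n)
  counts <- vapply(1:3, function(a) {
    x <- s[, a]
    if (pop_sd(x) == 0) return(0)
    r <- norm_acf(x, lag_max)
    thr <- max(prominence * pop_sd(r), band)
    length(find_prominent_peaks(r, thr, height_min = band))
  }, numeric(1))
  names(counts) <- c("n_x", "n_y", "n_z")
  counts
}

#' Extract the full feature vector of a pose sequence
#'
#' Runs the whole featurization pipeline: sacrum estimation, smoothed
#' finite-difference kinematics, then every feature in the registry, in
#' registry order.
#'
#' @param pose A [pose_sequence()].
#' @param registry A [feature_registry()].
#' @param smoothing A [smoothing_config()].
#' @param rotation_variant Passed to [angular_momentum_stats()].
#' @param prominence Peak-prominence threshold (fraction of series SD).
#' @return A named numeric vector (class \code{feature_vector}) with
#'   attributes \code{sequence_id}, \code{genre}, \code{tier}.
#' @export
extract_features <- function(pose, registry = feature_registry(),
                             smoothing = smoothing_config(),
                             rotation_variant = c("vertical", "xz"),
                             prominence = 1.0) {
  rotation_variant <- match.arg(rotation_variant)
  va <- pose$layout$vertical_axis
  sacrum <- estimate_sacrum(pose)
  stack <- differentiate(pose$positions, pose$fps, smoothing)
  sac_stack <- differentiate(array(sacrum, c(nrow(sacrum), 1, 3)), pose$fps,
                             smoothing)
  trace <- angular_momentum_trace(pose, sacrum, stack)

  trans <- sacrum_translation_stats(sacrum, sac_stack, va)
  bounce <- bounce_features(sacrum, pose$fps, va)
  ankles <- ankle_height_stats(pose)
  am <- angular_momentum_stats(trace, rotation_variant, va)
  sharp <- sharp_movement_counts(trace, pose$fps, prominence)
  expand <- expandedness_stats(pose, sacrum)

  vals <- c(
    sacrum_xz_speed_mean = trans$xz_speed_mean,
    sacrum_height_sd = trans$height_sd,
    sacrum_jerkiness = sacrum_jerkiness(sac_stack),
    bounce_frequency = bounce$frequency,
    bounce_regularity = bounce$regularity,
    wrist_accel_mean = extremity_acceleration(stack, pose$layout, "wrists"),
    ankle_accel_mean = extremity_acceleration(stack, pose$layout, "ankles"),
    ankle_height_mean = ankles$mean,
    ankle_height_sd = ankles$sd,
    angmom_mean_mag = am$mean_mag,
    angmom_sd_mag = am$sd_mag,
    horizontal_rotation = am$horizontal_rotation,
    sharp_rate_x = unname(sharp["rate_x"]),
    sharp_rate_y = unname(sharp["rate_y"]),
    sharp_rate_z = unname(sharp["rate_z"]),
    expandedness_mean = expand$mean,
    expandedness_sd = expand$sd
  )
  if (registry$augmented) {
    counts <- autocorr_peak_counts(trace, pose$fps, prominence)
    lag_window_s <- floor(dim(trace$L)[1] / 2) / pose$fps
    vals <- c(vals,
              autocorr_peak_rate_x = unname(counts["n_x"]) / lag_window_s,
              autocorr_peak_rate_y = unname(counts["n_y"]) / lag_window_s,
              autocorr_peak_rate_z = unname(counts["n_z"]) / lag_window_s)
  }
  vals <- vals[registry$specs$name]
  if (!all(is.finite(vals))) {
    bad <- registry$specs$name[!is.finite(vals)]
    stop("feature error: non-finite value for ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(vals, sequence_id = pose$sequence_id,
            genre = pose$genre %||% NA_character_,
            tier = pose$tier %||% NA_character_,
            class = "feature_vector")
}

#' Extract the feature matrix of a dataset
#'
#' @param data A [pose_dataset()].
#' @param registry A [feature_registry()].
#' @param smoothing A [smoothing_config()].
#' @param ... Passed to [extract_features()].
#' @return A data frame (class \code{feature_matrix}) with columns
#'   \code{sequence_id}, \code{genre}, \code{tier}, then the features in
#'   registry order; the registry is attached as attribute
#'   \code{"registry"}.
#' @export
extract_feature_matrix <- function(data, registry = feature_registry(),
                                   smoothing = smoothing_config(), ...) {
  stopifnot(inherits(data, "pose_dataset"))
  rows <- lapply(data$sequences, function(pose) {
    fv <- extract_features(pose, registry, smoothing, ...)
    cbind(data.frame(sequence_id = attr(fv, "sequence_id"),
                     genre = attr(fv, "genre"),
                     tier = attr(fv, "tier"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "registry") <- registry
  class(out) <- c("feature_matrix", class(out))
  out
}

# Numeric feature block of a feature matrix, in registry order.
feature_block <- function(fm, registry = attr(fm, "registry")) {
  as.matrix(fm[, registry$specs$name, drop = FALSE])
}
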