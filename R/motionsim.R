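#' Default standing base pose
#'
#' A fixed 17-joint (COCO layout) standing template with realistic segment
#' proportions for a 1.7 m tall figure, y up, facing +z. Used as the
#' skeleton every simulated dance deforms.
#'
#' @return Numeric \code{17 x 3} matrix, metres.
#' @export
default_base_pose <- function() {
  m <- rbind(
    nose           = c( 0.00, 1.62, 0.08),
    left_eye       = c( 0.03, 1.66, 0.07),
    right_eye      = c(-0.03, 1.66, 0.07),
    left_ear       = c( 0.07, 1.63, 0.02),
    right_ear      = c(-0.07, 1.63, 0.02),
    left_shoulder  = c( 0.20, 1.43, 0.00),
    right_shoulder = c(-0.20, 1.43, 0.00),
    left_elbow     = c( 0.24, 1.16, 0.02),
    right_elbow    = c(-0.24, 1.16, 0.02),
    left_wrist     = c( 0.26, 0.91, 0.05),
    right_wrist    = c(-0.26, 0.91, 0.05),
    left_hip       = c( 0.11, 0.95, 0.00),
    right_hip      = c(-0.11, 0.95, 0.00),
    left_knee      = c( 0.12, 0.52, 0.02),
    right_knee     = c(-0.12, 0.52, 0.02),
    left_ankle     = c( 0.13, 0.08, 0.00),
    right_ankle    = c(-0.13, 0.08, 0.00)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Specification of a simulated dance motion
#'
#' Each parameter drives one interpretable component of motion, so the
#' features extracted from a generated sequence can be checked against
#' closed-form expectations (see [expected_features()]).
#'
#' @param duration Sequence length, seconds.
#' @param fps Frame rate, Hz (default 60, the capture rate of the public
#'   dance keypoint collections this emulates).
#' @param base_pose \code{J x 3} static template; default
#'   [default_base_pose()].
#' @param bounce_amplitude Vertical whole-body sinusoid amplitude, m.
#' @param bounce_frequency Vertical sinusoid frequency, Hz.
#' @param spin_rate Steady rotation about the vertical axis through the
#'   sacrum, rad/s.
#' @param limb_amplitude Amplitude of sinusoidal wrist (lateral) and ankle
#'   (vertical) oscillation, m.
#' @param limb_frequency Limb oscillation frequency, Hz.
#' @param expand_scale Multiplier on all joint-to-sacrum offsets.
#' @param sharp_event_rate Poisson rate (events/s) of brief impulsive body
#'   twists.
#' @param sharp_magnitude Peak twist angle of one sharp event, rad.
#' @param noise_sd SD of additive Gaussian position noise, m.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class \code{motion_spec}.
#' @export
motion_spec <- function(duration = 10, fps = 60, base_pose = default_base_pose(),
                        bounce_amplitude = 0, bounce_frequency = 0,
                        spin_rate = 0, limb_amplitude = 0, limb_frequency = 0,
                        expand_scale = 1, sharp_event_rate = 0,
                        sharp_magnitude = 0.3, noise_sd = 0, seed = 1L) {
  stopifnot(duration > 0, fps > 0, bounce_amplitude >= 0,
            bounce_frequency >= 0, limb_amplitude >= 0, limb_frequency >= 0,
            expand_scale > 0, sharp_event_rate >= 0, sharp_magnitude >= 0,
            noise_sd >= 0)
  structure(list(duration = duration, fps = fps, base_pose = base_pose,
                 bounce_amplitude = bounce_amplitude,
                 bounce_frequency = bounce_frequency, spin_rate = spin_rate,
                 limb_amplitude = limb_amplitude,
                 limb_frequency = limb_frequency, expand_scale = expand_scale,
                 sharp_event_rate = sharp_event_rate,
                 sharp_magnitude = sharp_magnitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

# Smooth polynomial bump on [0, 1]: zero at both ends, 1 at the centre.
bump <- function(u) ifelse(u > 0 & u < 1, 16 * u^2 * (1 - u)^2, 0)

#' Generate a simulated pose sequence
#'
#' The skeleton's joint-to-sacrum offsets are scaled by
#' \code{expand_scale}; wrists and ankles oscillate sinusoidally in the body
#' frame; the body rotates about the vertical axis through the sacrum by the
#' steady spin plus impulsive 3-frame twist bumps at Poisson event times;
#' the whole body then translates by the vertical bounce sinusoid; Gaussian
#' position noise is added last.
#'
#' @param spec A [motion_spec()].
#' @param sequence_id Identifier for the resulting sequence.
#' @param genre,tier Optional labels to attach.
#' @param layout Skeleton layout of \code{base_pose}.
#' @return A [pose_sequence()].
#' @export
generate_motion <- function(spec, sequence_id = "sim", genre = NULL,
                            tier = NULL, layout = coco17_layout()) {
  n <- max(4L, round(spec$duration * spec$fps))
  t <- (seq_len(n) - 1) / spec$fps
  J <- nrow(spec$base_pose)
  lh <- role_idx(layout, "left_hip"); rh <- role_idx(layout, "right_hip")
  sacrum0 <- (spec$base_pose[lh, ] + spec$base_pose[rh, ]) / 2
  offsets <- sweep(spec$base_pose, 2, sacrum0) * spec$expand_scale

  withr::with_seed(spec$seed, {
    # impulsive twist angle trace
    twist <- numeric(n)
    if (spec$sharp_event_rate > 0) {
      n_events <- stats::rpois(1, spec$sharp_event_rate * spec$duration)
      if (n_events > 0) {
        times <- sort(stats::runif(n_events, 0, spec$duration))
        width <- 3 / spec$fps
        signs <- sample(c(-1, 1), n_events, replace = TRUE)
        for (k in seq_len(n_events)) {
          twist <- twist +
            signs[k] * spec$sharp_magnitude * bump((t - times[k]) / width)
        }
      }
    }
    noise <- if (spec$noise_sd > 0) {
      array(stats::rnorm(n * J * 3, sd = spec$noise_sd), c(n, J, 3))
    } else NULL
  })

  theta <- spec$spin_rate * t + twist
  ct <- cos(theta); st <- sin(theta)
  bounce_y <- spec$bounce_amplitude * sin(2 * pi * spec$bounce_frequency * t)

  # body-frame limb oscillation
  lw <- role_idx(layout, "left_wrist"); rw <- role_idx(layout, "right_wrist")
  la <- role_idx(layout, "left_ankle"); ra <- role_idx(layout, "right_ankle")
  wl <- spec$limb_amplitude * sin(2 * pi * spec$limb_frequency * t)
  wr <- spec$limb_amplitude * sin(2 * pi * spec$limb_frequency * t + pi)
  al <- spec$limb_amplitude * sin(2 * pi * spec$limb_frequency * t)
  ar <- spec$limb_amplitude * sin(2 * pi * spec$limb_frequency * t + pi / 2)

  positions <- array(0, c(n, J, 3))
  for (j in seq_len(J)) {
    ox <- rep(offsets[j, 1], n); oy <- rep(offsets[j, 2], n)
    oz <- rep(offsets[j, 3], n)
    if (j == lw) ox <- ox + wl
    if (j == rw) ox <- ox + wr
    if (j == la) oy <- oy + al
    if (j == ra) oy <- oy + ar
    positions[, j, 1] <- sacrum0[1] + ox * ct + oz * st
    positions[, j, 2] <- sacrum0[2] + bounce_y + oy
    positions[, j, 3] <- sacrum0[3] - ox * st + oz * ct
  }
  if (!is.null(noise)) positions <- positions + noise

  pose_sequence(positions, fps = spec$fps, layout = layout,
                sequence_id = sequence_id, genre = genre, tier = tier)
}

# At most one dynamic parameter class may be active for the closed-form
# oracles to hold.
active_classes <- function(spec) {
  classes <- c(
    bounce = spec$bounce_amplitude > 0 && spec$bounce_frequency > 0,
    spin = spec$spin_rate != 0,
    limb = spec$limb_amplitude > 0 && spec$limb_frequency > 0,
    sharp = spec$sharp_event_rate > 0
  )
  names(classes)[classes]
}

#' Closed-form feature expectations for a simulated motion
#'
#' Valid when the spec is noise-free and at most one dynamic parameter
#' class (bounce, spin, limb, sharp) is active; the expectations describe
#' the continuous-time motion, which raw finite differences recover up to
#' discretization error (compare with smoothing disabled). Features without
#' a closed form under the given spec are omitted from the result.
#'
#' Key forms: a vertical sinusoid of amplitude \eqn{A} and frequency
#' \eqn{f} has mean jerk magnitude \eqn{A (2\pi f)^3 \cdot 2/\pi}, height
#' SD \eqn{A/\sqrt 2}, and mean acceleration magnitude
#' \eqn{A (2\pi f)^2 \cdot 2/\pi}; steady rotation at \eqn{\omega} about
#' the vertical axis gives each joint angular momentum of magnitude
#' \eqn{\omega r \sqrt{r^2 + h^2}} with vertical component
#' \eqn{\omega r^2}, where \eqn{r} and \eqn{h} are the joint's horizontal
#' radius and height relative to the sacrum.
#'
#' @param spec A [motion_spec()].
#' @return Named list of expected feature values (a subset of the registry).
#' @export
expected_features <- function(spec) {
  if (spec$noise_sd > 0) {
    stop("oracle-domain error: expectations require noise_sd = 0", call. = FALSE)
  }
  act <- active_classes(spec)
  if (length(act) > 1) {
    stop("oracle-domain error: at most one dynamic parameter class may be ",
         "active (got ", paste(act, collapse = ", "), ")", call. = FALSE)
  }
  layout <- coco17_layout()
  lh <- role_idx(layout, "left_hip"); rh <- role_idx(layout, "right_hip")
  sacrum0 <- (spec$base_pose[lh, ] + spec$base_pose[rh, ]) / 2
  offsets <- sweep(spec$base_pose, 2, sacrum0) * spec$expand_scale
  d <- sqrt(rowSums(offsets^2))
  out <- list()

  if (!("limb" %in% act)) {
    out$expandedness_mean <- mean(d)
    out$expandedness_sd <- pop_sd(d)
  }
  if (length(act) == 0) {
    out <- c(out, list(
      sacrum_xz_speed_mean = 0, sacrum_height_sd = 0, sacrum_jerkiness = 0,
      bounce_frequency = 0, bounce_regularity = 0,
      wrist_accel_mean = 0, ankle_accel_mean = 0,
      angmom_mean_mag = 0, angmom_sd_mag = 0, horizontal_rotation = 0,
      sharp_rate_x = 0, sharp_rate_y = 0, sharp_rate_z = 0
    ))
  } else if (act == "bounce") {
    A <- spec$bounce_amplitude; w <- 2 * pi * spec$bounce_frequency
    out$sacrum_jerkiness <- A * w^3 * 2 / pi
    out$sacrum_height_sd <- A / sqrt(2)
    out$bounce_frequency <- spec$bounce_frequency
    out$sacrum_xz_speed_mean <- 0
    out$wrist_accel_mean <- A * w^2 * 2 / pi
    out$ankle_accel_mean <- A * w^2 * 2 / pi
  } else if (act == "spin") {
    w <- abs(spec$spin_rate)
    r <- sqrt(offsets[, 1]^2 + offsets[, 3]^2)
    h <- offsets[, 2]
    mags <- w * r * sqrt(r^2 + h^2)
    out$angmom_mean_mag <- mean(mags)
    out$angmom_sd_mag <- pop_sd(mags)
    out$horizontal_rotation <- w * mean(r^2)
    out$sacrum_jerkiness <- 0
    out$sacrum_height_sd <- 0
    out$sacrum_xz_speed_mean <- 0
  } else if (act == "limb") {
    A <- spec$limb_amplitude; w <- 2 * pi * spec$limb_frequency
    out$wrist_accel_mean <- A * w^2 * 2 / pi
    out$ankle_accel_mean <- A * w^2 * 2 / pi
    out$sacrum_jerkiness <- 0
    out$sacrum_xz_speed_mean <- 0
    out$sacrum_height_sd <- 0
  }
  out
}

#' A genre template for the simulator
#'
#' @param name Genre name.
#' @param spec_mean A [motion_spec()] holding the genre's mean parameters.
#' @param spec_jitter Relative SD applied multiplicatively to each numeric
#'   motion parameter when sampling individual sequences.
#' @return Object of class \code{genre_template}.
#' @export
genre_template <- function(name, spec_mean, spec_jitter = 0.08) {
  stopifnot(spec_jitter >= 0)
  structure(list(name = name, spec_mean = spec_mean,
                 spec_jitter = spec_jitter),
            class = "genre_template")
}

#' Default ten-genre simulator templates
#'
#' Ten templates named after the street-dance genres of the public dance
#' keypoint collection, each combining the simulator dials (bounce, spin,
#' limb oscillation, expandedness, sharp-event rate) in a distinct way:
#' e.g. a high-bounce high-sharp "Break", a level-sacrum high-sharp
#' "Krump", a steady mid-bounce "House", an expansive spinning
#' "Ballet Jazz". The parameter values are caricatures chosen to give the
#' genres distinct kinematic signatures, not measurements of real dances.
#'
#' @param noise_sd Position noise common to all templates, m.
#' @param spec_jitter Relative between-sequence parameter SD.
#' @return List of ten [genre_template()]s.
#' @export
default_genre_templates <- function(noise_sd = 0.005, spec_jitter = 0.08) {
  p <- list(
    "Ballet Jazz" = c(0.030, 1.0, 0.90, 0.22, 1.0, 1.15, 0.3),
    "Break"       = c(0.070, 2.6, 1.40, 0.25, 2.4, 1.05, 1.8),
    "House"       = c(0.060, 2.2, 0.50, 0.18, 2.2, 1.00, 0.9),
    "Krump"       = c(0.015, 0.8, 0.25, 0.28, 1.8, 1.10, 2.2),
    "LA Hip Hop"  = c(0.040, 1.8, 0.60, 0.18, 1.6, 1.00, 1.0),
    "Lock"        = c(0.030, 2.0, 0.35, 0.30, 2.0, 1.08, 1.5),
    "Mid Hip Hop" = c(0.055, 1.6, 0.45, 0.15, 1.4, 0.95, 0.7),
    "Pop"         = c(0.020, 1.2, 0.30, 0.20, 2.8, 0.92, 1.3),
    "Street Jazz" = c(0.035, 1.4, 0.80, 0.24, 1.8, 1.12, 0.6),
    "Waack"       = c(0.025, 1.1, 1.10, 0.32, 2.6, 1.02, 0.4)
  )
  lapply(names(p), function(g) {
    v <- p[[g]]
    genre_template(g, motion_spec(
      bounce_amplitude = v[1], bounce_frequency = v[2], spin_rate = v[3],
      limb_amplitude = v[4], limb_frequency = v[5], expand_scale = v[6],
      sharp_event_rate = v[7], noise_sd = noise_sd
    ), spec_jitter = spec_jitter)
  })
}

jitter_value <- function(x, rel_sd, lower = 0) {
  max(lower, x * (1 + stats::rnorm(1, sd = rel_sd)))
}

#' Generate a labelled multi-genre dataset
#'
#' Samples \code{n_per_genre} sequences from each template, jittering the
#' motion parameters multiplicatively. Tiers mimic the basic/advanced
#' structure of the public dance collection: basic sequences average 9.25 s
#' (SD 1.6), advanced 36.5 s (SD 6.1), both clipped to the collection's
#' 7.4--48 s range, with the advanced share of each genre set by
#' \code{advanced_fraction} (rounded half up).
#'
#' @param templates List of [genre_template()]s; default
#'   [default_genre_templates()].
#' @param n_per_genre Sequences per genre.
#' @param advanced_fraction Proportion of each genre's sequences labelled
#'   advanced (default 1/7, i.e. a 6:1 basic:advanced mix).
#' @param seed Integer seed.
#' @return A [pose_dataset()] with a \code{"manifest"} attribute recording
#'   each sequence's true simulation parameters.
#' @export
generate_genre_dataset <- function(templates = default_genre_templates(),
                                   n_per_genre = 12,
                                   advanced_fraction = 1 / 7, seed = 1L) {
  stopifnot(length(templates) >= 2, n_per_genre >= 1)
  sequences <- list()
  manifest <- list()
  withr::with_seed(seed, {
    for (tpl in templates) {
      n_adv <- min(n_per_genre, round_half_up(advanced_fraction * n_per_genre))
      tiers <- c(rep("advanced", n_adv), rep("basic", n_per_genre - n_adv))
      for (i in seq_len(n_per_genre)) {
        tier <- tiers[i]
        dur <- if (tier == "basic") stats::rnorm(1, 9.25, 1.6)
               else stats::rnorm(1, 36.5, 6.1)
        dur <- min(48, max(7.4, dur))
        m <- tpl$spec_mean
        js <- tpl$spec_jitter
        spec <- motion_spec(
          duration = dur, fps = m$fps, base_pose = m$base_pose,
          bounce_amplitude = jitter_value(m$bounce_amplitude, js),
          bounce_frequency = jitter_value(m$bounce_frequency, js),
          spin_rate = jitter_value(m$spin_rate, js),
          limb_amplitude = jitter_value(m$limb_amplitude, js),
          limb_frequency = jitter_value(m$limb_frequency, js),
          expand_scale = jitter_value(m$expand_scale, js, lower = 0.1),
          sharp_event_rate = jitter_value(m$sharp_event_rate, js),
          sharp_magnitude = m$sharp_magnitude, noise_sd = m$noise_sd,
          seed = sample.int(.Machine$integer.max, 1)
        )
        id <- sprintf("%s_%s_%03d", gsub("[^A-Za-z]", "", tpl$name),
                      tier, i)
        sequences[[length(sequences) + 1L]] <-
          generate_motion(spec, sequence_id = id, genre = tpl$name,
                          tier = tier)
        manifest[[length(manifest) + 1L]] <- data.frame(
          sequence_id = id, genre = tpl$name, tier = tier,
          duration = dur, bounce_amplitude = spec$bounce_amplitude,
          bounce_frequency = spec$bounce_frequency,
          spin_rate = spec$spin_rate, limb_amplitude = spec$limb_amplitude,
          limb_frequency = spec$limb_frequency,
          expand_scale = spec$expand_scale,
          sharp_event_rate = spec$sharp_event_rate,
          noise_sd = spec$noise_sd, seed = spec$seed,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  ds <- pose_dataset(sequences,
                     genre_vocabulary = vapply(templates, `[[`, "", "name"))
  attr(ds, "manifest") <- do.call(rbind, manifest)
  ds
}
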