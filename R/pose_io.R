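#' Skeleton joint layout
#'
#' A layout names the joints of the skeleton, maps the six anatomical roles
#' needed by the feature computations (hips, wrists, ankles, left and right)
#' to joint indices, and records which coordinate axis points up.
#'
#' @param joint_names Character vector of joint names, in array order.
#' @param role_index Named integer vector mapping the roles
#'   \code{left_hip}, \code{right_hip}, \code{left_wrist}, \code{right_wrist},
#'   \code{left_ankle}, \code{right_ankle} to 1-based joint indices.
#' @param vertical_axis Which of the three coordinate axes is vertical
#'   (1 = x, 2 = y, 3 = z). Default 2: y is up, x-z is the floor plane.
#'
#' @return An object of class \code{joint_layout}.
#' @seealso [coco17_layout()] for the default 17-keypoint layout.
#' @export
joint_layout <- function(joint_names, role_index, vertical_axis = 2L) {
  required <- c("left_hip", "right_hip", "left_wrist", "right_wrist",
                "left_ankle", "right_ankle")
  missing_roles <- setdiff(required, names(role_index))
  if (length(missing_roles) > 0) {
    stop("layout error: missing joint roles: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  role_index <- vapply(role_index, as.integer, integer(1))
  idx <- role_index[required]
  if (anyDuplicated(idx)) {
    stop("layout error: role indices must be distinct", call. = FALSE)
  }
  if (any(idx < 1L) || any(idx > length(joint_names))) {
    stop("layout error: role index outside joint range", call. = FALSE)
  }
  if (!vertical_axis %in% 1:3) {
    stop("layout error: vertical_axis must be 1, 2 or 3", call. = FALSE)
  }
  structure(
    list(joint_names = as.character(joint_names),
         role_index = role_index,
         vertical_axis = as.integer(vertical_axis)),
    class = "joint_layout"
  )
}

#' The COCO-17 keypoint layout
#'
#' The standard 17-keypoint human skeleton (nose, eyes, ears, shoulders,
#' elbows, wrists, hips, knees, ankles) used by common pose-estimation
#' pipelines and by large 3D dance-motion keypoint collections. The layout
#' omits the spine, so the sacrum must be approximated from the hips
#' (see [estimate_sacrum()]).
#'
#' @return A \code{joint_layout} with 17 joints and y as the vertical axis.
#' @export
coco17_layout <- function() {
  names17 <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
               "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
               "left_wrist", "right_wrist", "left_hip", "right_hip",
               "left_knee", "right_knee", "left_ankle", "right_ankle")
  joint_layout(
    names17,
    role_index = c(left_hip = 12L, right_hip = 13L,
                   left_wrist = 10L, right_wrist = 11L,
                   left_ankle = 16L, right_ankle = 17L),
    vertical_axis = 2L
  )
}

n_joints <- function(layout) length(layout$joint_names)

role_idx <- function(layout, role) unname(layout$role_index[[role]])

horizontal_axes <- function(layout) setdiff(1:3, layout$vertical_axis)

#' Construct a pose sequence
#'
#' A pose sequence holds an \code{N x J x 3} array of 3D joint positions
#' sampled at a fixed frame rate, together with its skeleton layout and
#' optional genre / tier labels.
#'
#' @param positions Numeric array \code{[frames x joints x 3]}, metres.
#' @param fps Frames per second (Hz, > 0).
#' @param layout A [joint_layout()]; defaults to [coco17_layout()].
#' @param sequence_id Identifier string.
#' @param genre Optional genre label.
#' @param tier Optional \code{"basic"} or \code{"advanced"}.
#'
#' @return An object of class \code{pose_sequence}.
#' @export
pose_sequence <- function(positions, fps, layout = coco17_layout(),
                          sequence_id = "sequence", genre = NULL, tier = NULL) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3) {
    stop("data error: positions must be a [frames x joints x 3] array",
         call. = FALSE)
  }
  if (dim(positions)[1] < 4) {
    stop("too-short error: at least 4 frames are required (third differences)",
         call. = FALSE)
  }
  if (dim(positions)[2] != n_joints(layout)) {
    stop("layout error: joint count ", dim(positions)[2],
         " does not match layout (", n_joints(layout), ")", call. = FALSE)
  }
  if (!all(is.finite(positions))) {
    stop("data error: non-finite coordinates", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) {
    stop("data error: fps must be positive", call. = FALSE)
  }
  if (!is.null(tier)) tier <- match.arg(tier, c("basic", "advanced"))
  structure(
    list(sequence_id = as.character(sequence_id),
         fps = as.numeric(fps),
         positions = unname(positions),
         layout = layout,
         genre = genre,
         tier = tier),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("pose_sequence '%s': %d frames x %d joints @ %g fps (%.1f s)\n",
              x$sequence_id, d[1], d[2], x$fps, d[1] / x$fps))
  if (!is.null(x$genre)) cat("  genre:", x$genre, "\n")
  if (!is.null(x$tier)) cat("  tier: ", x$tier, "\n")
  invisible(x)
}

n_frames <- function(pose) dim(pose$positions)[1]

duration_s <- function(pose) n_frames(pose) / pose$fps

#' Construct a dataset of pose sequences
#'
#' @param sequences List of [pose_sequence()] objects.
#' @param genre_vocabulary Ordered character vector of genre names. Defaults
#'   to the distinct genres present among the sequences.
#'
#' @return An object of class \code{pose_dataset}.
#' @export
pose_dataset <- function(sequences, genre_vocabulary = NULL) {
  stopifnot(is.list(sequences))
  genres <- unlist(lapply(sequences, function(s) s$genre %||% NA_character_))
  if (is.null(genre_vocabulary)) {
    genre_vocabulary <- sort(unique(genres[!is.na(genres)]))
  }
  labelled <- genres[!is.na(genres)]
  if (length(labelled) && !all(labelled %in% genre_vocabulary)) {
    stop("label error: sequence genre outside vocabulary", call. = FALSE)
  }
  structure(list(sequences = sequences,
                 genre_vocabulary = as.character(genre_vocabulary)),
            class = "pose_dataset")
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat(sprintf("pose_dataset: %d sequences, %d genres\n",
              length(x$sequences), length(x$genre_vocabulary)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of missing frames, per joint/axis column.
# Runs of missing frames longer than max_gap_s abort: long gaps cannot be
# reconstructed credibly by interpolation.
interpolate_missing <- function(positions, fps, max_gap_s = 0.5) {
  bad <- !is.finite(positions)
  if (!any(bad)) return(positions)
  bad_frame <- apply(bad, 1, any)
  r <- rle(bad_frame)
  if (any(r$values & r$lengths > max_gap_s * fps)) {
    stop("data error: run of missing frames longer than ", max_gap_s,
         " s", call. = FALSE)
  }
  n <- dim(positions)[1]
  for (j in seq_len(dim(positions)[2])) {
    for (a in 1:3) {
      col <- positions[, j, a]
      ok <- is.finite(col)
      if (all(ok)) next
      if (sum(ok) < 2) stop("data error: too few finite frames", call. = FALSE)
      positions[, j, a] <- stats::approx(which(ok), col[ok], xout = seq_len(n),
                                         rule = 2)$y
    }
  }
  if (!all(is.finite(positions))) {
    stop("data error: non-finite values after interpolation", call. = FALSE)
  }
  positions
}

# Convert z-up coordinates to the package's y-up convention by rotating
# about the x axis: (x, y, z) -> (x, z, -y).
zup_to_yup <- function(positions) {
  out <- positions
  out[, , 2] <- positions[, , 3]
  out[, , 3] <- -positions[, , 2]
  out
}

#' Read a pose sequence from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{\code{json}}{An object with fields \code{sequence_id}, \code{fps},
#'     \code{joints} (names) and \code{frames}, a list of per-frame
#'     \code{J x 3} matrices.}
#'   \item{\code{csv}}{A long table with columns \code{frame}, \code{joint},
#'     \code{x}, \code{y}, \code{z}; \code{joint} may hold names or indices.}
#'   \item{\code{aist_keypoints}}{A JSON serialization of the dance-motion
#'     keypoint container: a mapping holding an \code{N x 17 x 3} array under
#'     the key \code{"keypoints3d"} (sequences captured at 60 fps).}
#' }
#'
#' Frames with missing coordinates (NaN/NA) are linearly interpolated per
#' coordinate; runs of missing frames longer than 0.5 s raise an error.
#'
#' @param path File path.
#' @param format One of \code{"json"}, \code{"csv"}, \code{"aist_keypoints"}.
#' @param layout Skeleton layout the file must conform to.
#' @param fps Frame rate to assume when the file does not carry one.
#' @param z_up If \code{TRUE}, convert z-up input coordinates to y-up.
#'
#' @return A [pose_sequence()]. The sequence id is the filename stem; genre
#'   and tier are decoded from it with [parse_aist_name()] when possible.
#' @export
read_pose_sequence <- function(path, format = c("json", "csv", "aist_keypoints"),
                               layout = coco17_layout(), fps = 60,
                               z_up = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  J <- n_joints(layout)

  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    frames <- obj$frames
    if (is.list(frames)) frames <- simplify2array(frames)  # J x 3 x N
    if (length(dim(frames)) == 3 && dim(frames)[3] == 3) {
      # simplifyVector gave N x J x 3 directly
      positions <- frames
    } else {
      positions <- aperm(frames, c(3, 1, 2))
    }
    if (!is.null(obj$fps)) fps <- obj$fps
    if (!is.null(obj$sequence_id)) stem <- obj$sequence_id
  } else if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "joint", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      stop("data error: csv must have columns frame, joint, x, y, z",
           call. = FALSE)
    }
    jid <- tab$joint
    if (!is.numeric(jid)) jid <- match(jid, layout$joint_names)
    if (anyNA(jid)) stop("layout error: unknown joint name in csv", call. = FALSE)
    fid <- match(tab$frame, sort(unique(tab$frame)))
    N <- max(fid)
    positions <- array(NA_real_, c(N, J, 3))
    positions[cbind(fid, jid, 1L)] <- tab$x
    positions[cbind(fid, jid, 2L)] <- tab$y
    positions[cbind(fid, jid, 3L)] <- tab$z
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$keypoints3d)) {
      stop("data error: container lacks a 'keypoints3d' entry", call. = FALSE)
    }
    positions <- obj$keypoints3d
    if (length(dim(positions)) != 3) {
      stop("data error: keypoints3d is not a 3-way array", call. = FALSE)
    }
  }

  if (dim(positions)[2] != J) {
    stop("layout error: per-frame joint count ", dim(positions)[2],
         " does not match layout (", J, ")", call. = FALSE)
  }
  if (dim(positions)[1] < 4) {
    stop("too-short error: fewer than 4 usable frames", call. = FALSE)
  }
  positions <- interpolate_missing(positions, fps)
  if (z_up) positions <- zup_to_yup(positions)
  lab <- parse_aist_name(stem)
  genre <- lab$genre
  tier <- lab$tier
  if (format == "json") {
    genre <- obj$genre %||% genre
    tier <- obj$tier %||% tier
  }
  pose_sequence(positions, fps = fps, layout = layout, sequence_id = stem,
                genre = genre, tier = tier)
}

#' Write a pose sequence to disk
#'
#' @param pose A [pose_sequence()].
#' @param path Output path.
#' @param format \code{"json"} or \code{"csv"} (long table), matching the
#'   dialects of [read_pose_sequence()].
#' @return \code{path}, invisibly.
#' @export
write_pose_sequence <- function(pose, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(sequence_id = pose$sequence_id,
                fps = pose$fps,
                joints = pose$layout$joint_names,
                frames = pose$positions)
    if (!is.null(pose$genre)) obj$genre <- pose$genre
    if (!is.null(pose$tier)) obj$tier <- pose$tier
    # I(17) significant digits: doubles survive the round trip bit-for-bit
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  } else {
    N <- n_frames(pose); J <- dim(pose$positions)[2]
    tab <- data.frame(
      frame = rep(seq_len(N), each = J),
      joint = rep(pose$layout$joint_names, times = N),
      x = as.vector(t(pose$positions[, , 1])),
      y = as.vector(t(pose$positions[, , 2])),
      z = as.vector(t(pose$positions[, , 3]))
    )
    write_full_precision_csv(tab, path)
  }
  invisible(path)
}

#' Default filename token table for the dance-motion dataset
#'
#' The public 3D dance keypoint collection encodes genre and tier in its
#' sequence ids: a genre token (e.g. \code{gBR}) and a situation token
#' (\code{sBM} basic dance, \code{sFM} advanced dance). The table is plain
#' data so alternative conventions can be supplied.
#'
#' @return A list with \code{genres} (token -> genre name) and
#'   \code{tiers} (token -> tier).
#' @export
aist_name_table <- function() {
  list(
    genres = c(gBR = "Break", gPO = "Pop", gLO = "Lock", gMH = "Mid Hip Hop",
               gLH = "LA Hip Hop", gHO = "House", gWA = "Waack",
               gKR = "Krump", gJS = "Street Jazz", gJB = "Ballet Jazz"),
    tiers = c(sBM = "basic", sFM = "advanced")
  )
}

#' Decode genre and tier from a sequence id
#'
#' Pure function: ids that match the configured naming convention yield the
#' genre and tier; anything else yields \code{NULL}s.
#'
#' @param sequence_id Character id, e.g. \code{"gBR_sFM_cAll_d04_mBR0_ch01"}.
#' @param table Token table, by default [aist_name_table()].
#' @return List with elements \code{genre} and \code{tier} (either may be
#'   \code{NULL}).
#' @export
parse_aist_name <- function(sequence_id, table = aist_name_table()) {
  tokens <- strsplit(sequence_id, "_", fixed = TRUE)[[1]]
  g <- tokens[tokens %in% names(table$genres)]
  t <- tokens[tokens %in% names(table$tiers)]
  list(genre = if (length(g)) unname(table$genres[[g[1]]]) else NULL,
       tier = if (length(t)) unname(table$tiers[[t[1]]]) else NULL)
}

round_half_up <- function(x) floor(x + 0.5)

#' Split a dataset into a basic-heavy train set and an advanced-only test set
#'
#' Mirrors the evaluation design for the dance-genre task: the test set
#' contains only advanced (long, individualized) sequences, sampled per genre
#' at a fixed fraction, while all basic sequences and the remaining advanced
#' sequences form the training set. The default fraction 0.52 reproduces a
#' 103/96 advanced split on a collection with about 199 advanced sequences.
#'
#' @param data A [pose_dataset()] whose sequences carry genre and tier labels.
#' @param advanced_test_fraction Fraction of each genre's advanced sequences
#'   assigned to the test set (rounded half up).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with \code{train} and \code{test} datasets.
#' @export
split_advanced_test <- function(data, advanced_test_fraction = 0.52, seed = 1L) {
  stopifnot(inherits(data, "pose_dataset"))
  if (advanced_test_fraction <= 0 || advanced_test_fraction >= 1) {
    stop("config error: advanced_test_fraction must be in (0, 1)", call. = FALSE)
  }
  tiers <- vapply(data$sequences, function(s) s$tier %||% NA_character_, "")
  genres <- vapply(data$sequences, function(s) s$genre %||% NA_character_, "")
  adv <- which(tiers == "advanced")
  if (length(adv) == 0) {
    stop("split error: dataset has no advanced sequences", call. = FALSE)
  }
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (g in unique(genres[adv])) {
      pool <- adv[genres[adv] == g]
      k <- round_half_up(advanced_test_fraction * length(pool))
      k <- min(k, length(pool))
      # index into pool explicitly: sample(x, k) on a length-1 pool would
      # sample from 1:x instead
      if (k > 0) {
        test_idx <- c(test_idx, sort(pool[sample.int(length(pool), k)]))
      }
    }
  })
  train_idx <- setdiff(seq_along(data$sequences), test_idx)
  list(train = pose_dataset(data$sequences[train_idx], data$genre_vocabulary),
       test = pose_dataset(data$sequences[sort(test_idx)], data$genre_vocabulary))
}

# CSV writer that preserves doubles bit-for-bit (17 significant digits).
write_full_precision_csv <- function(tab, path) {
  out <- tab
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' One row per sequence: \code{sequence_id}, \code{genre}, \code{tier}, then
#' the feature columns in registry order, at full double precision.
#'
#' @param matrix A feature matrix from [extract_feature_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(is.data.frame(matrix), nrow(matrix) >= 1)
  write_full_precision_csv(matrix, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param registry Registry to re-attach; defaults to a registry inferred
#'   from the columns present.
#' @return A feature matrix data frame.
#' @export
read_feature_table <- function(path, registry = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(registry)) {
    registry <- feature_registry(augmented = "autocorr_peak_rate_x" %in% names(tab))
  }
  missing_cols <- setdiff(registry$specs$name, names(tab))
  if (length(missing_cols)) {
    stop("schema error: feature columns missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  attr(tab, "registry") <- registry
  class(tab) <- c("feature_matrix", class(tab))
  tab
}
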