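# Shared fixtures: small poses and synthetic feature tables built in code.

no_smooth <- smoothing_config(enabled = FALSE)

# A pose where every joint follows the base template plus a per-joint offset
# trajectory. `offsets` is a function(joint_index, t) -> n x 3 matrix, or
# NULL for a static pose.
make_pose <- function(n = 240, fps = 60, offsets = NULL, base = default_base_pose(),
                      genre = NULL, tier = NULL, id = "fixture") {
  t <- (seq_len(n) - 1) / fps
  J <- nrow(base)
  pos <- array(0, c(n, J, 3))
  for (j in seq_len(J)) {
    off <- if (is.null(offsets)) matrix(0, n, 3) else offsets(j, t)
    pos[, j, ] <- matrix(base[j, ], n, 3, byrow = TRUE) + off
  }
  pose_sequence(pos, fps = fps, sequence_id = id, genre = genre, tier = tier)
}

# Whole-body rigid offset trajectory shared by all joints.
whole_body <- function(traj_fun) {
  function(j, t) traj_fun(t)
}

# Offset only the named joints (indices into the COCO-17 layout).
only_joints <- function(idx, traj_fun) {
  function(j, t) {
    if (j %in% idx) traj_fun(t) else matrix(0, length(t), 3)
  }
}

coco <- coco17_layout()

# Minimal labelled 4-frame pose used by split tests (content irrelevant).
stub_pose <- function(id, genre, tier) {
  make_pose(n = 4, genre = genre, tier = tier, id = id)
}

# Synthetic feature matrix: Gaussian class clusters in registry feature
# space, bypassing motion generation (fast path for classifier tests).
make_feature_df <- function(centers, n_per_class, sd = 0.5, seed = 1,
                            registry = feature_registry(), tier = "basic") {
  p <- nrow(registry$specs)
  stopifnot(ncol(centers) == p)
  classes <- rownames(centers)
  withr::with_seed(seed, {
    rows <- lapply(classes, function(cl) {
      X <- matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p,
                  byrow = TRUE) +
        matrix(centers[cl, ], n_per_class, p, byrow = TRUE)
      colnames(X) <- registry$specs$name
      cbind(data.frame(sequence_id = paste0(cl, "_", seq_len(n_per_class)),
                       genre = cl, tier = tier, stringsAsFactors = FALSE),
            as.data.frame(X))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "registry") <- registry
  class(out) <- c("feature_matrix", class(out))
  out
}

# Random class centers separated well beyond the within-class sd.
make_separated_centers <- function(n_classes, registry = feature_registry(),
                                   spacing = 6, seed = 42) {
  p <- nrow(registry$specs)
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(n_classes * p) * spacing, n_classes, p)
  })
  rownames(centers) <- paste0("genre", seq_len(n_classes))
  centers
}
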