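#' Per-genre mean feature table
#'
#' @param fm A labelled feature matrix.
#' @return Numeric \code{genres x features} matrix of per-genre means.
#' @export
genre_mean_table <- function(fm) {
  registry <- attr(fm, "registry")
  X <- feature_block(fm, registry)
  g <- labels_of(fm)
  out <- do.call(rbind, lapply(sort(unique(g)), function(cl) {
    colMeans(X[g == cl, , drop = FALSE])
  }))
  rownames(out) <- sort(unique(g))
  out
}

#' Similarity embedding of genres by truncated SVD (LSA)
#'
#' Embeds the genres into a low-dimensional similarity space, in the manner
#' of latent semantic analysis: the \code{genre x feature} matrix of
#' per-genre mean features is column-standardized (z-scored; zero-variance
#' columns are set to zero) and decomposed by SVD, keeping the top
#' \code{k} components. Genre coordinates are the left singular vectors
#' scaled by the singular values, so inter-genre distances reflect the
#' best rank-\code{k} approximation of the standardized table.
#'
#' @param genre_table \code{genre x feature} numeric matrix, e.g. from
#'   [genre_mean_table()].
#' @param k Number of components (default 3).
#' @return Object of class \code{lsa_embedding}: \code{coordinates}
#'   (\code{genres x k}), \code{singular_values} (all, non-increasing),
#'   \code{loadings} (\code{features x k}, orthonormal), and the centering
#'   and scaling used.
#' @export
lsa_embed <- function(genre_table, k = 3L) {
  genre_table <- as.matrix(genre_table)
  if (k >= min(dim(genre_table))) {
    stop("rank error: k must be < min(genres, features)", call. = FALSE)
  }
  if (nrow(genre_table) < k + 1) {
    stop("rank error: need at least k + 1 genres", call. = FALSE)
  }
  mu <- colMeans(genre_table)
  sdev <- apply(genre_table, 2, stats::sd)
  zero_var <- sdev == 0 | !is.finite(sdev)
  sdev[zero_var] <- 1
  Z <- scale(genre_table, center = mu, scale = sdev)
  Z[, zero_var] <- 0
  s <- svd(Z)
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  rownames(coords) <- rownames(genre_table)
  colnames(coords) <- paste0("component_", seq_len(k))
  loadings <- s$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(genre_table)
  structure(list(coordinates = coords, singular_values = s$d,
                 loadings = loadings,
                 centering = mu, scaling = sdev, zero_variance = zero_var,
                 k = k),
            class = "lsa_embedding")
}

# --- feature importance -----------------------------------------------------

# Model output on a plain numeric matrix with feature names.
predict_proba_matrix <- function(model, X) {
  df <- as.data.frame(X)
  colnames(df) <- colnames(X)
  predict_proba(model, df)
}

shapley_exact <- function(model, x, background, classes) {
  m <- length(x)
  if (m > 12) stop("config error: exact Shapley limited to <= 12 features",
                   call. = FALSE)
  n_bg <- nrow(background)
  n_sub <- 2^m
  subset_bits <- matrix(FALSE, n_sub, m)
  for (j in seq_len(m)) {
    subset_bits[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  # v(S) for every subset: mean model output with features in S taken from
  # x and the rest from each background row
  big <- background[rep(seq_len(n_bg), times = n_sub), , drop = FALSE]
  for (j in seq_len(m)) {
    rows <- subset_bits[rep(seq_len(n_sub), each = n_bg), j]
    big[rows, j] <- x[j]
  }
  pr <- predict_proba_matrix(model, big)
  v <- rowsum(pr, group = rep(seq_len(n_sub), each = n_bg)) / n_bg
  sizes <- rowSums(subset_bits)
  phi <- array(0, c(m, length(classes)), dimnames = list(names(x), classes))
  for (j in seq_len(m)) {
    without <- which(!subset_bits[, j])
    with_j <- without + bitwShiftL(1L, j - 1L)
    s_sizes <- sizes[without]
    w <- factorial(s_sizes) * factorial(m - s_sizes - 1) / factorial(m)
    phi[j, ] <- colSums(w * (v[with_j, , drop = FALSE] -
                             v[without, , drop = FALSE]))
  }
  base <- v[1, ]  # empty subset: mean background prediction
  list(phi = phi, base = base)
}

shapley_sampling <- function(model, x, background, classes, n_perm) {
  m <- length(x)
  n_bg <- nrow(background)
  bg_pick <- sample.int(n_bg, n_perm, replace = TRUE)
  orders <- replicate(n_perm, sample.int(m), simplify = FALSE)
  # build all evaluation rows: per permutation, m + 1 states of the walk
  rows <- matrix(0, n_perm * (m + 1), m, dimnames = list(NULL, names(x)))
  for (p in seq_len(n_perm)) {
    z <- background[bg_pick[p], ]
    base_row <- (p - 1) * (m + 1)
    rows[base_row + 1, ] <- z
    for (step in seq_len(m)) {
      z[orders[[p]][step]] <- x[orders[[p]][step]]
      rows[base_row + 1 + step, ] <- z
    }
  }
  pr <- predict_proba_matrix(model, rows)
  phi <- array(0, c(m, length(classes)), dimnames = list(names(x), classes))
  base <- rep(0, length(classes))
  for (p in seq_len(n_perm)) {
    base_row <- (p - 1) * (m + 1)
    base <- base + pr[base_row + 1, ]
    diffs <- pr[base_row + 1 + seq_len(m), , drop = FALSE] -
      pr[base_row + seq_len(m), , drop = FALSE]
    phi[orders[[p]], ] <- phi[orders[[p]], ] + diffs
  }
  list(phi = phi / n_perm, base = base / n_perm)
}

#' Feature importance for a fitted classifier
#'
#' Two methods. \code{"shapley"} attributes each instance's predicted
#' class probabilities to the features game-theoretically, against a
#' background sample: absent features take background values, and a
#' feature's value is its average marginal contribution over feature
#' orderings (exact subset enumeration when the registry has at most 12
#' features and \code{exact = TRUE}, otherwise permutation sampling, which
#' preserves the local-accuracy property with respect to the sampled
#' backgrounds). \code{"permutation"} measures the mean increase in
#' multiclass log loss when one feature column is shuffled.
#'
#' @param model A fitted \code{ensemble_model} or \code{baseline_model}.
#' @param X Labelled feature matrix to explain.
#' @param method \code{"shapley"} or \code{"permutation"}.
#' @param background Background feature matrix for Shapley (defaults to
#'   \code{X}); at most \code{n_background} rows are used.
#' @param n_background Background sample size (default 100).
#' @param n_perm Permutations per instance for sampling Shapley.
#' @param n_instances Number of rows of \code{X} to explain (head; Shapley
#'   cost is linear in this).
#' @param n_repeats Shuffles per feature for the permutation method.
#' @param exact Use exact enumeration when feasible.
#' @param seed Integer seed.
#' @return Object of class \code{importance_report}: \code{global} (named,
#'   decreasing relevance), \code{per_class} (class -> named signed
#'   vector), \code{method}, and for Shapley the per-instance \code{phi}
#'   array and \code{base_values}.
#' @export
feature_importance <- function(model, X,
                               method = c("shapley", "permutation"),
                               background = NULL, n_background = 100L,
                               n_perm = 50L, n_instances = nrow(X),
                               n_repeats = 10L, exact = NULL, seed = 1L) {
  method <- match.arg(method)
  feat_names <- model$feature_names
  Xm <- as.matrix(X[, feat_names, drop = FALSE])
  classes <- model$class_labels

  if (method == "permutation") {
    y <- labels_of(X)
    base_pr <- predict_proba_matrix(model, Xm)
    base_loss <- multiclass_log_loss(y, base_pr)
    base_cl <- vapply(classes, function(cl) {
      rows <- y == cl
      if (any(rows)) multiclass_log_loss(y[rows], base_pr[rows, , drop = FALSE])
      else NA_real_
    }, numeric(1))
    global <- stats::setNames(numeric(length(feat_names)), feat_names)
    per_class <- lapply(classes, function(cl) {
      stats::setNames(numeric(length(feat_names)), feat_names)
    })
    names(per_class) <- classes
    withr::with_seed(seed, {
      for (j in seq_along(feat_names)) {
        incr <- numeric(n_repeats)
        incr_cl <- matrix(0, n_repeats, length(classes))
        for (r in seq_len(n_repeats)) {
          Xp <- Xm
          Xp[, j] <- sample(Xp[, j])
          pr <- predict_proba_matrix(model, Xp)
          incr[r] <- multiclass_log_loss(y, pr) - base_loss
          for (ci in seq_along(classes)) {
            rows <- y == classes[ci]
            if (any(rows)) {
              incr_cl[r, ci] <-
                multiclass_log_loss(y[rows], pr[rows, , drop = FALSE]) -
                base_cl[ci]
            }
          }
        }
        global[j] <- mean(incr)
        for (ci in seq_along(classes)) {
          per_class[[ci]][j] <- mean(incr_cl[, ci])
        }
      }
    })
    return(structure(list(global = sort(global, decreasing = TRUE),
                          per_class = per_class, method = "permutation"),
                     class = "importance_report"))
  }

  # Shapley
  bg <- as.matrix((background %||% X)[, feat_names, drop = FALSE])
  m <- length(feat_names)
  if (is.null(exact)) exact <- m <= 12
  n_instances <- min(n_instances, nrow(Xm))
  phi <- array(0, c(n_instances, m, length(classes)),
               dimnames = list(NULL, feat_names, classes))
  base_values <- matrix(0, n_instances, length(classes),
                        dimnames = list(NULL, classes))
  withr::with_seed(seed, {
    if (nrow(bg) > n_background) {
      bg <- bg[sample.int(nrow(bg), n_background), , drop = FALSE]
    }
    for (i in seq_len(n_instances)) {
      res <- if (exact && m <= 12) {
        shapley_exact(model, Xm[i, ], bg, classes)
      } else {
        shapley_sampling(model, Xm[i, ], bg, classes, n_perm)
      }
      phi[i, , ] <- res$phi
      base_values[i, ] <- res$base
    }
  })
  global <- apply(abs(phi), 2, mean)
  per_class <- lapply(seq_along(classes), function(ci) {
    stats::setNames(colMeans(phi[, , ci, drop = FALSE][, , 1, drop = TRUE],
                             na.rm = TRUE), feat_names)
  })
  names(per_class) <- classes
  structure(list(global = sort(global, decreasing = TRUE),
                 per_class = per_class, method = "shapley",
                 phi = phi, base_values = base_values,
                 explained = Xm[seq_len(n_instances), , drop = FALSE]),
            class = "importance_report")
}

#' Per-genre feature fingerprint
#'
#' A genre's fingerprint is its per-feature mean vector together with the
#' Pearson correlation matrix of the features over the genre's sequences.
#' Zero-variance features are flagged and their correlation entries marked
#' undefined (NA) rather than silently zeroed; with fewer than 3 sequences
#' the whole correlation matrix is undefined.
#'
#' @param fm A labelled feature matrix.
#' @param genre Genre name.
#' @return Object of class \code{genre_fingerprint}: \code{genre},
#'   \code{mean_vector}, \code{correlation}, \code{undefined} (logical
#'   per-feature flag), \code{n}.
#' @export
genre_fingerprint <- function(fm, genre) {
  registry <- attr(fm, "registry")
  g <- labels_of(fm)
  if (!genre %in% g) stop("label error: unknown genre: ", genre, call. = FALSE)
  X <- feature_block(fm, registry)[g == genre, , drop = FALSE]
  mean_vector <- colMeans(X)
  m <- ncol(X)
  undefined <- apply(X, 2, function(col) pop_sd(col) == 0)
  if (nrow(X) < 3) {
    correlation <- matrix(NA_real_, m, m,
                          dimnames = list(colnames(X), colnames(X)))
    undefined[] <- TRUE
  } else {
    correlation <- suppressWarnings(stats::cor(X))
    correlation[undefined, ] <- NA_real_
    correlation[, undefined] <- NA_real_
    diag(correlation)[!undefined] <- 1
  }
  structure(list(genre = genre, mean_vector = mean_vector,
                 correlation = correlation, undefined = undefined,
                 n = nrow(X)),
            class = "genre_fingerprint")
}

#' Compare two confusion-matrix reports
#'
#' Used to set a classifier's error structure against another evaluator of
#' the same genres (for instance a panel of human observers): per-class
#' accuracies (recall), their Spearman rank correlation, and the classes
#' ranked by disagreement.
#'
#' @param a,b [classification_report()] objects over the same class
#'   vocabulary.
#' @param tol Absolute per-class accuracy difference below which the two
#'   reports are considered to agree on a class.
#' @return List with \code{per_class_accuracy} (two-column matrix),
#'   \code{rank_correlation}, and \code{disagreements} (data frame sorted
#'   by decreasing |difference|, classes differing by more than \code{tol}).
#' @export
compare_confusions <- function(a, b, tol = 1e-12) {
  ca <- a$per_class$class
  cb <- b$per_class$class
  if (!identical(sort(ca), sort(cb))) {
    stop("schema error: class vocabularies differ", call. = FALSE)
  }
  acc_a <- stats::setNames(a$per_class$recall, ca)
  acc_b <- stats::setNames(b$per_class$recall, cb)[ca]
  rho <- suppressWarnings(stats::cor(acc_a, acc_b, method = "spearman"))
  diff <- acc_a - acc_b
  ord <- order(-abs(diff))
  disagreements <- data.frame(class = ca[ord], accuracy_a = acc_a[ord],
                              accuracy_b = acc_b[ord],
                              difference = diff[ord],
                              row.names = NULL, stringsAsFactors = FALSE)
  disagreements <- disagreements[abs(disagreements$difference) > tol, ]
  list(per_class_accuracy = cbind(a = acc_a, b = acc_b),
       rank_correlation = rho,
       disagreements = disagreements)
}
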