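#' Multiclass log loss
#'
#' The training objective of the genre-classification pipeline:
#' \deqn{f = -\frac{1}{M}\sum_{m=1}^{M}\sum_{k=1}^{K} y_{mk} \log p_{mk}}
#' where \eqn{y_{mk}} is the one-hot indicator of instance \eqn{m}'s true
#' class and \eqn{p_{mk}} the predicted probability. Probabilities are
#' clipped to \eqn{[\epsilon, 1-\epsilon]}, \eqn{\epsilon = 10^{-15}}.
#'
#' @param true_labels Character/factor vector of true classes.
#' @param predicted_probabilities Numeric \code{[instances x K]} matrix with
#'   class names as column names; rows must sum to 1 (within 1e-6).
#' @return Scalar log loss (nats).
#' @export
multiclass_log_loss <- function(true_labels, predicted_probabilities) {
  p <- as.matrix(predicted_probabilities)
  if (length(true_labels) != nrow(p)) {
    stop("shape error: labels and probability rows differ", call. = FALSE)
  }
  if (is.null(colnames(p))) {
    stop("shape error: probability matrix needs class column names",
         call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("shape error: probability rows must sum to 1", call. = FALSE)
  }
  idx <- match(as.character(true_labels), colnames(p))
  if (anyNA(idx)) stop("label error: label outside class vocabulary",
                       call. = FALSE)
  eps <- 1e-15
  p_true <- pmin(pmax(p[cbind(seq_len(nrow(p)), idx)], eps), 1 - eps)
  -mean(log(p_true))
}

# --- feature standardization (location/scale fitted on training data) ------

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mean = mu, sd = sdev)
}

apply_standardizer <- function(std, X) {
  scale(X, center = std$mean, scale = std$sd)[, , drop = FALSE]
}

# Softmax over rows of a decision-value matrix.
row_softmax <- function(d) {
  d <- d - apply(d, 1, max)
  e <- exp(d)
  e / rowSums(e)
}

labels_of <- function(fm) {
  g <- fm$genre
  if (anyNA(g)) stop("label error: unlabelled rows in feature matrix",
                     call. = FALSE)
  g
}

# --- linear baselines -------------------------------------------------------

#' Train a linear baseline classifier
#'
#' Two deliberately simple benchmarks for the genre task. The ridge
#' classifier solves a one-hot least-squares problem with an L2 penalty
#' (\eqn{W = (X^T X + \lambda I)^{-1} X^T Y}, targets \eqn{\pm 1}) and
#' predicts the argmax decision value. The perceptron is a one-vs-rest
#' averaged perceptron trained by cyclic online updates with per-epoch
#' shuffling. Both standardize features using training statistics only;
#' probabilities are softmax over decision values.
#'
#' @param train A feature matrix (see [extract_feature_matrix()]) with
#'   genre labels.
#' @param kind \code{"ridge"} or \code{"perceptron"}.
#' @param seed Integer seed (perceptron shuffling).
#' @param lambda Ridge penalty.
#' @param epochs Perceptron training epochs.
#' @param features Optional subset of feature names to train on.
#' @return Object of class \code{baseline_model}.
#' @export
train_baseline <- function(train, kind = c("ridge", "perceptron"), seed = 1L,
                           lambda = 1.0, epochs = 50L, features = NULL) {
  kind <- match.arg(kind)
  registry <- attr(train, "registry")
  feat_names <- features %||% registry$specs$name
  X <- as.matrix(train[, feat_names, drop = FALSE])
  y <- labels_of(train)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("degenerate-data error: single class",
                                call. = FALSE)
  std <- fit_standardizer(X)
  Xs <- cbind(1, apply_standardizer(std, X))
  K <- length(classes)
  Y <- matrix(-1, nrow(Xs), K, dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1

  if (kind == "ridge") {
    pen <- diag(ncol(Xs)) * lambda
    pen[1, 1] <- 0  # intercept unpenalized
    W <- solve(crossprod(Xs) + pen, crossprod(Xs, Y))
  } else {
    W <- matrix(0, ncol(Xs), K, dimnames = list(NULL, classes))
    Wsum <- W
    n_upd <- 0L
    withr::with_seed(seed, {
      for (e in seq_len(epochs)) {
        for (i in sample.int(nrow(Xs))) {
          d <- drop(Xs[i, ] %*% W)
          pred <- which.max(d)
          truth <- match(y[i], classes)
          if (pred != truth) {
            W[, truth] <- W[, truth] + Xs[i, ]
            W[, pred] <- W[, pred] - Xs[i, ]
          }
          Wsum <- Wsum + W
          n_upd <- n_upd + 1L
        }
      }
    })
    W <- Wsum / n_upd
  }
  structure(list(kind = kind, weights = W, standardization = std,
                 class_labels = classes, feature_names = feat_names),
            class = "baseline_model")
}

#' @export
predict_proba.baseline_model <- function(model, newdata, ...) {
  X <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  Xs <- cbind(1, apply_standardizer(model$standardization, X))
  p <- row_softmax(Xs %*% model$weights)
  colnames(p) <- model$class_labels
  p
}

#' Class-probability predictions
#'
#' @param model A fitted model (baseline or ensemble).
#' @param newdata Feature matrix to predict.
#' @param ... Unused.
#' @return Numeric \code{[rows x K]} matrix; rows sum to 1.
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

# Argmax labels; ties broken toward the lowest class index.
proba_to_labels <- function(p) {
  colnames(p)[max.col(p, ties.method = "first")]
}

# --- the model zoo ----------------------------------------------------------

zoo_families <- function() {
  c("glmnet", "ranger", "xgboost", "svm", "multinom", "knn")
}

sample_candidate <- function(family, p_features) {
  params <- switch(
    family,
    glmnet = list(alpha = sample(c(0, 0.25, 0.5, 0.75, 1), 1),
                  lambda = 10^stats::runif(1, -4, -0.5)),
    ranger = list(num.trees = sample(150:400, 1),
                  mtry = sample.int(min(8L, p_features), 1),
                  min.node.size = sample.int(10L, 1)),
    xgboost = list(nrounds = sample(50:250, 1),
                   eta = 10^stats::runif(1, -1.5, -0.3),
                   max_depth = sample(2:8, 1),
                   subsample = stats::runif(1, 0.6, 1)),
    svm = list(cost = 10^stats::runif(1, -1, 2),
               gamma = 10^stats::runif(1, -3, 0)),
    multinom = list(decay = 10^stats::runif(1, -4, 0)),
    knn = list(k = sample(c(1L, 3L, 5L, 7L, 9L, 11L), 1))
  )
  list(family = family, params = params)
}

fit_zoo_member <- function(candidate, X, y, classes, seed) {
  K <- length(classes)
  yf <- factor(y, levels = classes)
  fit <- withr::with_seed(seed, suppressWarnings(switch(
    candidate$family,
    glmnet = glmnet::glmnet(X, yf, family = "multinomial",
                            alpha = candidate$params$alpha,
                            lambda = candidate$params$lambda),
    ranger = ranger::ranger(x = X, y = yf, probability = TRUE,
                            num.trees = candidate$params$num.trees,
                            mtry = min(candidate$params$mtry, ncol(X)),
                            min.node.size = candidate$params$min.node.size,
                            seed = seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = K,
                    eta = candidate$params$eta,
                    max_depth = candidate$params$max_depth,
                    subsample = candidate$params$subsample,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(yf) - 1L),
      nrounds = candidate$params$nrounds, verbose = 0),
    svm = e1071::svm(X, yf, probability = TRUE, kernel = "radial",
                     cost = candidate$params$cost,
                     gamma = candidate$params$gamma),
    multinom = {
      df <- data.frame(.y = yf, X)
      nnet::multinom(.y ~ ., data = df, decay = candidate$params$decay,
                     trace = FALSE, maxit = 300, MaxNWts = 5000)
    },
    knn = list(X = X, y = yf, k = candidate$params$k)
  )))
  structure(list(family = candidate$family, params = candidate$params,
                 fit = fit, classes = classes, seed = seed),
            class = "zoo_member")
}

predict_zoo_member <- function(member, X) {
  classes <- member$classes
  K <- length(classes)
  p <- switch(
    member$family,
    glmnet = {
      pr <- stats::predict(member$fit, X, type = "response")
      m <- pr[, , 1]
      m[, classes, drop = FALSE]
    },
    ranger = {
      pr <- stats::predict(member$fit, data = X, num.threads = 1)$predictions
      pr[, classes, drop = FALSE]
    },
    xgboost = {
      pr <- stats::predict(member$fit, xgboost::xgb.DMatrix(X))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = K, byrow = TRUE)
      colnames(pr) <- classes
      pr
    },
    svm = {
      pr <- attr(stats::predict(member$fit, X, probability = TRUE),
                 "probabilities")
      pr[, classes, drop = FALSE]
    },
    multinom = {
      pr <- stats::predict(member$fit, newdata = data.frame(X),
                           type = "probs")
      if (is.null(dim(pr))) {
        # K = 2 gives P(second level); a single row gives a length-K vector
        pr <- if (K == 2) cbind(1 - pr, pr) else matrix(pr, nrow = 1)
      }
      colnames(pr) <- classes
      pr
    },
    knn = {
      tr <- member$fit
      d2 <- outer(rowSums(X^2), rowSums(tr$X^2), "+") - 2 * X %*% t(tr$X)
      out <- matrix(0, nrow(X), K, dimnames = list(NULL, classes))
      for (i in seq_len(nrow(X))) {
        nb <- order(d2[i, ])[seq_len(min(tr$k, ncol(d2)))]
        counts <- table(factor(tr$y[nb], levels = classes))
        out[i, ] <- (counts + 0.5) / (sum(counts) + 0.5 * K)
      }
      out
    }
  )
  p <- pmax(p, 1e-12)
  p / rowSums(p)
}

#' Training configuration for the budgeted model search
#'
#' The search draws \code{search_budget} random configurations from a model
#' zoo (regularized multinomial/elastic-net, random forest, gradient
#' boosting, RBF-kernel SVM, multinomial logistic, nearest neighbours),
#' scores each by multiclass log loss on an inner validation split, and
#' builds a weighted prediction ensemble by greedy forward selection with
#' replacement.
#'
#' @param search_budget Number of candidate configurations to evaluate.
#' @param ensemble_size Maximum number of greedy selection rounds
#'   (\eqn{M}, default 20); the ensemble holds at most this many members.
#' @param inner_validation Fraction of training rows held out for scoring.
#' @param seed Integer seed governing sampling, fitting and splitting.
#' @param families Zoo families to draw from.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(search_budget = 40L, ensemble_size = 20L,
                         inner_validation = 0.25, seed = 1L,
                         families = zoo_families()) {
  if (search_budget < 1) stop("config error: budget must be >= 1",
                              call. = FALSE)
  if (ensemble_size < 1) stop("config error: ensemble_size must be >= 1",
                              call. = FALSE)
  if (search_budget < ensemble_size) {
    # fewer distinct candidates than rounds is fine (selection has
    # replacement) but a budget below 1 round is not
    search_budget <- max(search_budget, 1L)
  }
  if (inner_validation <= 0 || inner_validation >= 1) {
    stop("config error: inner_validation must be in (0, 1)", call. = FALSE)
  }
  families <- match.arg(families, zoo_families(), several.ok = TRUE)
  structure(list(objective = "multiclass_log_loss",
                 search_budget = as.integer(search_budget),
                 ensemble_size = as.integer(ensemble_size),
                 inner_validation = inner_validation,
                 seed = as.integer(seed), families = families),
            class = "train_config")
}

# Stratified inner split: indices of validation rows.
stratified_holdout <- function(y, fraction, seed) {
  idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      pool <- which(y == cl)
      k <- max(1L, round_half_up(fraction * length(pool)))
      k <- min(k, length(pool) - 1L)  # keep at least one row in train
      if (k > 0) idx <- c(idx, sample(pool, k))
    }
  })
  sort(idx)
}

#' Fit the weighted genre-classification ensemble
#'
#' Budgeted random search over the model zoo followed by greedy weighted
#' ensembling under multiclass log loss. Candidates are fitted on an inner
#' training split and scored on the inner validation split; greedy forward
#' selection (with replacement, initialized at the best single member)
#' picks up to \code{ensemble_size} members, and the selection-count
#' weights are kept for the prefix with the lowest validation loss, so the
#' ensemble never scores worse than its best member on inner validation.
#' Selected members are then refitted on the full training set.
#'
#' @param train A labelled feature matrix.
#' @param config A [train_config()].
#' @return Object of class \code{ensemble_model} with members, weights
#'   (nonnegative, summing to 1), class labels, standardization, and the
#'   inner-validation log losses of candidates and ensemble.
#' @export
automl_fit <- function(train, config = train_config()) {
  registry <- attr(train, "registry")
  feat_names <- registry$specs$name
  X <- as.matrix(train[, feat_names, drop = FALSE])
  y <- labels_of(train)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("degenerate-data error: single class",
                                call. = FALSE)
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)

  val_idx <- stratified_holdout(y, config$inner_validation, config$seed)
  tr_idx <- setdiff(seq_along(y), val_idx)

  candidates <- withr::with_seed(config$seed, {
    fams <- sample(config$families, config$search_budget, replace = TRUE)
    lapply(fams, sample_candidate, p_features = ncol(Xs))
  })
  member_seeds <- config$seed + seq_len(config$search_budget)

  fits <- vector("list", config$search_budget)
  val_probs <- vector("list", config$search_budget)
  val_loss <- rep(NA_real_, config$search_budget)
  for (i in seq_len(config$search_budget)) {
    fit <- try(fit_zoo_member(candidates[[i]], Xs[tr_idx, , drop = FALSE],
                              y[tr_idx], classes, member_seeds[i]),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    pr <- try(predict_zoo_member(fit, Xs[val_idx, , drop = FALSE]),
              silent = TRUE)
    if (inherits(pr, "try-error") || !all(is.finite(pr))) next
    fits[[i]] <- fit
    val_probs[[i]] <- pr
    val_loss[i] <- multiclass_log_loss(y[val_idx], pr)
  }
  ok <- which(!is.na(val_loss))
  if (length(ok) == 0) stop("stage failure: no candidate model could be fitted",
                            call. = FALSE)

  # greedy forward selection with replacement
  sel <- integer(0)
  prefix_loss <- numeric(0)
  run_sum <- matrix(0, length(val_idx), length(classes),
                    dimnames = list(NULL, classes))
  for (round in seq_len(config$ensemble_size)) {
    losses <- vapply(ok, function(i) {
      multiclass_log_loss(y[val_idx],
                          (run_sum + val_probs[[i]]) / (length(sel) + 1))
    }, numeric(1))
    pick <- ok[which.min(losses)]
    sel <- c(sel, pick)
    run_sum <- run_sum + val_probs[[pick]]
    prefix_loss <- c(prefix_loss, min(losses))
  }
  best_prefix <- which.min(prefix_loss)
  sel <- sel[seq_len(best_prefix)]
  counts <- table(sel)
  member_idx <- as.integer(names(counts))
  weights <- as.numeric(counts) / length(sel)

  # refit selected members on the full training set
  members <- lapply(member_idx, function(i) {
    fit_zoo_member(candidates[[i]], Xs, y, classes, member_seeds[i])
  })

  structure(
    list(members = members, weights = weights, class_labels = classes,
         standardization = std, feature_names = feat_names,
         config = config,
         inner_val = list(candidate_loss = val_loss,
                          selected = member_idx,
                          ensemble_loss = prefix_loss[best_prefix],
                          best_member_loss = min(val_loss, na.rm = TRUE))),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d members (weights sum %.6f), %d classes\n",
              length(x$members), sum(x$weights), length(x$class_labels)))
  fam <- vapply(x$members, `[[`, "", "family")
  for (i in order(-x$weights)) {
    cat(sprintf("  w=%.3f %s\n", x$weights[i], fam[i]))
  }
  cat(sprintf("  inner-val log loss: ensemble %.4f, best member %.4f\n",
              x$inner_val$ensemble_loss, x$inner_val$best_member_loss))
  invisible(x)
}

#' @export
predict_proba.ensemble_model <- function(model, newdata, ...) {
  X <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  Xs <- apply_standardizer(model$standardization, X)
  out <- matrix(0, nrow(Xs), length(model$class_labels),
                dimnames = list(NULL, model$class_labels))
  for (i in seq_along(model$members)) {
    out <- out + model$weights[i] * predict_zoo_member(model$members[[i]], Xs)
  }
  out / rowSums(out)
}

#' Predict genre labels
#'
#' @param object A fitted \code{ensemble_model} or \code{baseline_model}.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted genres (argmax probability, ties
#'   broken toward the lowest class index).
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  proba_to_labels(predict_proba(object, newdata))
}

#' @rdname predict.ensemble_model
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  proba_to_labels(predict_proba(object, newdata))
}

#' Build a classification report from a confusion matrix
#'
#' @param confusion \code{K x K} count matrix, rows = true class, columns =
#'   predicted class, with matching dimnames.
#' @return Object of class \code{classification_report}: accuracy,
#'   per-class precision/recall/F1/support, macro and weighted averages,
#'   and the confusion matrix itself.
#' @export
classification_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  classes <- rownames(confusion)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL, stringsAsFactors = FALSE)
  w <- support / sum(support)
  structure(
    list(accuracy = sum(tp) / sum(confusion),
         per_class = per_class,
         macro_avg = c(precision = mean(precision), recall = mean(recall),
                       f1 = mean(f1)),
         weighted_avg = c(precision = sum(w * precision),
                          recall = sum(w * recall), f1 = sum(w * f1)),
         confusion = confusion),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: accuracy %.3f (n = %d)\n",
              x$accuracy, sum(x$confusion)))
  print(cbind(round(x$per_class[, c("precision", "recall", "f1")], 3),
              support = x$per_class$support),
        row.names = x$per_class$class)
  invisible(x)
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model Fitted \code{ensemble_model} or \code{baseline_model}.
#' @param test Labelled feature matrix.
#' @return A [classification_report()].
#' @export
evaluate_model <- function(model, test) {
  truth <- labels_of(test)
  pred <- proba_to_labels(predict_proba(model, test))
  classes <- model$class_labels
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  classification_report(unclass(as.matrix(confusion)))
}
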