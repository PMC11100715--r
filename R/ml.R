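#' Build a training set from a knockout screen
#'
#' One row per knockout simulation: the features are the post-knockout
#' steady-state node values (fixed column order = the model's node order) and
#' the label is the cell state the simulation was assigned to.
#'
#' @param screen A `ko_screen`.
#' @param include_baselines Also include the baseline (non-knockout) steady
#'   states labeled with their own state (off by default).
#' @return A `training_set`: list with binary matrix `X` and factor `y`.
#' @export
build_training_set <- function(screen, include_baselines = FALSE) {
  stopifnot(inherits(screen, "ko_screen"), nrow(screen$table) > 0)
  X <- screen$steady
  y <- screen$table$assigned
  if (include_baselines) {
    X <- rbind(X, screen$references)
    y <- c(y, rownames(screen$references))
  }
  if (length(unique(y)) < 2) {
    stop_ctx("single-class screen rejected for training")
  }
  structure(list(X = X, y = factor(y, levels = screen$states)),
            class = "training_set")
}

#' Classifier specification with fixed default hyperparameters
#'
#' Defaults per kind: multinomial elastic net with mixing parameter
#' alpha = 0.14 (penalty strength by 10-fold cross-validation); KNN with 13
#' neighbors on 80 recursively selected features; random forest with 1000
#' trees and 35 features per split; boosted trees with 100 trees, learning
#' rate 0.1, depth 1 and subsample 0.1.
#'
#' @param kind One of `"multinomial_elasticnet"`, `"knn"`, `"random_forest"`,
#'   `"boosted_trees"`.
#' @param seed Integer seed.
#' @param ... Hyperparameter overrides (see defaults in the returned spec).
#' @return A `model_spec`.
#' @export
model_spec <- function(kind = c("boosted_trees", "multinomial_elasticnet",
                                "knn", "random_forest"),
                       seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    multinomial_elasticnet = list(alpha = 0.14, nfolds = 10),
    knn = list(neighbors = 13, n_features = 80, feature_selection = TRUE),
    random_forest = list(ntree = 1000, mtry = 35, boruta = FALSE),
    boosted_trees = list(nrounds = 100, eta = 0.1, max_depth = 1,
                         subsample = 0.1, boruta = FALSE))
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop_ctx("unknown hyperparameter(s): %s",
                            paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(kind = kind, hyperparameters = defaults, seed = seed),
            class = "model_spec")
}

# bit-flip augmentation of a binary training matrix
augment_bitflip <- function(X, y, rate, copies, seed) {
  local_seed(seed, {
    Xa <- X; ya <- y
    for (i in seq_len(copies)) {
      F <- matrix(stats::runif(length(X)) < rate, nrow(X), ncol(X))
      Xa <- rbind(Xa, abs(X - F))
      ya <- c(ya, y)
    }
    list(X = Xa, y = factor(ya, levels = levels(y)))
  })
}

#' Train a cell-state classifier on simulation data
#'
#' @param ts A `training_set` (from [build_training_set()]) or a list with
#'   binary matrix `X` and factor/character `y`.
#' @param spec A `model_spec`.
#' @param augment_rate,augment_copies Optional bit-flip augmentation of the
#'   training rows (rate per bit, number of augmented copies); off when
#'   `augment_copies = 0` (the default).
#' @return A `state_classifier` holding the fitted model, feature order and
#'   class levels.
#' @export
train_classifier <- function(ts, spec = model_spec(), augment_rate = 0.05,
                             augment_copies = 0) {
  X <- as.matrix(ts$X)
  y <- if (is.factor(ts$y)) droplevels(ts$y) else factor(ts$y)
  stopifnot(nrow(X) == length(y), nlevels(y) >= 2)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (augment_copies > 0) {
    aug <- augment_bitflip(X, y, augment_rate, augment_copies, spec$seed)
    X <- aug$X; y <- aug$y
  }
  hp <- spec$hyperparameters
  features <- colnames(X)
  selected <- features
  fit <- local_seed(spec$seed, switch(spec$kind,
    multinomial_elasticnet = {
      nfolds <- min(hp$nfolds, max(3, min(table(y))))
      foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
      glmnet::cv.glmnet(X, y, family = "multinomial", alpha = hp$alpha,
                        foldid = foldid)
    },
    knn = {
      if (isTRUE(hp$feature_selection) && ncol(X) > hp$n_features) {
        selected <- rfe_select(X, y, hp$n_features)
      }
      list(X = X[, selected, drop = FALSE], y = y,
           k = min(hp$neighbors, nrow(X) - 1))
    },
    random_forest = {
      if (isTRUE(hp$boruta)) selected <- boruta_select(X, y, seed = spec$seed)
      randomForest::randomForest(
        x = X[, selected, drop = FALSE], y = y, ntree = hp$ntree,
        mtry = min(hp$mtry, length(selected)))
    },
    boosted_trees = {
      if (isTRUE(hp$boruta)) selected <- boruta_select(X, y, seed = spec$seed)
      d <- xgboost::xgb.DMatrix(X[, selected, drop = FALSE],
                                label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = nlevels(y),
                      eta = hp$eta, max_depth = hp$max_depth,
                      subsample = hp$subsample, nthread = 1),
        data = d, nrounds = hp$nrounds, verbose = 0)
    }))
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 features = features, selected = selected,
                 classes = levels(y)),
            class = "state_classifier")
}

# backward elimination ranked by pooled standardized class-mean separation
rfe_select <- function(X, y, n_features) {
  keep <- colnames(X)
  while (length(keep) > n_features) {
    score <- vapply(keep, function(f) {
      m <- tapply(X[, f], y, mean)
      s <- stats::sd(X[, f])
      if (is.na(s) || s == 0) return(0)
      sum(abs(outer(m, m, "-"))) / (2 * s)
    }, numeric(1))
    keep <- keep[-which.min(score)]
  }
  keep
}

#' Boruta-style all-relevant feature selection
#'
#' Shadow-feature scheme: each iteration appends a column-shuffled copy of
#' every feature, fits a random forest, and counts a "hit" for features whose
#' importance exceeds the best shadow importance; features with hits
#' significantly above (below) chance by a binomial test are confirmed
#' (rejected). Runs at most `max_runs` iterations.
#'
#' @param X Feature matrix, `y` labels, `max_runs` iteration cap,
#'   `alpha` binomial test level, `seed` RNG seed.
#' @param y,max_runs,alpha,seed See above.
#' @return Character vector of confirmed (plus still-tentative) features.
#' @export
boruta_select <- function(X, y, max_runs = 100, alpha = 0.05, seed = 1) {
  local_seed(seed, {
    features <- colnames(X)
    hits <- stats::setNames(integer(length(features)), features)
    status <- stats::setNames(rep("tentative", length(features)), features)
    for (run in seq_len(max_runs)) {
      open <- names(status)[status == "tentative"]
      if (length(open) == 0) break
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- paste0("shadow_", features)
      rf <- randomForest::randomForest(x = cbind(X, shadow), y = y,
                                       ntree = 100, importance = TRUE)
      imp <- randomForest::importance(rf, type = 2)[, 1]
      thr <- max(imp[paste0("shadow_", features)])
      hits <- hits + as.integer(imp[features] > thr)
      for (f in open) {
        p_hi <- stats::pbinom(hits[[f]] - 1, run, 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[[f]], run, 0.5)
        if (p_hi < alpha) status[f] <- "confirmed"
        else if (p_lo < alpha) status[f] <- "rejected"
      }
    }
    out <- names(status)[status != "rejected"]
    if (length(out) == 0) features else out
  })
}

#' Predict cell states for booleanized activity profiles
#'
#' @param object A `state_classifier`.
#' @param profiles Binary matrix (rows = samples) or a single named vector;
#'   columns are matched to the training feature order, missing features are
#'   imputed as 0 with a warning.
#' @param ... Unused.
#' @return data.frame: `sample`, `state` (argmax class) and one `score_*`
#'   column per class.
#' @export
predict_state <- function(object, profiles, ...) {
  stopifnot(inherits(object, "state_classifier"))
  if (is.null(dim(profiles))) profiles <- t(as.matrix(profiles))
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0 || ncol(profiles) == 0) {
    stop_ctx("empty profile rejected")
  }
  if (is.null(colnames(profiles))) {
    stopifnot(ncol(profiles) == length(object$features))
    colnames(profiles) <- object$features
  }
  missing <- setdiff(object$features, colnames(profiles))
  if (length(missing)) {
    warn_ctx("missing feature(s) imputed as 0: %s",
             paste(missing, collapse = ", "))
    pad <- matrix(0, nrow(profiles), length(missing),
                  dimnames = list(NULL, missing))
    profiles <- cbind(profiles, pad)
  }
  X <- profiles[, object$features, drop = FALSE]
  cls <- object$classes
  scores <- switch(object$kind,
    multinomial_elasticnet = {
      p <- drop(stats::predict(object$fit, newx = X, s = "lambda.min",
                               type = "response"))
      if (is.null(dim(p))) p <- t(as.matrix(p))
      p[, cls, drop = FALSE]
    },
    knn = knn_scores(object$fit, X),
    random_forest = {
      p <- stats::predict(object$fit,
                          X[, object$selected, drop = FALSE], type = "prob")
      p[, cls, drop = FALSE]
    },
    boosted_trees = {
      p <- stats::predict(object$fit,
                          xgboost::xgb.DMatrix(X[, object$selected, drop = FALSE]))
      colnames(p) <- cls
      p
    })
  state <- apply(scores, 1, function(s) cls[which.max(s)])
  out <- data.frame(sample = rownames(profiles) %||% seq_len(nrow(X)),
                    state = state, stringsAsFactors = FALSE, row.names = NULL)
  for (cl in cls) out[[paste0("score_", cl)]] <- scores[, cl]
  out
}

# k-nearest-neighbour class vote fractions (Euclidean distance, deterministic
# neighbour order; distance ties resolved by training-row order)
knn_scores <- function(fit, X) {
  tr <- fit$X[, , drop = FALSE]
  Xs <- X[, colnames(tr), drop = FALSE]
  cls <- levels(fit$y)
  d2 <- outer(rowSums(Xs^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(Xs)), rowSums(tr^2)) - 2 * Xs %*% t(tr)
  sc <- t(apply(d2, 1, function(d) {
    nb <- order(d)[seq_len(fit$k)]
    tab <- table(factor(fit$y[nb], levels = cls))
    as.numeric(tab) / fit$k
  }))
  colnames(sc) <- cls
  sc
}

#' One-vs-rest balanced accuracy of a class
#'
#' `(sensitivity + specificity) / 2` for the given class; invariant to how
#' the negative classes are labeled.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param class Class to score; if absent from `y_true` the quantity is
#'   undefined and `NA` is returned with a warning.
#' @return Balanced accuracy in `[0, 1]`, or flagged `NA`.
#' @export
balanced_accuracy <- function(y_true, y_pred, class) {
  stopifnot(length(y_true) == length(y_pred))
  if (!class %in% c(y_true, y_pred)) {
    stop_ctx("class '%s' absent from both y_true and y_pred", class)
  }
  pos <- y_true == class
  if (!any(pos)) {
    warn_ctx("class '%s' absent from y_true; balanced accuracy undefined", class)
    return(NA_real_)
  }
  sens <- mean(y_pred[pos] == class)
  spec <- if (any(!pos)) mean(y_pred[!pos] != class) else NA_real_
  (sens + spec) / 2
}

#' Additive tree-Shapley attributions for boosted-tree predictions
#'
#' Exact per-feature Shapley contributions to each class's margin score,
#' computed tree by tree with cover-weighted conditional expectations (the
#' path-dependent TreeSHAP quantity) and summed over the ensemble in double
#' precision, so the additivity identity — base value plus the sum of the
#' contributions equals the class margin — holds to numerical precision well
#' inside 1e-6. Each tree's Shapley values are obtained by exhaustive subset
#' enumeration over the features that tree actually splits on (a handful for
#' shallow trees; depth-1 stumps contribute only through their single split
#' feature), which for the cover-weighted value function is exactly the
#' TreeSHAP attribution.
#'
#' @param object A `state_classifier` of kind `boosted_trees`.
#' @param profiles Binary matrix (rows = samples) or single named vector in
#'   the training feature space.
#' @return data.frame in long format: `sample`, `class`, `feature`, `value`,
#'   `base_value`, plus the per-class margin in `margin`.
#' @export
attribute <- function(object, profiles) {
  stopifnot(inherits(object, "state_classifier"))
  if (object$kind != "boosted_trees") {
    stop_ctx("attributions require a tree-based (boosted_trees) classifier")
  }
  if (is.null(dim(profiles))) profiles <- t(as.matrix(profiles))
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles))) {
    stopifnot(ncol(profiles) == length(object$features))
    colnames(profiles) <- object$features
  }
  X <- profiles[, object$selected, drop = FALSE]
  cls <- object$classes
  n_class <- length(cls)
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = object$fit))
  cfg <- xgboost::xgb.config(object$fit)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  trees <- split(dump, dump$Tree)
  tree_class <- as.integer(names(trees)) %% n_class

  feat_names <- colnames(X)
  samples <- rownames(profiles) %||% as.character(seq_len(nrow(X)))
  phi <- array(0, c(nrow(X), n_class, length(feat_names)),
               dimnames = list(samples, cls, feat_names))
  # margin recomputed independently of the attributions: base score plus the
  # leaf value on each sample's deterministic path through every tree
  marg <- matrix(base_score, nrow(X), n_class)
  base_value <- stats::setNames(rep(base_score, n_class), cls)
  for (ti in seq_along(trees)) {
    tt <- index_tree(trees[[ti]])
    ci <- tree_class[ti] + 1L
    used <- tt$used
    e0 <- tree_value(tt, NULL, character())   # unconditional expectation
    base_value[ci] <- base_value[ci] + e0
    for (i in seq_len(nrow(X))) {
      marg[i, ci] <- marg[i, ci] + tree_value(tt, X[i, ], used)
    }
    if (length(used) == 0) next
    if (length(used) > 12) {
      stop_ctx("tree %d splits on %d features; exact enumeration capped at 12",
               ti - 1L, length(used))
    }
    p <- length(used)
    masks <- 0:(2^p - 1)
    subsets <- lapply(masks, function(m) used[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
    w_size <- factorial(0:(p - 1)) * factorial(p - (0:(p - 1)) - 1) /
      factorial(p)
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      v <- vapply(subsets, function(S) tree_value(tt, x, S), numeric(1))
      for (jj in seq_len(p)) {
        bit <- 2^(jj - 1)
        without <- which(bitwAnd(masks, bit) == 0)
        sizes <- vapply(subsets[without], length, integer(1))
        phi[i, ci, used[jj]] <- phi[i, ci, used[jj]] +
          sum(w_size[sizes + 1] * (v[without + bit] - v[without]))
      }
    }
  }

  rows <- list()
  for (i in seq_len(nrow(X))) {
    for (ci in seq_len(n_class)) {
      contrib <- phi[i, ci, ]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[i], class = cls[ci], feature = feat_names,
        value = as.numeric(contrib), base_value = unname(base_value[ci]),
        margin = marg[i, ci], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# convert one tree of the model dump into an index-based structure
index_tree <- function(tr) {
  list(leaf = tr$Feature == "Leaf",
       feature = tr$Feature,
       split = tr$Split,
       yes = match(tr$Yes, tr$ID),
       no = match(tr$No, tr$ID),
       value = tr$Gain,
       cover = tr$Cover,
       used = setdiff(unique(tr$Feature), "Leaf"))
}

# cover-weighted conditional expectation of one tree: features in S follow
# the sample x, all other splits are averaged with cover weights
tree_value <- function(tt, x, S) {
  rec <- function(k) {
    if (tt$leaf[k]) return(tt$value[k])
    f <- tt$feature[k]
    if (f %in% S) {
      return(rec(if (x[[f]] < tt$split[k]) tt$yes[k] else tt$no[k]))
    }
    wy <- tt$cover[tt$yes[k]]
    wn <- tt$cover[tt$no[k]]
    (wy * rec(tt$yes[k]) + wn * rec(tt$no[k])) / (wy + wn)
  }
  rec(1L)
}
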