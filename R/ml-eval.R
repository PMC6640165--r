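# Nested cross-validated classification of intervention condition:
# stratified 80/20 outer split, rotated inner thirds for regularization
# selection, four model families, repeated splits, hierarchical feature-group
# addition.

#' Cross-validation configuration
#'
#' @param outer_test_fraction held-out test fraction per repeat (default
#'   0.2).
#' @param inner_folds inner folds for regularization selection (default 3;
#'   each third validates once).
#' @param regularization_grid ordered regularization strengths for the
#'   linear families (default 1e-3, 1e-2, 1e-1, 1, 10). For L1 logistic the
#'   values are lambda; for the SVM families cost = 1/lambda.
#' @param include_zero also try an unregularized fit (strength 0) for the
#'   L1 logistic family (default TRUE).
#' @param n_repeats number of repeated outer splits (default 20).
#' @param seed RNG seed for all splits.
#' @param model_families subset of `"logistic_l1"`, `"svm_l1"`,
#'   `"adaboost_svm"`, `"random_forest"`.
#' @param rf_nodesize_grid native complexity grid for random forests
#'   (minimum node sizes).
#' @param rf_ntree trees per forest (default 200).
#' @param adaboost_rounds boosting rounds for the AdaBoost-SVM family.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(outer_test_fraction = 0.2,
                      inner_folds = 3,
                      regularization_grid = c(1e-3, 1e-2, 1e-1, 1, 10),
                      include_zero = TRUE,
                      n_repeats = 20,
                      seed = 1L,
                      model_families = c("logistic_l1", "svm_l1",
                                         "adaboost_svm", "random_forest"),
                      rf_nodesize_grid = c(1, 2, 5, 10, 20),
                      rf_ntree = 200,
                      adaboost_rounds = 10) {
  stopifnot(outer_test_fraction > 0, outer_test_fraction < 1,
            inner_folds >= 2, length(regularization_grid) >= 1,
            all(regularization_grid > 0), n_repeats >= 1)
  model_families <- match.arg(model_families, several.ok = TRUE)
  structure(as.list(environment()), class = "cv_config")
}

# ---------------------------------------------------------------------------
# Model family backends. Each backend provides:
#   grid(config)                 -> regularization values to search
#   eval_grid(xtr, ytr, xva, grid) -> matrix of validation predictions
#   fit(x, y, value)             -> final model
#   predict(model, x)            -> 0/1 predictions
#   coefs(model)                 -> named coefficient vector or NULL
# ---------------------------------------------------------------------------

backend_logistic <- function(config) {
  grid <- sort(config$regularization_grid, decreasing = TRUE)
  if (config$include_zero) grid <- c(grid, 0)
  list(
    grid = grid,
    fit = function(x, y, value) {
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 1, lambda = sort(unique(c(grid, value)),
                                              decreasing = TRUE))
    },
    predict = function(model, x, value) {
      as.integer(predict(model, newx = x, s = value, type = "class"))
    },
    coefs = function(model, value) {
      cf <- as.matrix(coef(model, s = value))
      setNames(cf[, 1], rownames(cf))
    }
  )
}

backend_svm <- function(config) {
  grid <- config$regularization_grid
  list(
    grid = grid,
    fit = function(x, y, value) {
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = 1 / value, scale = apply(x, 2, sd) > 0)
    },
    predict = function(model, x, value) {
      as.integer(as.character(predict(model, x)))
    },
    coefs = function(model, value) {
      w <- drop(t(model$coefs) %*% model$SV)
      setNames(as.numeric(w), colnames(model$SV))
    }
  )
}

backend_adaboost <- function(config) {
  grid <- config$regularization_grid
  rounds <- config$adaboost_rounds
  list(
    grid = grid,
    fit = function(x, y, value) {
      fit_adaboost_svm(x, y, cost = 1 / value, rounds = rounds)
    },
    predict = function(model, x, value) predict_adaboost_svm(model, x),
    coefs = function(model, value) NULL
  )
}

backend_rf <- function(config) {
  grid <- config$rf_nodesize_grid
  list(
    grid = grid,
    fit = function(x, y, value) {
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = config$rf_ntree, nodesize = value)
    },
    predict = function(model, x, value) {
      as.integer(as.character(predict(model, x)))
    },
    coefs = function(model, value) NULL
  )
}

family_backend <- function(family, config) {
  switch(family,
    logistic_l1 = backend_logistic(config),
    svm_l1 = backend_svm(config),
    adaboost_svm = backend_adaboost(config),
    random_forest = backend_rf(config),
    stop("unknown model family: ", family)
  )
}

# AdaBoost.M1 with linear-SVM base learners via weighted resampling.
fit_adaboost_svm <- function(x, y, cost, rounds = 10) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  yy <- ifelse(y == 1, 1, -1)
  for (r in seq_len(rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    if (length(unique(y[idx])) < 2) next
    m <- tryCatch(
      e1071::svm(x[idx, , drop = FALSE], factor(y[idx], levels = c(0, 1)),
                 kernel = "linear", cost = cost,
                 scale = apply(x[idx, , drop = FALSE], 2, sd) > 0),
      error = function(e) NULL
    )
    if (is.null(m)) next
    pred <- as.integer(as.character(predict(m, x)))
    err <- sum(w * (pred != y))
    if (err >= 0.5) next
    err <- max(err, 1e-10)
    a <- 0.5 * log((1 - err) / err)
    pp <- ifelse(pred == 1, 1, -1)
    w <- w * exp(-a * yy * pp)
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- m
    alphas <- c(alphas, a)
  }
  if (length(learners) == 0) {
    stop("AdaBoost-SVM failed: no usable base learner")
  }
  list(learners = learners, alphas = alphas)
}

predict_adaboost_svm <- function(model, x) {
  score <- numeric(nrow(x))
  for (i in seq_along(model$learners)) {
    p <- as.integer(as.character(predict(model$learners[[i]], x)))
    score <- score + model$alphas[i] * ifelse(p == 1, 1, -1)
  }
  as.integer(score > 0)
}

# ---------------------------------------------------------------------------

#' Nested cross-validated classification
#'
#' Implements the six-step scheme: (1) stratified 80/20 train/test split;
#' (2) training set split into stratified thirds; (3-4) for each
#' regularization value, train on two thirds and validate on the remaining
#' third, rotating so each third validates once; (5) the value with the best
#' mean inner-validation accuracy (ties broken toward the most regularized
#' model) is refit on the full training set and scored on the test set;
#' (6) the whole procedure is repeated `n_repeats` times with fresh splits.
#' Mean and standard error (SD / sqrt(n_repeats)) of training and test
#' accuracy are reported per model family, with the coefficient vector of
#' the best test run for the linear families.
#'
#' @param features numeric matrix or data.frame (participants x features).
#'   Rows with missing values are dropped (and counted).
#' @param labels 0/1 intervention condition per row.
#' @param config a [cv_config()].
#' @param pca_groups optional named list of column-name vectors; each group
#'   is reduced to `pca_k` principal components fitted on the training rows
#'   of every repeat (leak-free) before model fitting.
#' @param pca_k components per group (default 5).
#' @return object of class `cv_result`: data.frame `accuracy` (per family:
#'   train/test mean and SE), list `coefficients` (best-run coefficient
#'   vectors), `selected` (per family x repeat chosen regularization),
#'   `n_dropped`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 4), 100)
#' colnames(x) <- paste0("f", 1:4)
#' y <- rbinom(100, 1, 0.5)
#' r <- nested_cv_classify(x, y, cv_config(n_repeats = 3,
#'   model_families = "logistic_l1"))
#' r
nested_cv_classify <- function(features, labels, config = cv_config(),
                               pca_groups = NULL, pca_k = 5) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) == 1) {
    # some backends need >= 2 columns; an all-zero pad is inert
    x <- cbind(x, .pad = 0)
  }
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  ok <- complete.cases(x)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2) stop("both classes must be present")

  families <- config$model_families
  acc_train <- matrix(NA_real_, config$n_repeats, length(families),
                      dimnames = list(NULL, families))
  acc_test <- acc_train
  selected <- acc_train
  best_coef <- setNames(vector("list", length(families)), families)
  best_acc <- setNames(rep(-Inf, length(families)), families)

  set.seed(as.integer(config$seed))
  seeds <- sample.int(2^30, config$n_repeats)

  for (r in seq_len(config$n_repeats)) {
    set.seed(seeds[r])
    test_idx <- stratified_split(y, config$outer_test_fraction)
    tries <- 0L
    while ((length(unique(y[test_idx])) < 2 ||
            length(unique(y[-test_idx])) < 2) && tries < 20L) {
      test_idx <- stratified_split(y, config$outer_test_fraction)
      tries <- tries + 1L
    }
    if (length(unique(y[test_idx])) < 2 ||
        length(unique(y[-test_idx])) < 2) {
      stop("could not obtain a split with both classes in train and test")
    }
    xtr_raw <- x[-test_idx, , drop = FALSE]; ytr <- y[-test_idx]
    xte_raw <- x[test_idx, , drop = FALSE]; yte <- y[test_idx]

    if (!is.null(pca_groups)) {
      red <- reduce_feature_groups(xtr_raw, xte_raw, pca_groups, pca_k)
      xtr <- red$train; xte <- red$test
    } else {
      xtr <- xtr_raw; xte <- xte_raw
    }

    fold <- stratified_folds(ytr, config$inner_folds)

    for (fam in families) {
      be <- family_backend(fam, config)
      grid <- be$grid
      val_acc <- matrix(NA_real_, config$inner_folds, length(grid))
      for (k in seq_len(config$inner_folds)) {
        xin <- xtr[fold != k, , drop = FALSE]; yin <- ytr[fold != k]
        xva <- xtr[fold == k, , drop = FALSE]; yva <- ytr[fold == k]
        for (g in seq_along(grid)) {
          # small inner folds provoke harmless small-class warnings
          m <- tryCatch(suppressWarnings(be$fit(xin, yin, grid[g])),
                        error = function(e) NULL)
          val_acc[k, g] <- if (is.null(m)) NA_real_ else {
            mean(be$predict(m, xva, grid[g]) == yva)
          }
        }
      }
      mean_acc <- colMeans(val_acc, na.rm = TRUE)
      if (all(!is.finite(mean_acc))) next
      best_g <- which(mean_acc >= max(mean_acc, na.rm = TRUE) - 1e-12)
      # tie-break toward the most regularized model
      strength <- if (fam == "random_forest") grid else grid
      pick <- if (fam == "random_forest") {
        best_g[which.max(strength[best_g])] # larger nodesize = simpler
      } else {
        best_g[which.max(strength[best_g])] # larger lambda = stronger L1
      }
      value <- grid[pick]
      model <- suppressWarnings(be$fit(xtr, ytr, value))
      tr_acc <- mean(be$predict(model, xtr, value) == ytr)
      te_acc <- mean(be$predict(model, xte, value) == yte)
      acc_train[r, fam] <- tr_acc
      acc_test[r, fam] <- te_acc
      selected[r, fam] <- value
      if (te_acc > best_acc[fam]) {
        best_acc[fam] <- te_acc
        best_coef[[fam]] <- be$coefs(model, value)
      }
    }
  }

  summarise <- function(m) {
    data.frame(
      family = colnames(m),
      mean = colMeans(m, na.rm = TRUE),
      se = apply(m, 2, function(v) sd(v, na.rm = TRUE)) /
        sqrt(colSums(!is.na(m))),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  tr <- summarise(acc_train); te <- summarise(acc_test)
  accuracy <- data.frame(
    family = tr$family,
    train_accuracy = tr$mean, train_se = tr$se,
    test_accuracy = te$mean, test_se = te$se,
    stringsAsFactors = FALSE
  )
  structure(
    list(accuracy = accuracy,
         coefficients = best_coef,
         selected = selected,
         per_repeat = list(train = acc_train, test = acc_test),
         n_dropped = n_dropped,
         config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat("Nested cross-validation (", x$config$n_repeats, "repeats,",
      sprintf("%.0f%%", 100 * x$config$outer_test_fraction),
      "test fraction )\n")
  print(x$accuracy, digits = digits, row.names = FALSE)
  if (x$n_dropped > 0) cat("rows dropped for missing values:",
                           x$n_dropped, "\n")
  invisible(x)
}

# Per-repeat leak-free PCA: fit each group's reduction on training rows,
# project train and test.
reduce_feature_groups <- function(xtr, xte, groups, k) {
  tr_parts <- list(); te_parts <- list()
  for (g in names(groups)) {
    cols <- intersect(groups[[g]], colnames(xtr))
    if (length(cols) == 0) next
    if (length(cols) <= k) {
      tr_parts[[g]] <- xtr[, cols, drop = FALSE]
      te_parts[[g]] <- xte[, cols, drop = FALSE]
      next
    }
    red <- suppressWarnings(reduce_pca(xtr[, cols, drop = FALSE], k = k))
    str <- red$scores
    ste <- predict(red, xte[, cols, drop = FALSE])
    colnames(str) <- colnames(ste) <- paste0(g, "_pc", seq_len(ncol(str)))
    tr_parts[[g]] <- str; te_parts[[g]] <- ste
  }
  list(train = do.call(cbind, tr_parts), test = do.call(cbind, te_parts))
}

#' Reduce a feature group to principal components
#'
#' Shared reduction used before hierarchical evaluation: standardized PCA
#' ([reduce_pca()]) returning the first k component scores per participant.
#'
#' @param features participants x variables table.
#' @param k components (default 5).
#' @return score matrix with named columns.
#' @export
reduce_group_pca <- function(features, k = 5) {
  red <- reduce_pca(features, k = k)
  s <- red$scores
  colnames(s) <- paste0("pc", seq_len(ncol(s)))
  s
}

#' Hierarchical feature-group evaluation
#'
#' Evaluates (a) each feature group alone and (b) the baseline group plus
#' each additional group, all through [nested_cv_classify()], and tabulates
#' mean +/- SE accuracies with the test-accuracy delta against the baseline
#' combination. Any increase above the baseline accuracy beyond its
#' uncertainty indicates that the added group carries condition information.
#'
#' @param groups named, ordered list of feature tables (participants x
#'   variables), all with the same aligned rows; the first group is the
#'   baseline (self-report in the source design).
#' @param labels 0/1 condition per participant.
#' @param config a [cv_config()].
#' @param pca_k components used to reduce each group (default 5); set to
#'   `NULL` to use raw variables.
#' @param pca_scope `"fold"` (leak-free: reductions fitted inside each
#'   training split) or `"global"` (one reduction on all participants before
#'   cross-validation).
#' @return data.frame of class `hierarchical_cv`: one row per combination x
#'   family with train/test accuracy, SE, and `delta_test_vs_baseline`.
#' @export
hierarchical_evaluation <- function(groups, labels, config = cv_config(),
                                    pca_k = 5,
                                    pca_scope = c("fold", "global")) {
  pca_scope <- match.arg(pca_scope)
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  n <- nrow(as.matrix(groups[[1]]))
  for (g in names(groups)) {
    gm <- as.matrix(groups[[g]])
    if (nrow(gm) != n) {
      stop("feature groups are misaligned: group '", g, "' has ",
           nrow(gm), " rows, expected ", n)
    }
    rn1 <- rownames(as.matrix(groups[[1]])); rng <- rownames(gm)
    if (!is.null(rn1) && !is.null(rng) && !identical(rn1, rng)) {
      stop("participant mismatch in group '", g, "': ",
           paste(head(setdiff(rng, rn1)), collapse = ", "))
    }
  }

  prep <- function(sel) {
    # build the combined feature matrix + pca group map for `sel` groups
    mats <- lapply(sel, function(g) {
      m <- as.matrix(groups[[g]])
      colnames(m) <- paste(g, colnames(m) %||%
                             paste0("v", seq_len(ncol(m))), sep = ".")
      m
    })
    xx <- do.call(cbind, mats)
    gmap <- lapply(seq_along(sel), function(i) colnames(mats[[i]]))
    names(gmap) <- sel
    list(x = xx, map = gmap)
  }

  run <- function(sel) {
    pr <- prep(sel)
    if (is.null(pca_k)) {
      nested_cv_classify(pr$x, labels, config)
    } else if (pca_scope == "fold") {
      nested_cv_classify(pr$x, labels, config,
                         pca_groups = pr$map, pca_k = pca_k)
    } else {
      parts <- lapply(names(pr$map), function(g) {
        cols <- pr$map[[g]]
        if (length(cols) <= pca_k) return(pr$x[, cols, drop = FALSE])
        s <- reduce_group_pca(pr$x[, cols, drop = FALSE], k = pca_k)
        colnames(s) <- paste0(g, "_", colnames(s))
        s
      })
      nested_cv_classify(do.call(cbind, parts), labels, config)
    }
  }

  baseline <- names(groups)[1]
  combos <- c(
    lapply(names(groups), function(g) g),
    if (length(groups) > 1) {
      lapply(names(groups)[-1], function(g) c(baseline, g))
    }
  )
  out <- list()
  base_acc <- setNames(rep(NA_real_, length(config$model_families)),
                       config$model_families)
  for (cb in combos) {
    res <- run(cb)
    a <- res$accuracy
    a$combination <- paste(cb, collapse = "+")
    if (identical(cb, baseline)) {
      base_acc[a$family] <- a$test_accuracy
    }
    out[[length(out) + 1L]] <- a
  }
  tab <- do.call(rbind, out)
  tab$delta_test_vs_baseline <- tab$test_accuracy - base_acc[tab$family]
  tab <- tab[, c("combination", "family", "train_accuracy", "train_se",
                 "test_accuracy", "test_se", "delta_test_vs_baseline")]
  class(tab) <- c("hierarchical_cv", "data.frame")
  tab
}

#' @export
print.hierarchical_cv <- function(x, digits = 3, ...) {
  cat("Hierarchical feature-group evaluation:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
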