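# The eight-transporter IC50 QSAR panel. Each hepatic transporter has a
# fixed learning algorithm; models are regressors on pIC50 (-log10 molar),
# the standard QSAR target scale. IC50 in micromolar and pIC50 are linked by
# ic50_uM = 10^(6 - pic50).

#' Transporters of the cholestasis panel
#' @return Character vector of the eight transporter names.
#' @export
panel_transporters <- function() {
  c("BCRP", "MRP2", "MRP3", "MRP4", "OATP1B1", "OATP1B3", "BSEP", "P-gp")
}

# Fixed transporter -> algorithm assignment.
default_algorithm_map <- function() {
  c(BCRP = "random_forest", MRP2 = "random_forest", MRP3 = "svm",
    MRP4 = "random_forest", OATP1B1 = "random_forest", OATP1B3 = "svm",
    BSEP = "xgboost", `P-gp` = "random_forest")
}

#' Default transporter panel
#'
#' Returns the eight-transporter panel with its fixed algorithm assignment:
#' random forest for BCRP, MRP2, MRP4, OATP1B1 and P-gp; support vector
#' machine for MRP3 and OATP1B3; XGBoost for BSEP. Estimators are empty
#' until trained with [train_transporter_model()] or [train_panel()].
#'
#' @param feature_spec Featurization recipe tag; must match the vectors the
#'   panel will be trained and queried with.
#' @return Object of class `transporter_panel`.
#' @export
default_panel <- function(feature_spec = feature_spec_id()) {
  structure(
    list(
      transporters = panel_transporters(),
      algorithm_map = default_algorithm_map(),
      estimators = stats::setNames(
        vector("list", length(panel_transporters())), panel_transporters()),
      feature_spec_id = feature_spec
    ),
    class = "transporter_panel"
  )
}

#' @export
print.transporter_panel <- function(x, ...) {
  cat("Transporter IC50 panel (", x$feature_spec_id, ")\n", sep = "")
  for (t in x$transporters) {
    fitted <- if (is.null(x$estimators[[t]])) "untrained" else "fitted"
    cat(sprintf("  %-8s %-14s %s\n", t, x$algorithm_map[[t]], fitted))
  }
  invisible(x)
}

#' pIC50 to IC50 conversion
#'
#' `ic50_uM = 10^(6 - pic50)`; pIC50 is -log10 of the molar IC50.
#' @param pic50 Numeric vector.
#' @return IC50 in micromolar, always positive.
#' @export
pic50_to_ic50 <- function(pic50) 10^(6 - pic50)

#' @rdname pic50_to_ic50
#' @param ic50_uM IC50 in micromolar, > 0.
#' @export
ic50_to_pic50 <- function(ic50_uM) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("ic50_uM must be finite and > 0")
  }
  6 - log10(ic50_uM)
}

check_transporter <- function(panel, transporter) {
  stopifnot(inherits(panel, "transporter_panel"))
  if (!transporter %in% panel$transporters) {
    stop(sprintf("unknown transporter '%s'; panel members: %s", transporter,
                 paste(panel$transporters, collapse = ", ")))
  }
}

check_features <- function(panel, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  fsid <- attr(features, "feature_spec_id")
  if (!is.null(fsid) && !identical(fsid, panel$feature_spec_id)) {
    stop(sprintf("feature spec mismatch: panel '%s' vs features '%s'",
                 panel$feature_spec_id, fsid))
  }
  if (ncol(features) != feature_length()) {
    stop(sprintf("feature length %d does not match recipe length %d",
                 ncol(features), feature_length()))
  }
  features
}

#' Train one transporter's IC50 model
#'
#' Fits the regressor assigned to `transporter` on (feature vector, pIC50)
#' pairs. Hyperparameters are fixed, documented defaults: random forest with
#' 500 trees; RBF support vector machine with cost and gamma chosen on a
#' small grid by 5-fold cross-validation; XGBoost with 300 rounds, maximum
#' depth 6, learning rate 0.05, single-threaded. Training is reproducible
#' given `seed`.
#'
#' @param panel `transporter_panel`.
#' @param transporter Panel member name.
#' @param features Numeric feature matrix (rows = compounds), as produced by
#'   [featurize()].
#' @param pic50 Numeric target vector, finite, length `nrow(features)`.
#' @param seed Integer RNG seed.
#' @return Fitted estimator (class `cholmech_estimator`). Insert into a
#'   panel with [set_estimator()] or use [train_panel()].
#' @export
train_transporter_model <- function(panel, transporter, features, pic50,
                                    seed = 42L) {
  check_transporter(panel, transporter)
  features <- check_features(panel, features)
  if (nrow(features) < 20L) {
    stop("at least 20 training pairs are required")
  }
  if (length(pic50) != nrow(features) || any(!is.finite(pic50))) {
    stop("pic50 must be finite and match the number of feature rows")
  }
  algorithm <- panel$algorithm_map[[transporter]]
  set.seed(seed)
  # drop zero-variance columns (constant fingerprint bits); remember which,
  # so prediction uses the same columns
  keep <- which(apply(features, 2, function(col) any(col != col[1])))
  if (length(keep) == 0L) keep <- 1L
  x <- features[, keep, drop = FALSE]
  # standardize once (fingerprint bits and physicochemical values live on
  # very different scales, which matters for the RBF kernel); constants are
  # stored in the estimator so prediction reuses them
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  hyper <- NULL
  fit <- switch(
    algorithm,
    random_forest = {
      hyper <- list(ntree = 500)
      randomForest::randomForest(x = x, y = pic50, ntree = 500)
    },
    svm = {
      # Univariate feature screen: the RBF distance over a thousand mostly
      # uninformative fingerprint bits drowns the signal, so keep only the
      # top-k features by absolute correlation with the target. The screen
      # size is tuned jointly with cost and gamma by 5-fold CV on shared
      # folds.
      co <- abs(suppressWarnings(stats::cor(x, pic50)))
      co[is.na(co)] <- 0
      ord <- order(co, decreasing = TRUE)
      fold_id <- rep_len(seq_len(5L), length(pic50))[sample.int(length(pic50))]
      grid <- expand.grid(k = pmin(c(32L, 64L, 128L), ncol(x)),
                          cost = c(1, 10), gamma_scale = c(0.2, 1, 5))
      grid <- grid[!duplicated(grid), ]
      cv_err <- vapply(seq_len(nrow(grid)), function(i) {
        k <- grid$k[i]
        cols <- ord[seq_len(k)]
        xs <- scale(x[, cols, drop = FALSE], center = center[cols],
                    scale = scl[cols])
        svm_cv_error(xs, pic50, cost = grid$cost[i],
                     gamma = grid$gamma_scale[i] / k, fold_id = fold_id)
      }, numeric(1))
      best <- grid[which.min(cv_err), ]
      top <- ord[seq_len(best$k)]
      keep <- keep[top]
      x <- x[, top, drop = FALSE]
      center <- center[top]
      scl <- scl[top]
      hyper <- list(kernel = "radial", cost = best$cost,
                    gamma = best$gamma_scale / best$k,
                    screen_top_k = best$k)
      e1071::svm(x = scale(x, center = center, scale = scl), y = pic50,
                 kernel = "radial", cost = best$cost,
                 gamma = best$gamma_scale / best$k, scale = FALSE)
    },
    xgboost = {
      # moderately regularized boosting: shallow trees with column
      # subsampling generalize better when informative descriptors are a
      # small fraction of a wide fingerprint block
      hyper <- list(nrounds = 300, max_depth = 4, eta = 0.05,
                    colsample_bytree = 0.3, subsample = 0.8, lambda = 5,
                    min_child_weight = 5)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = 4,
                      eta = 0.05, colsample_bytree = 0.3, subsample = 0.8,
                      lambda = 5, min_child_weight = 5,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = pic50),
        nrounds = 300, verbose = 0
      )
    },
    stop(sprintf("unsupported algorithm '%s'", algorithm))
  )
  structure(
    list(transporter = transporter, algorithm = algorithm, fit = fit,
         keep_columns = keep, center = center, scale = scl,
         feature_spec_id = panel$feature_spec_id,
         seed = seed, hyperparameters = hyper, n_train = nrow(features)),
    class = "cholmech_estimator"
  )
}

svm_cv_error <- function(x, y, cost, gamma, fold_id) {
  n <- length(y)
  sq <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    m <- e1071::svm(x = x[tr, , drop = FALSE], y = y[tr], kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
    pr <- stats::predict(m, x[!tr, , drop = FALSE])
    sq <- sq + sum((pr - y[!tr])^2)
  }
  sq / n
}

#' Insert a fitted estimator into a panel
#' @param panel `transporter_panel`.
#' @param estimator `cholmech_estimator` from [train_transporter_model()].
#' @return The panel with the estimator attached.
#' @export
set_estimator <- function(panel, estimator) {
  stopifnot(inherits(estimator, "cholmech_estimator"))
  check_transporter(panel, estimator$transporter)
  if (!identical(estimator$feature_spec_id, panel$feature_spec_id)) {
    stop("estimator feature spec does not match the panel")
  }
  panel$estimators[[estimator$transporter]] <- estimator
  panel
}

#' Train every (selected) transporter model of a panel
#'
#' @param panel `transporter_panel`.
#' @param training_sets Named list (by transporter) of lists with elements
#'   `features` (matrix) and `pic50` (numeric).
#' @param seed Integer base seed; each transporter trains under
#'   `seed + its panel index`.
#' @return Fitted panel.
#' @export
train_panel <- function(panel, training_sets, seed = 42L) {
  for (t in names(training_sets)) {
    est <- train_transporter_model(
      panel, t, training_sets[[t]]$features, training_sets[[t]]$pic50,
      seed = seed + match(t, panel$transporters)
    )
    panel <- set_estimator(panel, est)
  }
  panel
}

estimator_pic50 <- function(estimator, features) {
  x <- features[, estimator$keep_columns, drop = FALSE]
  # deserialized fits need their package namespace for S3 predict dispatch
  ns <- switch(estimator$algorithm, random_forest = "randomForest",
               svm = "e1071", xgboost = "xgboost", NULL)
  if (!is.null(ns)) loadNamespace(ns)
  switch(
    estimator$algorithm,
    random_forest = as.numeric(stats::predict(estimator$fit, x)),
    svm = as.numeric(stats::predict(
      estimator$fit,
      scale(x, center = estimator$center, scale = estimator$scale))),
    xgboost = as.numeric(stats::predict(estimator$fit,
                                        xgboost::xgb.DMatrix(x))),
    oracle = as.numeric(oracle_pic50(estimator$fit, features)),
    stop(sprintf("unsupported algorithm '%s'", estimator$algorithm))
  )
}

#' Predict IC50 for one transporter
#'
#' @param panel Fitted `transporter_panel`.
#' @param transporter Panel member with a fitted estimator.
#' @param features Feature matrix (or single vector) from [featurize()].
#' @return data.frame with columns `transporter`, `pic50`, `ic50_uM`
#'   (one row per compound, in input order).
#' @export
predict_ic50 <- function(panel, transporter, features) {
  check_transporter(panel, transporter)
  features <- check_features(panel, features)
  est <- panel$estimators[[transporter]]
  if (is.null(est)) {
    stop(sprintf(
      "transporter '%s' has no fitted estimator; train it first", transporter))
  }
  if (!identical(est$feature_spec_id, panel$feature_spec_id)) {
    stop("estimator feature spec does not match the panel")
  }
  pic50 <- estimator_pic50(est, features)
  data.frame(transporter = transporter, pic50 = pic50,
             ic50_uM = pic50_to_ic50(pic50))
}

#' Persist a fitted panel
#'
#' Writes one serialized estimator per transporter plus a JSON manifest
#' recording the algorithm map, featurization recipe, seeds and
#' hyperparameters.
#'
#' @param panel Fitted `transporter_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "transporter_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fitted <- names(Filter(Negate(is.null), panel$estimators))
  for (t in fitted) {
    est <- panel$estimators[[t]]
    if (identical(est$algorithm, "xgboost")) {
      # xgboost handles are external pointers; serialize via raw vector
      est$fit <- xgboost::xgb.save.raw(est$fit)
      est$xgb_raw <- TRUE
    }
    saveRDS(est, file.path(dir, paste0(safe_name(t), ".rds")))
  }
  manifest <- list(
    package = "cholmech",
    feature_spec_id = panel$feature_spec_id,
    transporters = panel$transporters,
    algorithm_map = as.list(panel$algorithm_map),
    fitted = fitted,
    seeds = lapply(panel$estimators[fitted], function(e) e$seed),
    hyperparameters = lapply(panel$estimators[fitted],
                             function(e) e$hyperparameters)
  )
  jsonlite::write_json(manifest, file.path(dir, "panel_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Load a persisted panel
#' @param dir Directory written by [save_panel()].
#' @return Fitted `transporter_panel`.
#' @export
load_panel <- function(dir) {
  manifest_path <- file.path(dir, "panel_manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no panel manifest at '%s'; train models first", dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  panel <- default_panel(feature_spec = manifest$feature_spec_id)
  for (t in manifest$fitted) {
    est <- readRDS(file.path(dir, paste0(safe_name(t), ".rds")))
    if (isTRUE(est$xgb_raw)) {
      est$fit <- xgboost::xgb.load.raw(est$fit)
      est$xgb_raw <- NULL
    }
    panel <- set_estimator(panel, est)
  }
  panel
}
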