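# Reverse dosimetry and the cholestasis call.
#
# A predicted IC50 (uM) is converted to the oral dose rate whose steady-state
# plasma concentration equals it (QIVIVE, valid because Css is linear in
# dose), divided by the user's correction factor K, and compared with the
# compound's therapeutic dose under one of three logical rules over the
# selected transporters.

#' Rule configuration for the cholestasis call
#'
#' @param selected Non-empty subset of [panel_transporters()].
#' @param rule One of "OR", "AND", "MAJORITY" (case-insensitive).
#' @param k Correction factor applied to the in vivo doses, > 0, default 1.
#'   By default the extrapolated dose is DIVIDED by `k`, so `k` > 1 acts as a
#'   conservative uncertainty factor that lowers the flagging threshold and
#'   marks more compounds as cholestatic; set `k_multiplies = TRUE` for the
#'   inverse convention.
#' @param k_multiplies Use the inverse convention (multiply by `k`).
#' @return Object of class `rule_config`.
#' @export
rule_config <- function(selected = panel_transporters(), rule = "OR", k = 1,
                        k_multiplies = FALSE) {
  rule <- toupper(rule)
  if (!rule %in% c("OR", "AND", "MAJORITY")) {
    stop("rule must be one of OR, AND, MAJORITY")
  }
  if (length(selected) == 0) stop("at least one transporter must be selected")
  bad <- setdiff(selected, panel_transporters())
  if (length(bad)) {
    stop("unknown transporter(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a finite positive number")
  }
  structure(list(selected = unique(selected), rule = rule, k = k,
                 k_multiplies = isTRUE(k_multiplies)),
            class = "rule_config")
}

#' QIVIVE: IC50 to oral-equivalent dose
#'
#' Converts an in vitro inhibitory concentration to the oral dose rate whose
#' analytic steady-state plasma concentration equals it:
#' `dose = (ic50_uM * mw / 1000) / css_analytic(params, 1)` mg/kg/day.
#' Linear in `ic50_uM`.
#'
#' @param ic50_uM IC50 in micromolar, >= 0. Vectorized.
#' @param mw Molecular weight, g/mol, > 0.
#' @param params `pbtk_parameters` with a nonzero clearance pathway.
#' @return Dose rate(s), mg/kg/day.
#' @export
qivive_dose <- function(ic50_uM, mw, params) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM < 0)) {
    stop("ic50_uM must be finite and >= 0")
  }
  if (!is.finite(mw) || mw <= 0) stop("mw must be > 0")
  c_mgL <- ic50_uM * mw / 1000
  c_mgL / css_analytic(params, 1)
}

#' Apply the correction factor K
#'
#' @param dose Dose rate(s), mg/kg/day.
#' @param k Correction factor, > 0.
#' @param k_multiplies If TRUE, multiply instead of divide (inverse
#'   convention).
#' @return Corrected dose rate(s).
#' @export
apply_correction <- function(dose, k, k_multiplies = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a finite positive number")
  }
  if (isTRUE(k_multiplies)) dose * k else dose / k
}

#' Rule-based cholestasis call
#'
#' A transporter "votes" cholestatic when the therapeutic dose strictly
#' exceeds that transporter's (K-corrected) in vivo dose. OR flags the
#' compound on at least one vote, AND on all votes, MAJORITY on strictly
#' more than half of the selected transporters.
#'
#' @param td_per_kg Therapeutic dose, mg/kg/day.
#' @param doses Named numeric vector of in vivo doses (mg/kg/day) covering
#'   every selected transporter.
#' @param config `rule_config`.
#' @return Integer 0/1.
#' @export
classify <- function(td_per_kg, doses, config) {
  stopifnot(inherits(config, "rule_config"))
  if (!is.finite(td_per_kg)) stop("td_per_kg must be a finite number")
  missing_t <- setdiff(config$selected, names(doses))
  if (length(missing_t)) {
    stop("missing in vivo dose for transporter(s): ",
         paste(missing_t, collapse = ", "))
  }
  votes <- td_per_kg > doses[config$selected]  # strict inequality
  n <- length(votes)
  pos <- switch(config$rule,
                OR = any(votes),
                AND = all(votes),
                MAJORITY = sum(votes) > n / 2)
  as.integer(pos)
}

#' Predict cholestasis for one compound
#'
#' Full mechanistic pipeline for a single compound record: featurize the
#' structure, predict per-transporter IC50s with the fitted panel, convert
#' each to an oral-equivalent dose by reverse dosimetry, apply the
#' correction factor, and call the compound against its therapeutic dose
#' under the configured rule. The continuous ranking score is the fraction
#' of selected transporters voting cholestatic.
#'
#' @param record One-row compound table slice or list with at least `smiles`,
#'   `fub`, `clint`, and `dose_max` (mg/day) unless `expected_dose` is given.
#' @param panel Fitted `transporter_panel` covering `config$selected`.
#' @param config `rule_config`.
#' @param physiology Optional named list of physiology overrides.
#' @param expected_dose Fallback daily dose, mg/day, used when `dose_max` is
#'   absent.
#' @param features Optional precomputed feature row for the compound (skips
#'   featurization; used by batch callers).
#' @return Object of class `prediction_result`.
#' @export
predict_compound <- function(record, panel, config = rule_config(),
                             physiology = NULL, expected_dose = NULL,
                             features = NULL) {
  rec <- as.list(record)
  stopifnot(inherits(panel, "transporter_panel"),
            inherits(config, "rule_config"))
  dose_max <- rec$dose_max
  if (is.null(dose_max) || is.na(dose_max)) dose_max <- expected_dose
  if (is.null(dose_max) || is.na(dose_max)) {
    stop("no exposure estimate: dose_max is absent and no expected dose given")
  }
  params <- build_parameters(rec, overrides = physiology %||% list())
  if (is.null(features)) features <- featurize(rec$smiles)
  mw <- unname(features[1, "MW"])
  doses <- vapply(config$selected, function(t) {
    ic50 <- predict_ic50(panel, t, features)$ic50_uM
    apply_correction(qivive_dose(ic50, mw, params), config$k,
                     config$k_multiplies)
  }, numeric(1))
  td_per_kg <- dose_max / params$body_weight
  predicted <- classify(td_per_kg, doses, config)
  votes <- sum(td_per_kg > doses)
  activity <- rec$activity
  agrees <- if (is.null(activity) || is.na(activity)) NA else
    identical(as.integer(activity), predicted)
  structure(
    list(compound = rec, in_vivo_dose = doses, td_per_kg = td_per_kg,
         predicted = predicted, score = votes / length(doses),
         rule_used = config, agrees = agrees),
    class = "prediction_result"
  )
}

#' Predict cholestasis for a compound table
#'
#' @param table `compound_table` (or data.frame with the same columns).
#' @param panel Fitted `transporter_panel`.
#' @param config `rule_config`.
#' @inheritParams predict_compound
#' @return List of `prediction_result` (class `prediction_results`), input
#'   order preserved.
#' @export
predict_batch <- function(table, panel, config = rule_config(),
                          physiology = NULL, expected_dose = NULL) {
  stopifnot(nrow(table) >= 1L)
  feats <- featurize(table$smiles)
  results <- lapply(seq_len(nrow(table)), function(i) {
    predict_compound(table[i, ], panel, config, physiology = physiology,
                     expected_dose = expected_dose,
                     features = feats[i, , drop = FALSE])
  })
  structure(results, class = "prediction_results")
}

#' @export
print.prediction_result <- function(x, ...) {
  lab <- if (x$predicted == 1) "cholestatic" else "non-cholestatic"
  cat(sprintf("%s: predicted %s (rule %s, K = %g, score %.2f)\n",
              x$compound$name %||% x$compound$smiles, lab, x$rule_used$rule,
              x$rule_used$k, x$score))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate prediction results
#'
#' One row per compound: the input fields, the K-corrected in vivo dose per
#' selected transporter (columns `dose_<transporter>`), the predicted
#' activity, the ranking score, and agreement with the experimental label
#' where available.
#'
#' @param x `prediction_results`.
#' @param ... Unused.
#' @return data.frame.
#' @export
as.data.frame.prediction_results <- function(x, ...) {
  selected <- x[[1]]$rule_used$selected
  rows <- lapply(x, function(r) {
    rec <- r$compound
    base <- data.frame(
      name = rec$name %||% NA_character_,
      chembl_id = rec$chembl_id %||% NA_character_,
      smiles = rec$smiles,
      dose_max = rec$dose_max %||% NA_real_,
      activity = rec$activity %||% NA_integer_,
      fub = rec$fub, clint = rec$clint,
      stringsAsFactors = FALSE
    )
    dose_cols <- as.data.frame(as.list(r$in_vivo_dose))
    # syntactic column names so the CSV round-trips without renaming
    names(dose_cols) <- paste0("dose_", gsub("[^A-Za-z0-9_]", "_", selected))
    cbind(base, dose_cols,
          data.frame(predicted_activity = r$predicted, score = r$score,
                     agrees = r$agrees))
  })
  do.call(rbind, rows)
}

#' Evaluate predictions against experimental activity
#'
#' Computes the confusion matrix and the panel of classification metrics:
#' sensitivity, specificity, accuracy, Matthews correlation coefficient, and
#' AUC by the rank statistic over the continuous score with midrank tie
#' handling. AUC and MCC are reported as NA (flagged undefined) unless both
#' classes are present.
#'
#' @param results `prediction_results`, or a data.frame with columns
#'   `activity`, `predicted_activity` and `score`.
#' @return Object of class `metrics_report`.
#' @export
evaluate <- function(results) {
  if (inherits(results, "prediction_results")) {
    results <- as.data.frame(results)
  }
  df <- results[!is.na(results$activity), , drop = FALSE]
  if (nrow(df) == 0) stop("no results with experimental activity to evaluate")
  y <- as.integer(df$activity)
  yhat <- as.integer(df$predicted_activity)
  score <- as.numeric(df$score)
  tp <- sum(y == 1 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  tn <- sum(y == 0 & yhat == 0); fp <- sum(y == 0 & yhat == 1)
  n <- length(y)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  auc <- if (any(y == 1) && any(y == 0)) auc_midrank(y, score) else NA_real_
  structure(
    c(metrics,
      list(auc = auc, n = n,
           confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
           both_classes = any(y == 1) && any(y == 0))),
    class = "metrics_report"
  )
}

# Closed-form metrics from a 2x2 confusion table. Undefined ratios (empty
# class, zero MCC denominator) are NA. Vectorized over table entries.
confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  acc <- (tp + tn) / n
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, NA_real_)
  list(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

# Rank-statistic AUC (equivalent to the Mann-Whitney U) with midrank ties.
auc_midrank <- function(y, score) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (n =", x$n, ")\n")
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  for (m in c("sensitivity", "specificity", "accuracy", "mcc", "auc")) {
    cat(sprintf("  %-11s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined (one class only)",
                       sprintf("%.4f", x[[m]]))))
  }
  invisible(x)
}
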