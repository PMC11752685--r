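# Shared fixtures and independent oracles, built in code at test time.

.test_cache <- new.env(parent = emptyenv())

# Small synthetic compound table (computed once per test run).
small_table <- function() {
  if (is.null(.test_cache$small_table)) {
    .test_cache$small_table <-
      generate_compound_table(fixture_spec(n_compounds = 25L, seed = 101L))
  }
  .test_cache$small_table
}

# Feature matrix of the embedded SMILES library, with a lookup by SMILES.
lib_features <- function() {
  if (is.null(.test_cache$lib_features)) {
    .test_cache$lib_features <- featurize(unname(drug_smiles_library()))
    .test_cache$lib_smiles <- unname(drug_smiles_library())
  }
  .test_cache$lib_features
}

features_for_smiles <- function(smiles) {
  f <- lib_features()
  idx <- match(smiles, .test_cache$lib_smiles)
  stopifnot(!anyNA(idx))
  out <- f[idx, , drop = FALSE]
  attr(out, "feature_spec_id") <- attr(f, "feature_spec_id")
  out
}

# Independent brute-force classification metrics from label/prediction/score
# vectors: explicit counting and O(n^2) pairwise AUC with half-credit ties.
brute_force_metrics <- function(y, yhat, score) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && yhat[i] == 1) fp <- fp + 1L
    if (y[i] == 0 && yhat[i] == 0) tn <- tn + 1L
    if (y[i] == 1 && yhat[i] == 0) fn <- fn + 1L
  }
  pos <- which(y == 1); neg <- which(y == 0)
  auc <- NA_real_
  if (length(pos) > 0 && length(neg) > 0) {
    wins <- 0
    for (i in pos) for (j in neg) {
      if (score[i] > score[j]) wins <- wins + 1
      else if (score[i] == score[j]) wins <- wins + 0.5
    }
    auc <- wins / (length(pos) * length(neg))
  }
  s1 <- tp + fn; s0 <- tn + fp; p1 <- tp + fp; p0 <- tn + fn
  mcc <- if (s1 > 0 && s0 > 0 && p1 > 0 && p0 > 0) {
    (tp * tn - fp * fn) / sqrt(s1) / sqrt(s0) / sqrt(p1) / sqrt(p0)
  } else NA_real_
  list(
    sensitivity = if (s1 > 0) tp / s1 else NA_real_,
    specificity = if (s0 > 0) tn / s0 else NA_real_,
    accuracy = (tp + tn) / length(y),
    mcc = mcc, auc = auc,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)
  )
}

# Truth-table oracle for the combination rules, straight from their
# definitions over an explicit vote vector.
rule_oracle <- function(votes, rule) {
  k <- sum(votes); n <- length(votes)
  switch(rule,
         OR = as.integer(k >= 1),
         AND = as.integer(k == n),
         MAJORITY = as.integer(k > n / 2))
}

# Construct per-transporter doses realizing a given vote pattern at td = 1.
doses_for_votes <- function(votes, transporters) {
  stats::setNames(ifelse(votes, 0.5, 2), transporters)
}
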