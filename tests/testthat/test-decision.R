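# Reverse dosimetry, the correction factor, the combination rules, and the
# evaluation metrics, each against independent oracles.

test_that("QIVIVE dose is linear in IC50 with the defining fixed point", {
  p <- build_parameters(list(fub = 0.3, clint = 12))
  expect_identical(qivive_dose(0, 300, p), 0)
  set.seed(4)
  ic <- 10^runif(20, -2, 3)
  expect_equal(qivive_dose(2 * ic, 350, p), 2 * qivive_dose(ic, 350, p),
               tolerance = 1e-12)
  # an IC50 whose mass concentration equals Css at 1 mg/kg/day maps to
  # exactly 1 mg/kg/day
  mw <- 300
  ic_fix <- css_analytic(p, 1) * 1000 / mw
  expect_equal(qivive_dose(ic_fix, mw, p), 1, tolerance = 1e-12)
  expect_error(qivive_dose(-1, 300, p), "ic50")
  expect_error(qivive_dose(1, 0, p), "mw")
})

test_that("the correction factor divides doses and is monotone in effect", {
  expect_identical(apply_correction(7.5, 1), 7.5)
  expect_equal(apply_correction(10, 10), 1)
  expect_equal(apply_correction(10, 10, k_multiplies = TRUE), 100)
  expect_error(apply_correction(1, 0), "k")
  expect_error(apply_correction(1, -2), "k")

  # growing K never un-flags a compound
  set.seed(8)
  for (rep in 1:30) {
    doses <- stats::setNames(10^runif(4, -2, 2), panel_transporters()[1:4])
    td <- 10^runif(1, -2, 2)
    cfgs <- lapply(c(0.5, 1, 2, 10), function(k)
      rule_config(selected = names(doses), rule = "MAJORITY", k = k))
    calls <- vapply(cfgs, function(cfg)
      classify(td, apply_correction(doses, cfg$k), cfg), integer(1))
    expect_true(all(diff(calls) >= 0))
  }
})

test_that("rule semantics match the quoted definitions on a forced example", {
  doses <- c(A = 5, B = 20)
  names(doses) <- c("BSEP", "P-gp")
  td <- 10  # votes: BSEP yes (10 > 5), P-gp no (10 < 20)
  expect_identical(classify(td, doses, rule_config(names(doses), "OR")), 1L)
  expect_identical(classify(td, doses, rule_config(names(doses), "AND")), 0L)
  expect_identical(classify(td, doses, rule_config(names(doses), "MAJORITY")),
                   0L)  # needs strictly more than 1 of 2
  # ties are non-cholestatic: strict inequality
  expect_identical(classify(5, c(BSEP = 5), rule_config("BSEP", "OR")), 0L)
})

test_that("with one selected transporter all three rules coincide", {
  for (dose in c(0.5, 2)) {
    calls <- vapply(c("OR", "AND", "MAJORITY"), function(r)
      classify(1, c(BSEP = dose), rule_config("BSEP", r)), integer(1))
    expect_true(all(calls == calls[1]))
  }
})

test_that("exhaustive truth tables match the brute-force oracle for 1-8 transporters", {
  for (n in 1:8) {
    sel <- panel_transporters()[seq_len(n)]
    patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    for (i in seq_len(nrow(patterns))) {
      votes <- patterns[i, ]
      doses <- doses_for_votes(votes, sel)
      calls <- vapply(c("OR", "AND", "MAJORITY"), function(r)
        classify(1, doses, rule_config(sel, r)), integer(1))
      oracle <- vapply(c("OR", "AND", "MAJORITY"), function(r)
        rule_oracle(votes, r), integer(1))
      expect_identical(calls, oracle)
      # AND-positive implies MAJORITY-positive implies OR-positive
      expect_true(calls["AND"] <= calls["MAJORITY"])
      expect_true(calls["MAJORITY"] <= calls["OR"])
    }
  }
})

test_that("classify validates its inputs", {
  expect_error(classify(1, c(BSEP = 1), rule_config(c("BSEP", "P-gp"), "OR")),
               "missing in vivo dose")
  expect_error(rule_config(character(0), "OR"), "at least one")
  expect_error(rule_config("BSEP", "XOR"), "rule")
  expect_error(rule_config("NotATransporter", "OR"), "unknown")
})

test_that("engineered compounds are called identically under all rules", {
  spec <- fixture_spec(n_compounds = 10L, seed = 31L)
  tab <- small_table()[1:3, ]
  pan <- oracle_panel(fixture_spec(25L, 101L))
  for (rule in c("OR", "AND", "MAJORITY")) {
    # huge therapeutic dose: every transporter votes -> predicted 1
    res_hi <- predict_compound(
      transform(tab[1, ], dose_max = 1e9), pan,
      rule_config(rule = rule, k = 1))
    expect_identical(res_hi$predicted, 1L)
    expect_identical(res_hi$score, 1)
    # vanishing therapeutic dose: no votes -> predicted 0
    res_lo <- predict_compound(
      transform(tab[1, ], dose_max = 1e-9), pan,
      rule_config(rule = rule, k = 1))
    expect_identical(res_lo$predicted, 0L)
    expect_identical(res_lo$score, 0)
  }
})

test_that("batch prediction preserves order and reports agreement", {
  tab <- small_table()
  pan <- oracle_panel(fixture_spec(25L, 101L))
  res <- predict_batch(tab, pan, rule_config(rule = "OR", k = 1))
  expect_identical(length(res), nrow(tab))
  df <- as.data.frame(res)
  expect_identical(df$name, tab$name)
  expect_true(all(df$agrees))  # oracle models reproduce the planted labels
  # absent dose_max without a fallback is an error; expected_dose rescues it
  rec <- transform(tab[1, ], dose_max = NA_real_)
  expect_error(predict_compound(rec, pan, rule_config()), "no exposure")
  res1 <- predict_compound(rec, pan, rule_config(), expected_dose = 100)
  expect_true(res1$predicted %in% c(0L, 1L))
})

test_that("metrics equal an independent brute-force implementation", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    yhat <- rbinom(n, 1, 0.5)
    score <- sample(c(runif(n), round(runif(n), 1)), n)  # with ties
    df <- data.frame(activity = y, predicted_activity = yhat, score = score)
    m <- evaluate(df)
    o <- brute_force_metrics(y, yhat, score)
    expect_identical(m$confusion, o$confusion)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$mcc, o$mcc)
    expect_equal(m$auc, o$auc)
  }
})

test_that("a perfect classifier scores perfectly and label-free AUC is null", {
  y <- c(0, 0, 1, 1, 1, 0)
  df <- data.frame(activity = y, predicted_activity = y, score = y)
  m <- evaluate(df)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$auc, 1)
  # scores independent of labels: AUC near 1/2 by the rank statistic
  set.seed(12)
  n <- 4000
  y <- rbinom(n, 1, 0.5)
  score <- runif(n)
  m2 <- evaluate(data.frame(activity = y, predicted_activity = y,
                            score = score))
  expect_lt(abs(m2$auc - 0.5), 3 / sqrt(n))  # binomial-scale sampling error
})

test_that("one-class evaluations flag AUC and MCC as undefined", {
  df <- data.frame(activity = c(1, 1, 1), predicted_activity = c(1, 0, 1),
                   score = c(0.9, 0.2, 0.8))
  m <- evaluate(df)
  expect_true(is.na(m$auc))
  expect_true(is.na(m$mcc))
  expect_false(m$both_classes)
  expect_equal(m$sensitivity, 2 / 3)
  expect_error(evaluate(data.frame(activity = NA_integer_,
                                   predicted_activity = 1, score = 1)),
               "no results")
})
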