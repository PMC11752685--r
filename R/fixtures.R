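# Synthetic data generation. Stands in for a real labelled reference set:
# compound tables with pharmacokinetic fields and cholestasis labels, and
# per-transporter IC50 training tables carrying a planted
# structure-activity signal, all fully reproducible under a seed and
# generated offline from the package's embedded drug SMILES library.
#
# Variance decomposition of the planted pIC50: the linear signal component
# is scaled to variance signal_strength * V0 over the SMILES library and
# Gaussian noise with sd noise_sd (default sqrt((1 - signal_strength) * V0))
# is added, with V0 = 1.44 pIC50^2 (a realistic ~1.2 log-unit spread). With
# the defaults the planted, recoverable R^2 equals signal_strength.

PLANTED_TOTAL_VARIANCE <- 1.44
# Transporter inhibition is typically weak (tens to hundreds of micromolar);
# centring planted pIC50 at 3.5 (~300 uM) also yields balanced labels under
# the OR generative rule at the default exposure ranges.
PLANTED_PIC50_MEAN <- 3.5

#' Specification for synthetic fixtures
#'
#' @param n_compounds Number of records/rows to generate, >= 1.
#' @param seed Integer seed (< 2^30); all outputs are deterministic in it.
#' @param fub_range Sampling interval for the unbound fraction, within
#'   (0, 1]; log-uniform.
#' @param clint_range Sampling interval for intrinsic clearance,
#'   uL/min/1e6 cells; log-uniform.
#' @param dose_range Sampling interval for the maximum therapeutic dose,
#'   mg/day; log-uniform.
#' @param signal_strength Fraction of planted pIC50 variance explained by
#'   the descriptor signal, in [0, 1].
#' @param noise_sd Noise standard deviation in pIC50 units; default
#'   `sqrt((1 - signal_strength) * 1.44)` so the planted R^2 equals
#'   `signal_strength`.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 100L, seed = 1L,
                         fub_range = c(0.02, 1), clint_range = c(0.5, 100),
                         dose_range = c(5, 2000), signal_strength = 0.8,
                         noise_sd = NULL) {
  n_compounds <- as.integer(n_compounds)
  if (is.na(n_compounds) || n_compounds < 1L) stop("n_compounds must be >= 1")
  if (fub_range[1] <= 0 || fub_range[2] > 1 || fub_range[1] > fub_range[2]) {
    stop("fub_range must lie within (0, 1]")
  }
  if (clint_range[1] < 0 || clint_range[1] > clint_range[2]) {
    stop("clint_range must be non-negative and ordered")
  }
  if (dose_range[1] <= 0 || dose_range[1] > dose_range[2]) {
    stop("dose_range must be positive and ordered")
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must lie in [0, 1]")
  }
  if (is.null(noise_sd)) {
    noise_sd <- sqrt((1 - signal_strength) * PLANTED_TOTAL_VARIANCE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n_compounds = n_compounds, seed = as.integer(seed),
         fub_range = fub_range, clint_range = clint_range,
         dose_range = dose_range, signal_strength = signal_strength,
         noise_sd = noise_sd),
    class = "fixture_spec"
  )
}

.cholmech_cache <- new.env(parent = emptyenv())

# Feature matrix of the embedded SMILES library, computed once per session.
library_features <- function() {
  if (is.null(.cholmech_cache$lib_features)) {
    smi <- drug_smiles_library()
    .cholmech_cache$lib_features <- featurize(unname(smi))
    .cholmech_cache$lib_smiles <- smi
  }
  .cholmech_cache$lib_features
}

# Planted per-transporter linear pIC50 models. For each transporter a small
# set of descriptor columns (informative fingerprint bits plus the
# physicochemical block) gets standard-normal weights, rescaled so the
# signal variance over the library is signal_strength * V0.
planted_models <- function(spec) {
  feats <- library_features()
  nbit <- N_FP_BITS
  freq <- colMeans(feats[, seq_len(nbit), drop = FALSE])
  informative_bits <- which(freq >= 0.2 & freq <= 0.8)
  phys_cols <- nbit + seq_along(PHYSCHEM_NAMES)
  lib_mean <- colMeans(feats)
  lib_sd <- apply(feats, 2, stats::sd)
  lib_sd[lib_sd == 0] <- 1

  set.seed((spec$seed + 104729L) %% .Machine$integer.max)
  lapply(stats::setNames(nm = panel_transporters()), function(t) {
    cols <- c(sample(informative_bits, 8L), phys_cols)
    w <- stats::rnorm(length(cols))
    z <- scale(feats[, cols, drop = FALSE], center = lib_mean[cols],
               scale = lib_sd[cols])
    s <- as.numeric(z %*% w)
    target_sd <- sqrt(spec$signal_strength * PLANTED_TOTAL_VARIANCE)
    factor <- if (stats::sd(s) > 0) target_sd / stats::sd(s) else 0
    list(cols = cols, weights = w * factor, center = lib_mean[cols],
         scale = lib_sd[cols], intercept = PLANTED_PIC50_MEAN)
  })
}

# Noise-free planted pIC50 of a feature matrix under one planted model.
oracle_pic50 <- function(model, features) {
  z <- scale(features[, model$cols, drop = FALSE], center = model$center,
             scale = model$scale)
  model$intercept + as.numeric(z %*% model$weights)
}

#' Oracle IC50 panel for a fixture specification
#'
#' Returns a fitted panel whose estimators reproduce the generator's planted
#' structure-activity functions exactly (noise-free). Running the prediction
#' pipeline with this panel on a table from [generate_compound_table()] of
#' the same spec recovers the planted Activity labels with accuracy 1.
#'
#' @param spec `fixture_spec`.
#' @return Fitted `transporter_panel`.
#' @export
oracle_panel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  models <- planted_models(spec)
  panel <- default_panel()
  for (t in panel$transporters) {
    est <- structure(
      list(transporter = t, algorithm = "oracle", fit = models[[t]],
           keep_columns = integer(0), feature_spec_id = panel$feature_spec_id,
           seed = spec$seed, hyperparameters = list(planted = TRUE),
           n_train = NA_integer_),
      class = "cholmech_estimator"
    )
    panel <- set_estimator(panel, est)
  }
  panel
}

runif_log <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic compound table
#'
#' Samples structures from the embedded drug SMILES library, draws FUB,
#' CLint and maximum dose log-uniformly within the spec's ranges, and
#' assigns the cholestasis Activity label by running the true generative
#' rule: noise-free planted IC50s for all eight transporters, reverse
#' dosimetry under default physiology, and the OR rule at K = 1 against the
#' sampled therapeutic dose. Ground truth is therefore recoverable by
#' construction.
#'
#' @param spec `fixture_spec`.
#' @return `compound_table` with attributes `fixture_spec` and
#'   `planted_ic50` (compounds x transporters matrix, uM).
#' @export
generate_compound_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  models <- planted_models(spec)
  lib <- library_features()
  smi_lib <- .cholmech_cache$lib_smiles
  n <- spec$n_compounds

  set.seed(spec$seed)
  idx <- sample.int(length(smi_lib), n, replace = n > length(smi_lib))
  fub <- runif_log(n, spec$fub_range)
  clint <- runif_log(n, spec$clint_range)
  dose_max <- runif_log(n, spec$dose_range)

  feats <- lib[idx, , drop = FALSE]
  planted_ic50 <- vapply(panel_transporters(), function(t)
    pic50_to_ic50(oracle_pic50(models[[t]], feats)), numeric(n))
  if (n == 1L) planted_ic50 <- matrix(planted_ic50, nrow = 1,
                                      dimnames = list(NULL,
                                                      panel_transporters()))

  bw <- default_physiology()$body_weight
  activity <- vapply(seq_len(n), function(i) {
    params <- build_parameters(list(fub = fub[i], clint = clint[i]))
    mw <- feats[i, "MW"]
    doses <- qivive_dose(planted_ic50[i, ], mw, params)  # K = 1
    as.integer(any(dose_max[i] / bw > doses))            # OR rule, strict
  }, integer(1))

  tab <- compound_table(
    name = sprintf("%s_%03d", names(smi_lib)[idx], seq_len(n)),
    chembl_id = sprintf("SYN%06d", seq_len(n)),
    smiles = unname(smi_lib[idx]),
    dose_max = dose_max, activity = activity, fub = fub, clint = clint
  )
  attr(tab, "source") <- "synthetic"
  attr(tab, "fixture_spec") <- spec
  attr(tab, "planted_ic50") <- planted_ic50
  tab
}

#' Generate a synthetic IC50 training table for one transporter
#'
#' Samples structures from the embedded library and emits measured-style
#' IC50 values: the transporter's planted linear pIC50 signal plus Gaussian
#' noise (sd `spec$noise_sd`), back-transformed to micromolar.
#'
#' @param spec `fixture_spec`; `n_compounds` rows are drawn.
#' @param transporter Panel member name.
#' @return data.frame with columns `smiles` and `ic50_uM`, plus attribute
#'   `pic50` (the noisy targets on the log scale).
#' @export
generate_ic50_training_set <- function(spec, transporter) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!transporter %in% panel_transporters()) {
    stop(sprintf("unknown transporter '%s'", transporter))
  }
  models <- planted_models(spec)
  lib <- library_features()
  smi_lib <- .cholmech_cache$lib_smiles
  t_idx <- match(transporter, panel_transporters())

  set.seed((spec$seed + 1000L * t_idx) %% .Machine$integer.max)
  n <- spec$n_compounds
  idx <- sample.int(length(smi_lib), n, replace = n > length(smi_lib))
  feats <- lib[idx, , drop = FALSE]
  pic50 <- oracle_pic50(models[[transporter]], feats) +
    stats::rnorm(n, sd = spec$noise_sd)
  out <- data.frame(smiles = unname(smi_lib[idx]),
                    ic50_uM = pic50_to_ic50(pic50),
                    stringsAsFactors = FALSE)
  attr(out, "pic50") <- pic50
  attr(out, "transporter") <- transporter
  out
}
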