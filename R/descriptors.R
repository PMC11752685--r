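# Molecular featurization: canonical SMILES handling, molecular weight, and
# the fixed-length descriptor vector consumed by the transporter QSAR panel.
#
# The recipe is a 1024-bit OpenBabel FP2 linear-fragment fingerprint
# concatenated with a small physicochemical block. It is identified by a
# feature_spec_id tag so that trained models can refuse feature vectors
# produced under a different recipe.

#' @importFrom ChemmineOB forEachMol prop_OB fingerprint_OB
NULL

PHYSCHEM_NAMES <- c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2", "MR")
N_FP_BITS <- 1024L

#' Identifier of the current featurization recipe
#'
#' A tag stamped into every trained model and checked at prediction time.
#' Models trained under one recipe cannot silently consume vectors from
#' another.
#'
#' @return Character scalar.
#' @export
feature_spec_id <- function() "fp2-1024+physchem7/v1"

#' Length of the feature vector produced by the current recipe
#' @return Integer scalar.
#' @export
feature_length <- function() N_FP_BITS + length(PHYSCHEM_NAMES)

# Parse one SMILES with OpenBabel; returns list(props=1-row data.frame,
# fp=numeric(1024)) or signals a classed error naming the offending string.
ob_parse <- function(smiles, want_fp = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop(invalid_smiles_error(smiles))
  }
  res <- tryCatch(
    forEachMol("SMILES", trimws(smiles), function(mol) {
      p <- prop_OB(mol)
      fp <- if (want_fp) as.numeric(fingerprint_OB(list(mol), "FP2")) else NULL
      list(props = p, fp = fp)
    }),
    error = function(e) NULL
  )
  if (is.null(res) || length(res) != 1L || !is.finite(res[[1]]$props$MW) ||
      res[[1]]$props$MW <= 0) {
    stop(invalid_smiles_error(smiles))
  }
  res[[1]]
}

invalid_smiles_error <- function(smiles) {
  structure(
    class = c("cholmech_invalid_smiles", "error", "condition"),
    list(message = sprintf("invalid SMILES: '%s'", as.character(smiles)[1]),
         call = NULL, smiles = smiles)
  )
}

# Count heavy (non-hydrogen) atoms from a Hill formula such as "C9H8O4".
heavy_atom_count <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?\\d*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  n <- 0L
  for (tok in toks) {
    el <- gsub("\\d", "", tok)
    cnt <- suppressWarnings(as.integer(gsub("\\D", "", tok)))
    if (is.na(cnt)) cnt <- 1L
    if (!identical(el, "H")) n <- n + cnt
  }
  n
}

# Keep the largest organic fragment of a dotted (salt/mixture) SMILES:
# most carbon atoms, ties broken by molecular weight.
largest_fragment <- function(cansmi) {
  frags <- strsplit(cansmi, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1L) return(cansmi)
  score <- vapply(frags, function(f) {
    p <- tryCatch(ob_parse(f, want_fp = FALSE)$props, error = function(e) NULL)
    if (is.null(p)) return(c(-1, -1))
    formula <- p$formula
    m <- regmatches(formula, regexpr("C(?![a-z])\\d*", formula, perl = TRUE))
    ncarbon <- if (length(m) == 0) 0L else {
      d <- gsub("\\D", "", m)
      if (nzchar(d)) as.integer(d) else 1L
    }
    c(ncarbon, p$MW)
  }, numeric(2))
  frags[order(score[1, ], score[2, ], decreasing = TRUE)[1]]
}

#' Canonical SMILES
#'
#' Canonicalizes a SMILES string with OpenBabel so that equivalent spellings
#' of one molecule map to a single representation. Salts and mixtures are
#' reduced to their largest organic fragment first.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strip_salts Keep only the largest organic fragment (default TRUE).
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles, strip_salts = TRUE) {
  vapply(smiles, function(s) {
    can <- ob_parse(s, want_fp = FALSE)$props$cansmi
    can <- trimws(can)
    if (strip_salts) can <- largest_fragment(can)
    can
  }, character(1), USE.NAMES = FALSE)
}

#' Molecular weight from SMILES
#'
#' Average molecular weight in g/mol including implicit hydrogens, from
#' standard atomic masses.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric vector, g/mol.
#' @examples
#' molecular_weight("CCO")  # ethanol, 46.07
#' @export
molecular_weight <- function(smiles) {
  vapply(smiles, function(s) ob_parse(s, want_fp = FALSE)$props$MW,
         numeric(1), USE.NAMES = FALSE)
}

#' Validate SMILES strings
#'
#' @param smiles Character vector.
#' @return Logical vector: TRUE where the string parses to a molecule with at
#'   least one heavy atom.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    p <- tryCatch(ob_parse(s, want_fp = FALSE)$props, error = function(e) NULL)
    !is.null(p) && heavy_atom_count(p$formula) >= 1L
  }, logical(1), USE.NAMES = FALSE)
}

#' Featurize molecules for the QSAR panel
#'
#' Converts SMILES to the fixed-length numeric descriptor vector used by all
#' transporter models: a 1024-bit FP2 fingerprint plus a physicochemical
#' block (molecular weight, logP estimate, topological polar surface area,
#' H-bond donor and acceptor counts, molar refractivity). The input is
#' canonicalized (and salt-stripped) first, so equivalent SMILES spellings
#' produce identical vectors.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric matrix with one row per molecule, `feature_length()`
#'   columns, and attribute `feature_spec_id`. No non-finite entries.
#' @export
featurize <- function(smiles) {
  can <- canonical_smiles(smiles)
  rows <- lapply(can, function(s) {
    parsed <- ob_parse(s, want_fp = TRUE)
    phys <- unlist(parsed$props[PHYSCHEM_NAMES])
    v <- c(parsed$fp, phys)
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite descriptor value for SMILES '%s'", s))
    }
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("fp", seq_len(N_FP_BITS)), PHYSCHEM_NAMES)
  rownames(m) <- NULL
  attr(m, "feature_spec_id") <- feature_spec_id()
  m
}
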