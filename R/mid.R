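#' Mass-isotopologue distribution (MID) vectors
#'
#' A MID holds the fractional abundances `M0..Mn` of a metabolite's mass
#' shifts, where `Mi` is the fraction of molecules carrying `i` heavy
#' carbons. Fractions are nonnegative and sum to 1; the vector has
#' `n_carbons + 1` entries indexed by mass shift starting at `M0`
#' (unlabeled).
#'
#' @param fractions numeric vector of isotopologue fractions, `M0` first.
#' @param metabolite metabolite name (optional; used for carbon-count
#'   lookup in the registry when `n_carbons` is missing).
#' @param n_carbons number of skeleton carbons; defaults to
#'   `length(fractions) - 1`.
#' @param tol tolerance on the unit-sum check.
#' @return an object of class `"mid"`.
#' @examples
#' m <- mid_vector(c(0.7, 0.2, 0.1), metabolite = "acetyl_coa")
#' enrichment(m)
#' @export
mid_vector <- function(fractions, metabolite = NA_character_,
                       n_carbons = length(fractions) - 1L, tol = 1e-6) {
  fractions <- as.numeric(fractions)
  x <- structure(
    list(metabolite = as.character(metabolite),
         n_carbons = as.integer(n_carbons),
         fractions = fractions),
    class = "mid"
  )
  validate_mid(x, tol = tol)
  x
}

#' Validate a MID vector
#'
#' Checks nonnegativity, unit sum (within `tol`) and length
#' `n_carbons + 1`.
#'
#' @param mid an object of class `"mid"`.
#' @param tol tolerance on the unit-sum check.
#' @return `mid`, invisibly, if valid; otherwise a validation error.
#' @export
validate_mid <- function(mid, tol = 1e-6) {
  if (!inherits(mid, "mid")) stop_validation("not a 'mid' object")
  f <- mid$fractions
  if (length(f) != mid$n_carbons + 1L)
    stop_validation(sprintf(
      "MID for %s has %d entries but needs n_carbons + 1 = %d",
      mid$metabolite, length(f), mid$n_carbons + 1L))
  if (any(!is.finite(f)) || any(f < -tol))
    stop_validation("MID fractions must be finite and nonnegative")
  s <- sum(f)
  if (abs(s - 1) > tol)
    stop_validation(sprintf("MID fractions sum to %.8f, not 1", s))
  invisible(mid)
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("MID: %s (%d carbons)\n", x$metabolite, x$n_carbons))
  v <- round(x$fractions, 4)
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(v)
  invisible(x)
}

#' @export
as.numeric.mid <- function(x, ...) x$fractions

#' Summarize a MID into a scalar enrichment
#'
#' `atom_fraction` is the average fraction of labeled carbon atoms,
#' \eqn{\sum_i (i/n) M_i}; `labeled_fraction` is the fraction of molecules
#' carrying any label, \eqn{1 - M_0}. `atom_fraction` is the default
#' because a flux-slope interpretation needs a pool-average label measure;
#' `labeled_fraction` is kept for sensitivity analyses.
#'
#' @param mid an object of class `"mid"`.
#' @param mode `"atom_fraction"` (default) or `"labeled_fraction"`.
#' @return a fraction in \[0, 1\].
#' @export
enrichment <- function(mid, mode = c("atom_fraction", "labeled_fraction")) {
  validate_mid(mid)
  mode <- match.arg(mode)
  n <- mid$n_carbons
  if (n == 0L) stop_domain("enrichment undefined for a 0-carbon metabolite")
  f <- pmax(mid$fractions, 0)
  if (mode == "atom_fraction") {
    sum((seq_along(f) - 1L) / n * f)
  } else {
    1 - f[1L]
  }
}

#' Extract a single isotopologue fraction
#'
#' @param mid an object of class `"mid"`.
#' @param shift integer mass shift (0 = unlabeled `M0`).
#' @return the fraction `M_shift`.
#' @export
isotopologue_fraction <- function(mid, shift) {
  validate_mid(mid)
  shift <- as.integer(shift)
  if (length(shift) != 1L || is.na(shift) || shift < 0L ||
      shift > mid$n_carbons)
    stop_index(sprintf("mass shift %s outside 0..%d",
                       paste(shift, collapse = ","), mid$n_carbons))
  mid$fractions[shift + 1L]
}

#' Metabolite registry
#'
#' Carbon counts and the LC-MS/MS multiple-reaction-monitoring (MRM)
#' transitions (precursor/product m/z, negative-ion mode) used to quantify
#' each analyte, for channel labeling of simulator output and file readers.
#'
#' @return a data.frame with columns `metabolite`, `n_carbons`,
#'   `mrm_precursor_mz`, `mrm_product_mz` (`NA` where no transition is
#'   defined).
#' @export
metabolite_registry <- function() {
  data.frame(
    metabolite = c("citrate", "glutamate", "malate", "succinate",
                   "pyruvate", "alpha_ketoglutarate", "acetyl_coa",
                   "oxaloacetate", "glucose", "glutamine", "palmitate",
                   "lactate"),
    n_carbons = c(6L, 5L, 4L, 4L, 3L, 5L, 2L, 4L, 6L, 5L, 16L, 3L),
    mrm_precursor_mz = c(191, 146, 133, 117, NA, NA, NA, NA, NA, NA, NA, NA),
    mrm_product_mz   = c(173, 128, 115,  99, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# carbon count lookup; errors on unknown metabolite
carbon_count <- function(metabolite) {
  reg <- metabolite_registry()
  i <- match(metabolite, reg$metabolite)
  if (is.na(i)) stop_lookup(sprintf("unknown metabolite '%s'", metabolite))
  reg$n_carbons[i]
}
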