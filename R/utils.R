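#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used for all printed percentages
#' in this package. Base R's `round()` rounds half to even, which turns
#' 97.25 into 97.2; trait-occurrence tables instead print 97.3.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.25), 0:1 * 0) # 1 2 2
#' round_half_up(100 * 249 / 256, 1) # 97.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against binary representation of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count within a total
#'
#' @param n_positive Count of positives.
#' @param n_total Group size. A zero total yields `NA` (flagged, not divided).
#' @param decimals Decimal places, round-half-up.
#' @return Numeric vector of percentages on the 0-100 scale.
#' @examples
#' percent_of(249, 256) # 97.3
#' percent_of(3269, 3683) # 88.8
#' @export
percent_of <- function(n_positive, n_total, decimals = 1) {
  out <- rep(NA_real_, length(n_total))
  ok <- !is.na(n_total) & n_total > 0
  out[ok] <- round_half_up(100 * n_positive[ok] / n_total[ok], decimals)
  out
}

# closed vocabularies shared by iocore and syndata
kingdom_levels <- function() c("archaea", "bacteria", "eukaryota")
habitat_levels <- function() {
  c("host-associated", "aquatic", "terrestrial", "multiple", "specialized",
    "unknown")
}
oxygen_levels <- function() {
  c("anaerobic", "facultative", "microaerophilic", "aerobic", "unknown")
}
category_levels <- function() c("both", "moco_only", "nif_only", "none")

# organism id embedded as "<organism>|p<k>" in synthetic protein ids
organism_from_protein <- function(protein_id) {
  ifelse(grepl("|", protein_id, fixed = TRUE),
         sub("\\|.*$", "", protein_id),
         NA_character_)
}

check_probabilities <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s must be probabilities in [0, 1]", what))
  }
  invisible(p)
}

check_weights <- function(w, what) {
  check_probabilities(w, what)
  if (abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("%s must sum to 1 (got %.12f)", what, sum(w)))
  }
  invisible(w)
}

# exact integer allocation of n among weights (largest-remainder method);
# keeps per-category sample sizes deterministic under stratified assignment
allocate_counts <- function(n, weights) {
  check_weights(weights, "weights")
  raw <- n * weights
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}
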