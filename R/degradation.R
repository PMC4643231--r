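# Random-degradation survival model: a DNA target of x bases survives
# postmortem chain scission with probability exp(-lambda * x), where lambda
# is the per-bond scission probability set by the sample's thermal age.
# Applying this survival to a starting community predicts the taxon
# frequency skew observed in amplicon data from degraded samples.

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam >= 1)
    stop("lambda must be a single value in [0, 1)")
  lam
}

#' Survival probability of an x-base target under random degradation
#'
#' `exp(-lambda * x)`: the probability that a template of length `x` or
#' greater is still present after degradation at per-bond scission
#' probability `lambda`.
#'
#' @param lam per-bond scission probability, `0 <= lam < 1`.
#' @param x target length in bases, `x >= 0` (vectorized).
#' @return survival probabilities.
#' @export
#' @examples
#' survival_probability(0.0006, 183)
survival_probability <- function(lam, x) {
  check_lambda(lam)
  if (any(x < 0)) stop("negative target length")
  exp(-lam * x)
}

#' Predict the degraded (observed) community profile
#'
#' Reweights a starting community by per-taxon survival and renormalizes:
#' `f'_i = f_i * exp(-lambda * x_i) / sum_j f_j * exp(-lambda * x_j)`.
#' Weights are computed in log space with max-subtraction so that large
#' `lambda * x` (up to ~17 for the site/amplicon ranges considered here)
#' cannot underflow.  Taxa with `f_i = 0` stay 0.
#'
#' @param profile named numeric community profile (non-negative weights; it
#'   is normalized internally, so unnormalized inputs are accepted).
#' @param lengths named numeric vector of primer-inclusive amplicon lengths
#'   `x_i >= 1`; every taxon in `profile` must be present.
#' @param lam per-bond scission probability.
#' @return data.frame (`taxon`, `f_in`, `length`, `f_pred`) with
#'   `attr(, "lambda")`; `f_pred` sums to 1.
#' @export
#' @examples
#' predict_observed_profile(c(a = 0.5, b = 0.5), c(a = 151, b = 194), 0.01)
predict_observed_profile <- function(profile, lengths, lam) {
  check_lambda(lam)
  f <- normalize_profile(profile)
  missing <- setdiff(names(f), names(lengths))
  if (length(missing) > 0)
    stop("no amplicon length for taxon: ", paste(missing, collapse = ", "))
  x <- lengths[names(f)]
  if (any(x < 1)) stop("amplicon lengths must be >= 1")
  logw <- ifelse(f > 0, log(f) - lam * x, -Inf)
  if (all(is.infinite(logw)))
    stop("all survival weights are zero; compute in log space")
  logw <- logw - max(logw)
  w <- exp(logw)
  data.frame(taxon = names(f), f_in = unname(f), length = unname(x),
             f_pred = unname(w / sum(w)), stringsAsFactors = FALSE) |>
    structure(lambda = lam)
}

#' Frequency predictions across a series of degradation intensities
#'
#' One prediction per lambda (e.g. the thermal-age series of a set of
#' archaeological sites), rows ordered as given.
#'
#' @inheritParams predict_observed_profile
#' @param lams numeric vector of per-bond scission probabilities.
#' @param labels optional labels for each lambda (e.g. site names).
#' @return long data.frame (`label`, `lambda`, `taxon`, `f_in`, `length`,
#'   `f_pred`).
#' @export
thermal_series <- function(profile, lengths, lams, labels = NULL) {
  if (length(lams) == 0) stop("empty lambda list")
  if (is.null(labels)) labels <- format(lams)
  stopifnot(length(labels) == length(lams))
  out <- lapply(seq_along(lams), function(i) {
    pred <- predict_observed_profile(profile, lengths, lams[i])
    cbind(label = labels[i], lambda = lams[i], pred)
  })
  do.call(rbind, out)
}

#' Empirical amplifiable fraction of a fragment-length multiset
#'
#' Fractions of fragments at least `x_max` and at least `x_min` long — the
#' template fractions available for the longest and shortest variants of a
#' length-polymorphic amplicon target.
#'
#' @param lengths fragment lengths (non-empty).
#' @param x_min,x_max target length bounds, `x_min <= x_max`.
#' @return named numeric `c(frac_ge_xmax, frac_ge_xmin)`.
#' @export
#' @examples
#' amplifiable_fraction_empirical(c(100, 150, 200, 250), 150, 194)
amplifiable_fraction_empirical <- function(lengths, x_min, x_max) {
  if (length(lengths) == 0) stop("empty input")
  if (x_min > x_max) stop("x_min must be <= x_max")
  c(frac_ge_xmax = mean(lengths >= x_max),
    frac_ge_xmin = mean(lengths >= x_min))
}

#' Summary statistics of a fragment-length multiset
#'
#' Median and quartiles use the lower-median / nearest-rank (type-1
#' quantile) rule, so integer-valued inputs give integer-valued statistics.
#'
#' @param lengths fragment lengths (non-empty).
#' @param thresholds lengths at which to report the fraction of fragments
#'   at least that long (defaults to the 150/194 bounds of the V3 target).
#' @return list with `n`, `median`, `q1`, `q3` and named `frac_ge`
#'   fractions.
#' @export
fragment_stats <- function(lengths, thresholds = c(150, 194)) {
  if (length(lengths) == 0) stop("empty input")
  list(n = length(lengths),
       median = median_lower(lengths),
       q1 = quantile_nearest_rank(lengths, 0.25),
       q3 = quantile_nearest_rank(lengths, 0.75),
       frac_ge = setNames(vapply(thresholds, function(t) mean(lengths >= t),
                                 numeric(1)),
                          paste0("ge_", thresholds)))
}

#' Estimate the per-bond scission probability from fragment lengths
#'
#' The exponential-approximation moment estimator `1 / mean(length)`.
#' Fragments from finite templates make this estimator biased upward by
#' boundary effects (each template contributes one extra, break-free
#' fragment end), appreciable when `lambda * template_length` is below
#' about 3.  Supplying `template_length` switches to the exact break-count
#' estimator `(n_fragments - n_templates) / n_bonds`, which removes the
#' boundary bias; it requires unfiltered fragments (`min_len = 1`) that
#' partition their templates.
#'
#' @param lengths fragment lengths (`n >= 2`, mean > 1).
#' @param template_length optional original template length for the
#'   boundary-corrected estimator.
#' @return estimated lambda.
#' @export
estimate_lambda <- function(lengths, template_length = NULL) {
  if (length(lengths) < 2) stop("need at least two fragments")
  m <- mean(lengths)
  if (m <= 1) stop("mean fragment length must exceed 1")
  if (is.null(template_length)) return(1 / m)
  stopifnot(template_length > 1)
  n_templates <- sum(lengths) / template_length
  if (abs(n_templates - round(n_templates)) > 1e-6)
    stop("fragment lengths do not partition whole templates; ",
         "use min_len = 1 fragments or omit template_length")
  n_templates <- round(n_templates)
  (length(lengths) - n_templates) / (n_templates * (template_length - 1))
}

#' Packaged per-site scission probabilities
#'
#' Literature-derived thermal-age scission probabilities (lambda, per bond)
#' for seven archaeological sites, shipped as a TSV under `extdata`.
#' Thermal-age-to-lambda conversion itself (climate modelling) is out of
#' scope; these values are inputs.
#'
#' @return data.frame (`site`, `region`, `period`, `lambda`).
#' @export
site_lambda_table <- function() {
  read.delim(system.file("extdata", "site_lambdas.tsv", package = "paleoamp",
                         mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Packaged V3 amplicon lengths and baseline abundances for oral taxa
#'
#' Literature-derived predicted V3 (U341F/534R) primer-inclusive amplicon
#' lengths and baseline oral rank abundances (HOMD-style, percent) for a
#' panel of oral microbiome taxa of interest; abundance is `NA` where the
#' baseline database could not quantify the taxon.
#'
#' @return data.frame (`taxon`, `domain`, `category`, `v3_length_bp`,
#'   `homd_abundance_pct`).
#' @export
oral_taxon_table <- function() {
  read.delim(system.file("extdata", "oral_taxa_v3.tsv", package = "paleoamp",
                         mustWork = TRUE), stringsAsFactors = FALSE)
}
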