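# Community-profile classification and amplicon-versus-shotgun comparison
# metrics.

canon_label <- function(x) tolower(trimws(x))

#' Classify a genus-level profile into oral and other fractions
#'
#' A genus is "oral" iff it appears in the supplied membership list (e.g. an
#' oral microbiome database genus list); matching is exact after whitespace
#' trimming and case folding — no fuzzy matching.  Genera absent from the
#' list are "Other" by definition.
#'
#' @param profile named numeric genus-level community profile (normalized
#'   internally).
#' @param membership character vector of genus labels designated oral.
#' @return list with `oral_fraction`, `other_fraction` (summing to 1) and
#'   per-genus logical `flags`.
#' @export
classify_oral <- function(profile, membership) {
  f <- normalize_profile(profile)
  flags <- canon_label(names(f)) %in% canon_label(membership)
  oral <- sum(f[flags])
  list(oral_fraction = oral, other_fraction = 1 - oral,
       flags = setNames(flags, names(f)))
}

#' Summed frequency of archaeal taxa in a profile
#'
#' @param profile named numeric community profile (normalized internally).
#' @param lineages data.frame mapping `taxon` to `domain` (and optionally
#'   `phylum`); taxa without a lineage row count as non-archaeal.
#' @param phylum optional phylum label restricting the sum (e.g.
#'   `"Euryarchaeota"`).
#' @return summed relative frequency of archaeal taxa.
#' @export
archaeal_fraction <- function(profile, lineages, phylum = NULL) {
  stopifnot(is.data.frame(lineages), all(c("taxon", "domain") %in%
                                           names(lineages)))
  f <- normalize_profile(profile)
  idx <- match(canon_label(names(f)), canon_label(lineages$taxon))
  is_arch <- !is.na(idx) & canon_label(lineages$domain[idx]) == "archaea"
  if (!is.null(phylum)) {
    if (!"phylum" %in% names(lineages))
      stop("lineages lack a phylum column")
    is_arch <- is_arch &
      canon_label(lineages$phylum[idx]) == canon_label(phylum)
    is_arch[is.na(is_arch)] <- FALSE
  }
  sum(f[is_arch])
}

#' Per-taxon log2 fold change between amplicon and shotgun profiles
#'
#' Taxa are aligned by label union (a taxon absent from one profile has
#' frequency 0 there) and compared as
#' `LFC_i = log2((f_amp_i + eps) / (f_shot_i + eps))`.  The symmetric
#' pseudo-frequency `eps` keeps fold changes finite for dropout taxa —
#' amplification dropout being the phenomenon under study.  "Log fold
#' change" is base 2 throughout.
#'
#' @param p_amp,p_shot named numeric profiles (normalized internally).
#' @param epsilon pseudo-frequency, `> 0` (default 1e-6).
#' @return data.frame (`taxon`, `f_amplicon`, `f_shotgun`, `lfc`) with
#'   `attr(, "epsilon")`.
#' @export
#' @examples
#' compare_amplicon_shotgun(c(a = 0.7, b = 0.3), c(a = 0.5, b = 0.5))
compare_amplicon_shotgun <- function(p_amp, p_shot, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive value")
  a <- normalize_profile(p_amp)
  s <- normalize_profile(p_shot)
  taxa <- union(names(a), names(s))
  fa <- ifelse(taxa %in% names(a), a[taxa], 0)
  fs <- ifelse(taxa %in% names(s), s[taxa], 0)
  data.frame(taxon = taxa, f_amplicon = unname(fa), f_shotgun = unname(fs),
             lfc = log2((fa + epsilon) / (fs + epsilon)),
             row.names = NULL, stringsAsFactors = FALSE) |>
    structure(epsilon = epsilon)
}

#' Spearman rank correlation between two per-sample vectors
#'
#' Average ranks for ties; the coefficient only (no test).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 paired values")
  cor(x, y, method = "spearman")
}
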