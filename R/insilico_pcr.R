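# In-silico PCR: weighted-penalty primer-binding scoring, binding-site
# search, primer-inclusive amplicon extraction, and the three primer quality
# metrics (length variation, taxonomic coverage, taxonomic resolution).
#
# Penalty scheme (weighted sum over the best <=1-gap alignment):
#   non-3' mismatch       0.40 each
#   3' mismatch           1.00 each (any of the last 5 primer bases except
#                                    the final base)
#   final-base mismatch   3.00
#   non-3' gap            1.00 each
#   3' gap                3.00 each
# An alignment passes iff its score is <= 1.00.

PASS_THRESHOLD <- 1.00

# Mismatch class per primer position (primer orientation, 1-based):
# 0 non-3', 1 within the 5-base 3' window but not final, 2 final base.
mm_classes <- function(L) {
  cls <- rep(0L, L)
  cls[seq.int(max(1L, L - 4L), L)] <- 1L
  cls[L] <- 2L
  cls
}

# Gap class for a primer base aligned to a gap (deletion in the target):
# 3' iff the primer position is within the last 5.
del_classes <- function(L) as.integer(seq_len(L) >= L - 4L)

# Gap class for a target base inserted between primer positions g and g+1
# (g = 1..L-1): 3' iff the insertion interrupts the last-5 block.
ins_classes <- function(L) as.integer(seq_len(L - 1L) >= L - 4L)

primer_seq <- function(p) if (inherits(p, "primer")) p$sequence else toupper(p)

new_primer_match <- function(hit, strand) {
  structure(list(
    target_start = hit$start, target_end = hit$end, strand = strand,
    score = hit$score,
    breakdown = c(mm_non3 = hit$mm_non3, mm_3p = hit$mm_3p,
                  mm_last = hit$mm_last, gap_non3 = hit$gap_non3,
                  gap_3p = hit$gap_3p),
    passed = hit$score <= PASS_THRESHOLD + 1e-9), class = "primer_match")
}

#' Score a primer against a candidate binding window
#'
#' Returns the minimum weighted penalty over all alignments of the primer to
#' the window with at most one gap (two or more gaps can never pass, so the
#' search is capped there).  The window must be within one base of the
#' primer length.  Degenerate primer bases match a target base iff their
#' IUPAC sets intersect; a target `N` never matches.
#'
#' @param primer a `primer` object or IUPAC string (scored in primer
#'   orientation).
#' @param window nucleotide string of length `nchar(primer) +/- 1`.
#' @return list with `score`, `breakdown` (counts of non-3' mismatches, 3'
#'   mismatches, last-base mismatches, non-3' gaps, 3' gaps) and `passed`
#'   (`score <= 1.00`).
#' @export
#' @examples
#' p <- "ACGTACGTACGT"
#' score_primer_alignment(p, p)$score  # 0, perfect match
score_primer_alignment <- function(primer, window) {
  ps <- primer_seq(primer)
  L <- nchar(ps)
  m <- nchar(window)
  if (m < L - 1L || m > L + 1L)
    stop("window length must be within one base of the primer length")
  hit <- cpp_score_window(seq_to_masks(ps), seq_to_masks(window, target = TRUE),
                          mm_classes(L), del_classes(L), ins_classes(L))
  list(score = hit$score,
       breakdown = c(mm_non3 = hit$mm_non3, mm_3p = hit$mm_3p,
                     mm_last = hit$mm_last, gap_non3 = hit$gap_non3,
                     gap_3p = hit$gap_3p),
       passed = hit$score <= PASS_THRESHOLD + 1e-9)
}

#' Find the best passing primer binding site on a sense-strand sequence
#'
#' For a forward-orientation search the primer is scanned directly; for a
#' reverse-orientation search its reverse complement is scanned on the sense
#' strand with the 3' penalty window mapped accordingly (the primer's 3' end
#' faces left on the sense strand).  Among equal-score passing sites the
#' lowest start is kept for forward primers and the highest for reverse,
#' which maximizes the canonical amplicon.
#'
#' @param primer a `primer` object or IUPAC string.
#' @param sequence sense-strand nucleotide string (a reference record's
#'   sequence).
#' @param orientation `"forward"` or `"reverse"`; defaults to the primer's
#'   role if it is a `primer` object.
#' @return a `primer_match` (0-based half-open `target_start`/`target_end`,
#'   `score`, penalty `breakdown`, `passed`) or `NULL` when no site passes.
#' @export
find_best_site <- function(primer, sequence,
                           orientation = c("forward", "reverse")) {
  if (inherits(primer, "primer") && missing(orientation))
    orientation <- primer$role
  orientation <- match.arg(orientation)
  ps <- primer_seq(primer)
  L <- nchar(ps)
  tgt <- seq_to_masks(sequence, target = TRUE)
  if (orientation == "forward") {
    hit <- cpp_scan_best(seq_to_masks(ps), tgt, mm_classes(L),
                         del_classes(L), ins_classes(L),
                         PASS_THRESHOLD, FALSE)
    strand <- "sense-forward"
  } else {
    # reverse complement pattern: position j corresponds to primer position
    # L - j + 1, so the penalty class vectors are reversed; the insertion
    # junction after pattern position g is the primer junction L - g.
    pat <- seq_to_masks(revcomp_iupac(ps))
    hit <- cpp_scan_best(pat, tgt, rev(mm_classes(L)), rev(del_classes(L)),
                         rev(ins_classes(L)), PASS_THRESHOLD, TRUE)
    strand <- "sense-reverse-complement"
  }
  if (!isTRUE(hit$found)) return(NULL)
  new_primer_match(hit, strand)
}

#' Extract the predicted primer-inclusive amplicon from a record
#'
#' Both primers must pass the 1.00 penalty threshold and the forward site
#' must precede the reverse site on the sense strand.  The amplicon spans
#' the first base of the forward site through the last base of the
#' reverse-complement site (primer inclusive); results longer than
#' `max_len` are discarded.  With `search_revcomp = TRUE` the reverse
#' complement of the record is re-scanned when the sense strand yields no
#' amplicon.
#'
#' @param pair a `primer_pair`.
#' @param sequence sense-strand nucleotide string, or a `reference_db`
#'   record sequence.
#' @param max_len maximum amplicon length retained (default 500, matching
#'   the analysis restriction to amplicons under 500 bp).
#' @param search_revcomp also try the reverse complement of the record.
#' @return list with `amp_start`, `amp_end` (0-based half-open), `length`,
#'   `sequence`, `forward_match`, `reverse_match`; or `NULL`.
#' @export
extract_amplicon <- function(pair, sequence, max_len = 500,
                             search_revcomp = FALSE) {
  stopifnot(inherits(pair, "primer_pair"))
  res <- extract_amplicon_sense(pair, sequence, max_len)
  if (is.null(res) && search_revcomp)
    res <- extract_amplicon_sense(pair, revcomp_iupac(sequence), max_len)
  res
}

extract_amplicon_sense <- function(pair, sequence, max_len) {
  fwd <- find_best_site(pair$forward, sequence, "forward")
  if (is.null(fwd)) return(NULL)
  rev <- find_best_site(pair$reverse, sequence, "reverse")
  if (is.null(rev)) return(NULL)
  if (rev$target_start < fwd$target_end) return(NULL)
  amp_start <- fwd$target_start
  amp_end <- rev$target_end
  x <- amp_end - amp_start
  if (x > max_len) return(NULL)
  list(amp_start = amp_start, amp_end = amp_end, length = x,
       sequence = substr(sequence, amp_start + 1L, amp_end),
       forward_match = fwd, reverse_match = rev)
}

#' Predicted amplicons for every record of a database
#'
#' @param db a `reference_db`.
#' @param pair a `primer_pair`.
#' @param max_len maximum amplicon length retained.
#' @return data.frame with one row per record: `record_id`, `amplified`,
#'   `amp_start`, `amp_end` (0-based half-open), `length`, `sequence`.
#' @export
amplify_database <- function(db, pair, max_len = 500) {
  stopifnot(inherits(db, "reference_db"))
  res <- lapply(db$sequences, function(s) extract_amplicon(pair, s, max_len))
  ok <- !vapply(res, is.null, logical(1))
  pick_int <- function(field) vapply(res, function(r)
    if (is.null(r)) NA_integer_ else as.integer(r[[field]]), integer(1))
  data.frame(
    record_id = names(db$sequences),
    amplified = ok,
    amp_start = pick_int("amp_start"),
    amp_end = pick_int("amp_end"),
    length = pick_int("length"),
    sequence = vapply(res, function(r)
      if (is.null(r)) NA_character_ else r$sequence, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Lower median: for even n the lower of the two central order statistics,
# so integer-valued inputs give integer-valued medians.
median_lower <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty input")
  sort(x)[floor((n + 1) / 2)]
}

# Nearest-rank empirical percentile: the ceiling(p*n)-th order statistic.
quantile_nearest_rank <- function(x, p) {
  n <- length(x)
  if (n == 0) stop("empty input")
  # fuzz guards against p*n landing epsilon above an integer rank
  sort(x)[pmax(1L, ceiling(p * n - 1e-9))]
}

#' Empirical percentile bounds of a length multiset
#'
#' Nearest-rank percentiles at `(1-level)/2` and `1-(1-level)/2`; at the
#' default `level = 0.99` these are the 0.5 and 99.5 percent bounds used to
#' trim outliers (possible chimeras) from amplicon length ranges.
#'
#' @param lengths numeric vector, `n >= 1`.
#' @param level confidence level (default 0.99).
#' @return named numeric `c(low, high)`.
#' @export
length_ci <- function(lengths, level = 0.99) {
  if (length(lengths) == 0) stop("empty input")
  a <- (1 - level) / 2
  c(low = quantile_nearest_rank(lengths, a),
    high = quantile_nearest_rank(lengths, 1 - a))
}

#' Amplicon length distribution summarized by a taxonomic rank
#'
#' Groups predicted amplicon lengths by the value of `rank` and summarizes
#' each group with its size, lower-median length and 99% nearest-rank
#' percentile bounds.  Groups whose records yield no amplicon are reported
#' with `n = 0`.
#'
#' @param db a `reference_db`.
#' @param pair a `primer_pair`.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @param max_len maximum amplicon length retained.
#' @param level percentile level for the bounds.
#' @return data.frame (`group`, `n`, `median`, `ci_low`, `ci_high`) with the
#'   per-group length multisets retained in `attr(, "lengths")`.
#' @export
amplicon_length_distribution <- function(db, pair, rank = "genus",
                                         max_len = 500, level = 0.99) {
  stopifnot(inherits(db, "reference_db"))
  if (!rank %in% RANK_NAMES) stop("unknown rank name: ", rank)
  amps <- amplify_database(db, pair, max_len)
  groups <- db$taxonomy[[rank]]
  out <- lapply(sort(unique(groups)), function(g) {
    len <- amps$length[groups %in% g & amps$amplified]
    if (length(len) == 0)
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    ci <- length_ci(len, level)
    data.frame(group = g, n = length(len),
               median = as.numeric(median_lower(len)),
               ci_low = as.numeric(ci["low"]), ci_high = as.numeric(ci["high"]))
  })
  res <- do.call(rbind, out)
  attr(res, "lengths") <- setNames(
    lapply(res$group, function(g) amps$length[groups %in% g & amps$amplified]),
    res$group)
  res
}

#' Per-phylum taxonomic coverage of a primer pair
#'
#' The fraction of database records in each phylum for which
#' [extract_amplicon()] succeeds.
#'
#' @inheritParams amplicon_length_distribution
#' @return data.frame (`phylum`, `n_total`, `n_amplified`, `fraction`).
#' @export
taxonomic_coverage <- function(db, pair, max_len = 500) {
  stopifnot(inherits(db, "reference_db"))
  amps <- amplify_database(db, pair, max_len)
  phyla <- db$taxonomy$phylum
  out <- lapply(sort(unique(phyla)), function(p) {
    idx <- phyla %in% p
    data.frame(phylum = p, n_total = sum(idx),
               n_amplified = sum(amps$amplified[idx]),
               fraction = sum(amps$amplified[idx]) / sum(idx))
  })
  do.call(rbind, out)
}

# Global-alignment identity: matches / length of the shorter sequence, from
# a unit-cost global alignment (match +1, mismatch -1, gap -1).
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy centroid OTU clustering and taxonomic resolution
#'
#' Approximates greedy de novo OTU clustering at a fixed identity
#' threshold: inputs are processed in canonical order (decreasing length,
#' then lexicographic id), each sequence joins the first existing centroid
#' whose identity to it meets the threshold, else founds a new OTU.
#' Identity is matches divided by the length of the shorter sequence,
#' computed from a unit-cost global alignment.  Exact reproduction of any
#' particular published clusterer's OTU counts is not promised.
#'
#' @param seqs named character vector of sequences (names are ids; unnamed
#'   inputs are numbered).
#' @param threshold identity threshold (default 0.97).
#' @param reference_total optional denominator: the OTU count of a
#'   full-length reference clustering, to express resolution as a fraction.
#' @return list with `n_input`, `n_otus`, `reference_total`,
#'   `resolution_fraction` (or `NA`), and per-input `assignments`.
#' @export
taxonomic_resolution <- function(seqs, threshold = 0.97,
                                 reference_total = NULL) {
  if (length(seqs) == 0) stop("empty input")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%06d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- character(0)
  assignments <- integer(length(seqs))
  for (i in ord) {
    s <- seqs[[i]]
    hit <- 0L
    for (k in seq_along(centroids)) {
      if (alignment_identity(s, centroids[[k]]) >= threshold) { hit <- k; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, s)
      hit <- length(centroids)
    }
    assignments[i] <- hit
  }
  n_otus <- length(centroids)
  list(n_input = length(seqs), n_otus = n_otus,
       reference_total = reference_total,
       resolution_fraction = if (is.null(reference_total)) NA_real_
                             else n_otus / reference_total,
       assignments = setNames(assignments, names(seqs)))
}
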