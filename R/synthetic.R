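# Synthetic 16S reference databases with planted clade-specific V3 length
# polymorphisms, and a forward simulator of community sampling, random aDNA
# fragmentation, amplicon dropout and shotgun sampling.  Makes the whole
# pipeline testable without external downloads.

#' Specify a synthetic clade
#'
#' A clade is a set of records sharing a lineage (through genus), a planted
#' primer-inclusive amplicon length, and a within-clade divergence rate for
#' the variable loop between the primer sites.  An optional primer-site
#' defect supports coverage experiments: `"last_base_mismatch"` plants a
#' final-3'-base mismatch in the forward site (score 3.00, never amplifies);
#' `"non3prime_mismatch"` plants `n_defect_mismatches` mismatches outside
#' the 3' window (0.40 each).
#'
#' @param lineage semicolon lineage through genus, e.g.
#'   `"Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter"`.
#' @param n_otus number of records in the clade (`>= 1`).
#' @param amplicon_length planted primer-inclusive amplicon length (bases);
#'   must be at least the summed primer lengths.
#' @param divergence per-base substitution probability within the variable
#'   loop, in `[0, 0.3]`.
#' @param defect primer-site defect, see above.
#' @param n_defect_mismatches mismatch count for `"non3prime_mismatch"`.
#' @return a `clade_spec` object.
#' @export
clade_spec <- function(lineage, n_otus, amplicon_length, divergence = 0.02,
                       defect = c("none", "last_base_mismatch",
                                  "non3prime_mismatch"),
                       n_defect_mismatches = 3L) {
  defect <- match.arg(defect)
  stopifnot(n_otus >= 1, divergence >= 0, divergence <= 0.3,
            amplicon_length >= 1)
  ranks <- parse_lineage(lineage)
  if (is.na(ranks["genus"]))
    stop("clade lineage must be assigned through genus")
  structure(list(lineage = lineage, ranks = ranks, n_otus = as.integer(n_otus),
                 amplicon_length = as.integer(amplicon_length),
                 divergence = divergence, defect = defect,
                 n_defect_mismatches = as.integer(n_defect_mismatches)),
            class = "clade_spec")
}

clade_genus <- function(clade) unname(clade$ranks["genus"])

# Concrete (unambiguous) realization of an IUPAC string: one base drawn from
# each position's set, so the site matches the primer exactly.
realize_iupac <- function(x) {
  ch <- split_chars(toupper(x))
  paste(vapply(IUPAC_SETS[ch], function(s)
    if (length(s) == 1) s else sample(s, 1), character(1)), collapse = "")
}

# A base guaranteed to mismatch the IUPAC set at one primer position.
mismatching_base <- function(primer_char) {
  out <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[toupper(primer_char)]])
  if (length(out) == 0)
    stop("cannot plant a mismatch against an N primer base")
  sample(out, 1)
}

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

mutate_bases <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- split_chars(seq)
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

#' Generate a synthetic 16S reference database
#'
#' Builds full-length (default 1540 nt) templates in which every record of a
#' clade carries an exact-match forward primer site starting at the pair's
#' anchor position and an exact-match reverse-complement site placed so that
#' the primer-inclusive amplicon length equals the clade's planted length —
#' emulating the clade-structured stem-loop length polymorphisms of the V3
#' region (archaeal clades shortest).  The variable loop between the sites
#' holds a clade consensus mutated per record at the clade's divergence
#' rate; flanks and non-amplicon regions are filled deterministically from
#' the seed and shared across clades (conserved background).  Primer-site
#' defects are applied where specified.
#'
#' @param clades list of [clade_spec()] objects with unique lineages.
#' @param pair the `primer_pair` whose sites are planted.
#' @param template_length template length in bases (default 1540, the
#'   approximate full 16S rRNA gene length).
#' @param seed integer seed; generation is deterministic given
#'   `(clades, pair, template_length, seed)`.
#' @return a `reference_db`.
#' @export
generate_reference_db <- function(clades, pair, template_length = 1540,
                                  seed = 1L) {
  stopifnot(inherits(pair, "primer_pair"), length(clades) >= 1)
  genera <- vapply(clades, clade_genus, character(1))
  if (anyDuplicated(genera)) stop("clade lineages (genera) must be unique")
  lf <- nchar(pair$forward$sequence)
  lr <- nchar(pair$reverse$sequence)
  fwd_start <- pair$ecoli_start  # 1-based first base of the amplicon
  with_seed(seed, {
    background <- random_bases(template_length)
    fwd_site <- realize_iupac(pair$forward$sequence)
    rev_site <- realize_iupac(revcomp_iupac(pair$reverse$sequence))
    sequences <- character(0)
    lineages <- character(0)
    for (clade in clades) {
      x <- clade$amplicon_length
      if (x < lf + lr)
        stop(sprintf("clade %s: amplicon length %d shorter than the summed primer lengths (%d)",
                     clade_genus(clade), x, lf + lr))
      amp_end <- fwd_start + x - 1L  # 1-based last base of the amplicon
      if (amp_end > template_length)
        stop(sprintf("clade %s: amplicon end %d exceeds template length %d",
                     clade_genus(clade), amp_end, template_length))
      loop_len <- x - lf - lr
      consensus <- if (loop_len > 0) random_bases(loop_len) else ""
      site <- fwd_site
      if (clade$defect == "last_base_mismatch") {
        substr(site, lf, lf) <- mismatching_base(
          substr(pair$forward$sequence, lf, lf))
      } else if (clade$defect == "non3prime_mismatch") {
        k <- min(clade$n_defect_mismatches, lf - 5L)
        pos <- sample(seq_len(lf - 5L), k)
        for (p in pos)
          substr(site, p, p) <- mismatching_base(
            substr(pair$forward$sequence, p, p))
      }
      for (i in seq_len(clade$n_otus)) {
        loop <- mutate_bases(consensus, clade$divergence)
        tpl <- background
        substr(tpl, fwd_start, fwd_start + lf - 1L) <- site
        if (loop_len > 0)
          substr(tpl, fwd_start + lf, fwd_start + lf + loop_len - 1L) <- loop
        substr(tpl, amp_end - lr + 1L, amp_end) <- rev_site
        id <- sprintf("%s_%03d", clade_genus(clade), i)
        sequences[id] <- tpl
        lineages[id] <- clade$lineage
      }
    }
    ranks <- t(vapply(lineages, parse_lineage, character(7)))
    taxonomy <- data.frame(record_id = names(sequences), ranks,
                           row.names = NULL, stringsAsFactors = FALSE)
    db <- new_reference_db(sequences, taxonomy)
    attr(db, "template_length") <- as.integer(template_length)
    db
  })
}

#' Draw a pool of intact template molecules from a community
#'
#' Multinomial draw of `n_templates` template copies across the profile's
#' taxa (one 16S copy per template organism — copy-number variation is
#' ignored), then uniformly across each taxon's records.
#'
#' @param profile named numeric community profile; names must be genera
#'   present in `db`.
#' @param db the source `reference_db`.
#' @param n_templates total template copies (`>= 1`).
#' @param seed integer seed.
#' @return a `template_pool`: data.frame (`record_id`, `taxon`, `count`)
#'   with `attr(, "template_length")`.
#' @export
sample_community <- function(profile, db, n_templates, seed = 1L) {
  stopifnot(inherits(db, "reference_db"), n_templates >= 1)
  f <- normalize_profile(profile)
  genera <- db$taxonomy$genus
  missing <- setdiff(names(f), genera)
  if (length(missing) > 0)
    stop("profile taxa absent from database: ", paste(missing, collapse = ", "))
  tlen <- attr(db, "template_length")
  if (is.null(tlen)) {
    tlen <- unique(nchar(db$sequences))
    if (length(tlen) != 1)
      stop("simulator requires equal-length templates")
  }
  with_seed(seed, {
    taxon_counts <- as.vector(rmultinom(1, n_templates, f))
    rows <- lapply(seq_along(f), function(i) {
      recs <- db$taxonomy$record_id[genera == names(f)[i]]
      cnt <- as.vector(rmultinom(1, taxon_counts[i],
                                 rep(1 / length(recs), length(recs))))
      data.frame(record_id = recs, taxon = names(f)[i], count = cnt,
                 stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, rows)
    attr(pool, "template_length") <- as.integer(tlen)
    class(pool) <- c("template_pool", "data.frame")
    pool
  })
}

#' Fragment template molecules by random chain scission
#'
#' Every internal phosphodiester bond of every template copy breaks
#' independently with probability `lam`; fragments are the maximal unbroken
#' runs, and fragments shorter than `min_len` are discarded (mirroring the
#' short-read filter applied to sequencing data).
#'
#' @param pool a `template_pool`.
#' @param lam per-bond scission probability, `0 <= lam < 1`.
#' @param min_len minimum retained fragment length (default 25).
#' @param seed integer seed.
#' @return a `fragment_set`: data.frame (`record_id`, `taxon`, `start`,
#'   `end`, `length`) with 0-based half-open coordinates on the template and
#'   attributes `template_length`, `lambda`, `min_len`.
#' @export
fragment_templates <- function(pool, lam, min_len = 25, seed = 1L) {
  stopifnot(inherits(pool, "template_pool"))
  check_lambda(lam)
  tlen <- attr(pool, "template_length")
  res <- with_seed(seed, cpp_fragment_templates(pool$count, tlen, lam,
                                                as.integer(min_len)))
  frags <- data.frame(
    record_id = pool$record_id[res$record],
    taxon = pool$taxon[res$record],
    start = res$start, end = res$end, length = res$end - res$start,
    stringsAsFactors = FALSE)
  attr(frags, "template_length") <- tlen
  attr(frags, "lambda") <- lam
  attr(frags, "min_len") <- as.integer(min_len)
  class(frags) <- c("fragment_set", "data.frame")
  frags
}

amplicon_intervals <- function(db, pair, record_ids, max_len = 500) {
  ivals <- lapply(record_ids, function(id) {
    amp <- extract_amplicon(pair, db$sequences[[id]], max_len)
    if (is.null(amp)) c(NA_integer_, NA_integer_)
    else c(amp$amp_start, amp$amp_end)
  })
  m <- do.call(rbind, ivals)
  rownames(m) <- record_ids
  colnames(m) <- c("amp_start", "amp_end")
  m
}

#' Count amplifiable fragments per taxon
#'
#' A fragment yields one amplicon iff its interval fully contains its source
#' record's primer-inclusive amplicon interval (amplification requires a
#' template spanning the whole target plus both primer sites).  PCR is
#' modelled as exhaustive: every amplifiable fragment contributes one
#' amplicon; the bias mechanism under study is template availability, not
#' polymerase kinetics.  Taxa whose records yield no amplicon interval are
#' skipped with a warning.
#'
#' @param frags a `fragment_set`.
#' @param pair a `primer_pair`.
#' @param db the source `reference_db`.
#' @param max_len maximum amplicon length.
#' @return named integer vector of amplicon counts per taxon.
#' @export
amplify_fragments <- function(frags, pair, db, max_len = 500) {
  stopifnot(inherits(frags, "fragment_set"))
  ids <- unique(frags$record_id)
  ivals <- amplicon_intervals(db, pair, ids, max_len)
  no_amp <- ids[is.na(ivals[, 1])]
  if (length(no_amp) > 0) {
    skipped <- unique(frags$taxon[frags$record_id %in% no_amp])
    warning("no amplicon interval for records of taxa: ",
            paste(skipped, collapse = ", "), "; their fragments are skipped")
  }
  a0 <- ivals[frags$record_id, "amp_start"]
  a1 <- ivals[frags$record_id, "amp_end"]
  hit <- !is.na(a0) & frags$start <= a0 & frags$end >= a1
  taxa <- sort(unique(frags$taxon))
  counts <- vapply(taxa, function(t) sum(hit & frags$taxon == t), integer(1))
  setNames(as.integer(counts), taxa)
}

#' Sample shotgun reads from a fragment set
#'
#' Reads are drawn uniformly over fragments with replacement (one read per
#' drawn fragment, not length-weighted: library molecules are fragments, and
#' with equal-length templates taxon frequencies then track template
#' proportions).  Set `length_weighted = TRUE` to weight draws by fragment
#' length instead.
#'
#' @param frags a `fragment_set` (non-empty).
#' @param n_reads number of reads (`>= 1`).
#' @param seed integer seed.
#' @param length_weighted weight draws by fragment length.
#' @return named integer vector of read counts per taxon.
#' @export
shotgun_sample <- function(frags, n_reads, seed = 1L,
                           length_weighted = FALSE) {
  stopifnot(inherits(frags, "fragment_set"), n_reads >= 1)
  if (nrow(frags) == 0) stop("empty fragment set")
  w <- if (length_weighted) frags$length else rep(1, nrow(frags))
  idx <- with_seed(seed, sample.int(nrow(frags), n_reads, replace = TRUE,
                                    prob = w))
  taxa <- sort(unique(frags$taxon))
  tab <- table(factor(frags$taxon[idx], levels = taxa))
  setNames(as.integer(tab), taxa)
}

#' Run the full synthetic amplicon-versus-shotgun experiment
#'
#' Composes the pipeline: generate the synthetic database, draw a template
#' pool from the community, fragment it by random scission, then in
#' parallel (i) count amplifiable fragments per taxon (amplicon arm) and
#' (ii) draw shotgun reads; finally compare the two profiles and attach the
#' analytic frequency prediction at the same lambda for cross-checking.
#' Stage seeds are derived deterministically from the master seed.
#'
#' With `engine = "counts"` the fragmentation stage runs a streaming kernel
#' that applies the identical per-bond scission model but returns only
#' per-record tallies (fragments kept, fragments containing the amplicon
#' interval) instead of materialising every fragment, and the shotgun draw
#' becomes the equivalent multinomial over per-taxon fragment counts;
#' required for pools of millions of templates.
#'
#' @param clades list of [clade_spec()] objects.
#' @param profile named numeric community profile over the clade genera.
#' @param pair a `primer_pair`.
#' @param lam per-bond scission probability.
#' @param n_templates template copies to draw.
#' @param n_reads shotgun reads to draw.
#' @param seed master seed.
#' @param template_length template length (default 1540).
#' @param min_len minimum retained fragment length (default 25).
#' @param max_len maximum amplicon length (default 500).
#' @param engine `"fragments"` (materialise the fragment set) or
#'   `"counts"` (streaming tallies).
#' @return list with `amplicon_counts`, `shotgun_counts`, `comparison`
#'   (`NULL` when the amplicon library is empty), `prediction` (analytic),
#'   `n_amplicons`, `params`, and (fragments engine only) `fragments`.
#' @export
run_end_to_end <- function(clades, profile, pair, lam, n_templates, n_reads,
                           seed = 1L, template_length = 1540, min_len = 25,
                           max_len = 500,
                           engine = c("fragments", "counts")) {
  engine <- match.arg(engine)
  check_lambda(lam)
  sub <- with_seed(seed, sample.int(2^31 - 2, 4))
  db <- generate_reference_db(clades, pair, template_length, seed = sub[1])
  pool <- sample_community(profile, db, n_templates, seed = sub[2])
  frags <- NULL
  if (engine == "fragments") {
    frags <- fragment_templates(pool, lam, min_len, seed = sub[3])
    amp_counts <- amplify_fragments(frags, pair, db, max_len)
    shot_counts <- shotgun_sample(frags, n_reads, seed = sub[4])
  } else {
    ivals <- amplicon_intervals(db, pair, pool$record_id, max_len)
    a0 <- ivals[, "amp_start"]; a1 <- ivals[, "amp_end"]
    a0[is.na(a0)] <- -1L; a1[is.na(a1)] <- -1L
    tallies <- with_seed(sub[3], cpp_fragment_counts(
      pool$count, template_length, lam, as.integer(min_len),
      as.integer(a0), as.integer(a1)))
    taxa <- sort(unique(pool$taxon))
    by_taxon <- function(v) vapply(taxa, function(t)
      sum(v[pool$taxon == t]), integer(1))
    kept <- by_taxon(tallies$kept)
    amp_counts <- setNames(as.integer(by_taxon(tallies$amplifiable)), taxa)
    if (sum(kept) == 0) stop("empty fragment set")
    shot_counts <- with_seed(sub[4],
      setNames(as.integer(rmultinom(1, n_reads, kept)), taxa))
  }
  comparison <- if (sum(amp_counts) > 0)
    compare_amplicon_shotgun(amp_counts, shot_counts) else NULL
  lengths <- setNames(vapply(clades, function(cl) cl$amplicon_length,
                             integer(1)),
                      vapply(clades, clade_genus, character(1)))
  prediction <- predict_observed_profile(profile, lengths, lam)
  list(amplicon_counts = amp_counts, shotgun_counts = shot_counts,
       comparison = comparison, prediction = prediction,
       n_amplicons = sum(amp_counts), fragments = frags,
       params = list(lambda = lam, n_templates = n_templates,
                     n_reads = n_reads, seed = seed, min_len = min_len,
                     template_length = template_length, engine = engine))
}

#' Empirical survival of a fixed target window
#'
#' The fraction of template copies in which a fixed `x`-base window is
#' retained intact (covered by a single fragment) — the empirical
#' counterpart of the model survival `exp(-lambda * x)`.  Each template
#' contributes at most one covering fragment, so the numerator can be read
#' directly off the fragment set.  The fragment set must be unfiltered
#' (`min_len = 1`) so that no covering fragment has been discarded; windows
#' of length below the filter could otherwise be undercounted.
#'
#' @param frags a `fragment_set` built with `min_len <= start offset`
#'   considerations satisfied (use `min_len = 1`).
#' @param n_templates number of template copies fragmented.
#' @param x window length in bases.
#' @param start 0-based window start on the template (default 0).
#' @return fraction of templates retaining the intact window.
#' @export
window_survival_empirical <- function(frags, n_templates, x, start = 0) {
  stopifnot(inherits(frags, "fragment_set"), n_templates >= 1, x >= 1)
  tlen <- attr(frags, "template_length")
  if (start + x > tlen) stop("window exceeds template length")
  sum(frags$start <= start & frags$end >= start + x) / n_templates
}
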