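test_that("generated databases carry the planted clade structure", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  expect_equal(n_records(db), 9L)
  amps <- amplify_database(db, pair)
  expect_true(all(amps$amplified))
  want <- rep(c(151L, 169L, 194L), each = 3)
  expect_equal(amps$length, want)
  # determinism: same spec + seed is bit-identical
  db2 <- generate_reference_db(test_clades(), pair, seed = 7)
  expect_identical(db2$sequences, db$sequences)
  # zero divergence makes within-clade amplicon regions identical
  db0 <- generate_reference_db(test_clades(divergence = 0), pair, seed = 7)
  a0 <- amplify_database(db0, pair)
  for (g in unique(db0$taxonomy$genus)) {
    seqs <- a0$sequence[db0$taxonomy$genus == g]
    expect_equal(length(unique(seqs)), 1L)
  }
  # amplicon length shorter than the primers is rejected
  expect_error(generate_reference_db(
    list(clade_spec("Bacteria;P;C;O;F;G1", 1, 30)), pair), "primer lengths")
})

test_that("community sampling is multinomial and deterministic", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  # single taxon: every copy that taxon
  pool1 <- sample_community(c(Treponema = 1), db, 500, seed = 1)
  expect_equal(sum(pool1$count), 500L)
  expect_true(all(pool1$count[pool1$taxon != "Treponema"] == 0))
  # 50/50 split within 3 binomial sigma
  n <- 1e5
  pool <- sample_community(c(Methanobrevibacter = 0.5, Treponema = 0.5),
                           db, n, seed = 2)
  n_m <- sum(pool$count[pool$taxon == "Methanobrevibacter"])
  expect_lt(abs(n_m - n / 2), 3 * sqrt(n * 0.25))
  # determinism
  pool_b <- sample_community(c(Methanobrevibacter = 0.5, Treponema = 0.5),
                             db, n, seed = 2)
  expect_identical(pool_b$count, pool$count)
  expect_error(sample_community(c(Unknown = 1), db, 10), "absent")
})

test_that("fragmentation conserves bases and counts breaks correctly", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  pool <- sample_community(test_profile(), db, 2000, seed = 3)
  # lambda = 0: one full-length fragment per template
  fr0 <- fragment_templates(pool, 0, min_len = 1, seed = 4)
  expect_equal(nrow(fr0), 2000L)
  expect_true(all(fr0$length == 1540))
  # min_len = 1 partitions the templates exactly
  fr <- fragment_templates(pool, 0.02, min_len = 1, seed = 4)
  expect_equal(sum(fr$length), 2000L * 1540L)
  expect_true(all(fr$start >= 0 & fr$end <= 1540))
  # filter contract
  fr25 <- fragment_templates(pool, 0.02, min_len = 25, seed = 4)
  expect_true(all(fr25$length >= 25))
  expect_lte(sum(fr25$length), sum(fr$length))
  # determinism
  fr_b <- fragment_templates(pool, 0.02, min_len = 1, seed = 4)
  expect_identical(fr_b, fr)
})

test_that("fragment-length distribution matches a brute-force per-bond simulator", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  pool <- sample_community(test_profile(), db, 3000, seed = 5)
  lam <- 0.01
  fr <- fragment_templates(pool, lam, min_len = 1, seed = 6)
  set.seed(99)
  oracle <- oracle_fragment_lengths(3000, 1540, lam, min_len = 1)
  # both simulate the same per-bond Bernoulli model: compare fragment
  # counts and the length ECDF at a grid of points
  n1 <- nrow(fr); n2 <- length(oracle)
  expected_frags <- 3000 * (1 + 1539 * lam)
  expect_lt(abs(n1 - expected_frags), 4 * sqrt(3000 * 1539 * lam))
  expect_lt(abs(n2 - expected_frags), 4 * sqrt(3000 * 1539 * lam))
  for (x in c(25, 50, 100, 200, 400)) {
    p1 <- mean(fr$length >= x)
    p2 <- mean(oracle >= x)
    se <- sqrt(p2 * (1 - p2) * (1 / n1 + 1 / n2))
    expect_lt(abs(p1 - p2), 4 * se + 1e-6)
  }
})

test_that("target-window survival tracks the per-bond survival law", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  n <- 3e4
  pool <- sample_community(test_profile(), db, n, seed = 8)
  for (lam in c(0.0149, 0.0701)) {
    fr <- fragment_templates(pool, lam, min_len = 1, seed = 9)
    for (x in c(50, 100, 150)) {
      emp <- window_survival_empirical(fr, n, x, start = 300)
      theo <- (1 - lam)^(x - 1)  # x-1 internal bonds must hold
      expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / n) + 1e-9)
    }
  }
})

test_that("amplification counts fragments containing the amplicon interval", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  pool <- sample_community(test_profile(), db, 5e4, seed = 10)
  lam <- 0.005
  fr <- fragment_templates(pool, lam, min_len = 25, seed = 11)
  counts <- amplify_fragments(fr, pair, db)
  # analytic expectation: n_i * (1-lambda)^(x_i - 1) within 3 binomial sigma
  x <- c(Anaerolinea = 169, Methanobrevibacter = 151, Treponema = 194)
  for (taxon in names(counts)) {
    n_i <- sum(pool$count[pool$taxon == taxon])
    p_i <- (1 - lam)^(x[[taxon]] - 1)
    expect_lt(abs(counts[[taxon]] - n_i * p_i),
              3 * sqrt(n_i * p_i * (1 - p_i)))
  }
  # a fragment exactly equal to the amplicon interval is counted; one
  # base short is not
  amp <- extract_amplicon(pair, db$sequences[[1]])
  mk_frag <- function(s, e) {
    f <- data.frame(record_id = names(db$sequences)[1],
                    taxon = "Methanobrevibacter", start = s, end = e,
                    length = e - s, stringsAsFactors = FALSE)
    attr(f, "template_length") <- 1540L
    class(f) <- c("fragment_set", "data.frame")
    f
  }
  exact <- amplify_fragments(mk_frag(amp$amp_start, amp$amp_end), pair, db)
  expect_equal(unname(exact["Methanobrevibacter"]), 1L)
  short <- amplify_fragments(mk_frag(amp$amp_start, amp$amp_end - 1L),
                             pair, db)
  expect_equal(unname(short["Methanobrevibacter"]), 0L)
})

test_that("taxa without an amplicon interval are skipped with a warning", {
  pair <- test_v3_pair()
  clades <- c(test_clades(),
              list(clade_spec("Bacteria;Firmicutes;C;O;F;Deadgenus", 2, 180,
                              defect = "last_base_mismatch")))
  db <- generate_reference_db(clades, pair, seed = 12)
  prof <- c(Methanobrevibacter = 0.5, Deadgenus = 0.5)
  pool <- sample_community(prof, db, 2000, seed = 13)
  fr <- fragment_templates(pool, 0.001, min_len = 25, seed = 14)
  expect_warning(counts <- amplify_fragments(fr, pair, db), "Deadgenus")
  expect_equal(unname(counts["Deadgenus"]), 0L)
  expect_gt(counts[["Methanobrevibacter"]], 0L)
})

test_that("shotgun sampling splits reads by fragment counts", {
  pair <- test_v3_pair()
  db <- generate_reference_db(test_clades(), pair, seed = 7)
  # single-taxon fragments: all reads that taxon
  pool1 <- sample_community(c(Anaerolinea = 1), db, 1000, seed = 15)
  fr1 <- fragment_templates(pool1, 0.01, min_len = 25, seed = 16)
  s1 <- shotgun_sample(fr1, 500, seed = 17)
  expect_equal(unname(s1["Anaerolinea"]), 500L)
  # equal fragment pools split within 3 sigma of 50/50
  pool2 <- sample_community(c(Methanobrevibacter = 0.5, Treponema = 0.5),
                            db, 2e4, seed = 18)
  fr2 <- fragment_templates(pool2, 0.01, min_len = 25, seed = 19)
  s2 <- shotgun_sample(fr2, 1e4, seed = 20)
  frac_m <- sum(fr2$taxon == "Methanobrevibacter") / nrow(fr2)
  expect_lt(abs(s2[["Methanobrevibacter"]] - 1e4 * frac_m),
            3 * sqrt(1e4 * frac_m * (1 - frac_m)))
  # determinism and error contract
  expect_identical(shotgun_sample(fr2, 1e4, seed = 20), s2)
  expect_error(shotgun_sample(fr2[0, ], 10), "empty")
})

test_that("end-to-end run without degradation shows no amplification bias", {
  res <- run_end_to_end(test_clades(), test_profile(), test_v3_pair(),
                        lam = 0, n_templates = 3e4, n_reads = 1e4,
                        seed = 21)
  # every template amplifies; amplicon frequencies equal the multinomial
  # template frequencies, shotgun agrees within 3 sigma
  expect_equal(res$n_amplicons, 3e4)
  fa <- res$amplicon_counts / sum(res$amplicon_counts)
  fs <- res$shotgun_counts / sum(res$shotgun_counts)
  for (t in names(fa)) {
    se <- sqrt(fa[[t]] * (1 - fa[[t]]) * (1 / 3e4 + 1 / 1e4))
    expect_lt(abs(fa[[t]] - fs[[t]]), 3 * se + 1e-9)
  }
  expect_true(all(abs(res$comparison$lfc) < 0.2))
  # prediction equals input at lambda = 0
  expect_equal(setNames(res$prediction$f_pred, res$prediction$taxon),
               normalize_profile(test_profile()))
})

test_that("streaming counts engine reproduces the fragment engine exactly", {
  # both engines consume the identical RNG stream for fragmentation, so
  # per-taxon amplicon tallies must agree bit-for-bit at the same seed
  args <- list(test_clades(), test_profile(), test_v3_pair(), lam = 0.01,
               n_templates = 2e4, n_reads = 5e3, seed = 22)
  a <- do.call(run_end_to_end, c(args, engine = "fragments"))
  b <- do.call(run_end_to_end, c(args, engine = "counts"))
  expect_identical(a$amplicon_counts, b$amplicon_counts)
  # shotgun draws differ in mechanism (uniform fragment draws vs the
  # equivalent multinomial) but share the per-taxon law: 3-sigma agreement
  fa <- a$shotgun_counts / sum(a$shotgun_counts)
  fb <- b$shotgun_counts / sum(b$shotgun_counts)
  for (t in names(fa))
    expect_lt(abs(fa[[t]] - fb[[t]]), 3 * sqrt(2 * 0.25 / 5e3))
  # determinism of the full composite
  a2 <- do.call(run_end_to_end, c(args, engine = "fragments"))
  expect_identical(a2$amplicon_counts, a$amplicon_counts)
  expect_identical(a2$shotgun_counts, a$shotgun_counts)
})

test_that("degraded end-to-end runs skew toward the shortest amplicon", {
  res <- run_end_to_end(test_clades(), test_profile(), test_v3_pair(),
                        lam = 0.0149, n_templates = 1e5, n_reads = 2e4,
                        seed = 23, engine = "counts")
  cmp <- res$comparison
  lfc <- setNames(cmp$lfc, cmp$taxon)
  expect_gt(lfc[["Methanobrevibacter"]], 0)   # shortest amplicon enriched
  expect_lt(lfc[["Treponema"]], 0)            # longest amplicon depleted
  # amplicon frequencies agree with the analytic prediction within 3 sigma
  fa <- res$amplicon_counts / res$n_amplicons
  pred <- setNames(res$prediction$f_pred, res$prediction$taxon)
  for (t in names(fa)) {
    se <- sqrt(pred[[t]] * (1 - pred[[t]]) / res$n_amplicons)
    expect_lt(abs(fa[[t]] - pred[[t]]), 3 * se + 0.002)
  }
})
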