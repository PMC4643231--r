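#!/usr/bin/env Rscript
# Fragment-length structure of degraded 16S template pools at the seven
# packaged per-site scission probabilities, and the fraction of fragments
# long enough to serve as V3 amplification templates (150 and 194 bp, the
# short and long bounds of the length-polymorphic V3 target).

suppressPackageStartupMessages(library(paleoamp))
dir.create("results/fragmentation", recursive = TRUE, showWarnings = FALSE)
seed <- 20260924
n_templates <- 5e4

sites <- site_lambda_table()
sites <- sites[order(sites$lambda), ]
pair <- default_primer_pairs()$V3_U341F_534R
clade <- clade_spec("Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus",
                    n_otus = 1, amplicon_length = 183)  # median V3 target
db <- generate_reference_db(list(clade), pair, seed = seed)
pool <- sample_community(c(Streptococcus = 1), db, n_templates, seed = seed)

rows <- lapply(seq_len(nrow(sites)), function(i) {
  lam <- sites$lambda[i]
  fr <- fragment_templates(pool, lam, min_len = 25, seed = seed + i)
  st <- fragment_stats(fr$length, thresholds = c(150, 183, 194))
  surv183 <- survival_probability(lam, 183)
  message(sprintf(
    "%-18s lambda=%.4f: median fragment %d bp (q1 %d, q3 %d); %5.2f%% of fragments >=150 bp, %5.2f%% >=194 bp; model survival of the 183 bp median target: %.3g",
    sites$site[i], lam, st$median, st$q1, st$q3,
    100 * st$frac_ge[["ge_150"]], 100 * st$frac_ge[["ge_194"]], surv183))
  data.frame(site = sites$site[i], lambda = lam, n_fragments = st$n,
             median_bp = st$median, q1_bp = st$q1, q3_bp = st$q3,
             frac_ge_150 = st$frac_ge[["ge_150"]],
             frac_ge_183 = st$frac_ge[["ge_183"]],
             frac_ge_194 = st$frac_ge[["ge_194"]],
             model_survival_183 = surv183,
             lambda_hat = tryCatch(estimate_lambda(fr$length),
                                   error = function(e) NA_real_))
})
tab <- do.call(rbind, rows)
write_report(tab, "results/fragmentation/fragment_stats_by_site.tsv")
message("Longer targets sit ever deeper in the upper tail of the fragment-length distribution: amplifiable fractions shrink fast with thermal age, and the 194 bp targets are always rarer than the 150 bp ones.")
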