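#!/usr/bin/env Rscript
# End-to-end synthetic amplicon-versus-shotgun comparison: the forward
# simulator (community -> template pool -> per-bond fragmentation ->
# {amplicon dropout, shotgun sampling}) run at three packaged scission
# probabilities, summarized as per-genus log2 fold changes, archaeal
# fractions and oral/other fractions.

suppressPackageStartupMessages(library(paleoamp))
dir.create("results/comparison", recursive = TRUE, showWarnings = FALSE)
seed <- 20260924

clades <- list(
  clade_spec("Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
             3, 151),
  clade_spec("Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolineaceae;Anaerolinea",
             3, 169),
  clade_spec("Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus",
             3, 194),
  clade_spec("Bacteria;Spirochaetes;Spirochaetia;Spirochaetales;Spirochaetaceae;Treponema",
             3, 194))
profile <- c(Methanobrevibacter = 0.01, Anaerolinea = 0.04,
             Streptococcus = 0.55, Treponema = 0.40)
pair <- default_primer_pairs()$V3_U341F_534R
oral_list <- c("Methanobrevibacter", "Anaerolinea", "Streptococcus",
               "Treponema")
lineages <- data.frame(
  taxon = names(profile),
  domain = c("Archaea", "Bacteria", "Bacteria", "Bacteria"))

lams <- c(0.0006, 0.0149, 0.0701)  # young, mid, high thermal age
rows <- list()
for (i in seq_along(lams)) {
  lam <- lams[i]
  res <- run_end_to_end(clades, profile, pair, lam,
                        n_templates = if (lam > 0.05) 8e6 else 2e5,
                        n_reads = 5e4, seed = seed + i, engine = "counts")
  fa <- res$amplicon_counts / max(1, res$n_amplicons)
  fs <- res$shotgun_counts / sum(res$shotgun_counts)
  cmp <- res$comparison
  cmp$lambda <- lam
  cmp$f_predicted <- res$prediction$f_pred[match(cmp$taxon,
                                                 res$prediction$taxon)]
  rows[[i]] <- cmp
  arch_a <- archaeal_fraction(fa, lineages)
  arch_s <- archaeal_fraction(fs, lineages)
  arch_pred <- archaeal_fraction(
    setNames(res$prediction$f_pred, res$prediction$taxon), lineages)
  message(sprintf(
    "lambda=%.4f: %d amplicons from %g templates; archaeal fraction %5.1f%% (amplicon, model predicts %4.1f%%) vs %4.1f%% (shotgun); input was 1.0%%",
    lam, res$n_amplicons, res$params$n_templates, 100 * arch_a,
    100 * arch_pred, 100 * arch_s))
  lfc <- setNames(cmp$lfc, cmp$taxon)
  message(sprintf(
    "            log2 fold changes: Methanobrevibacter %+0.2f, Anaerolinea %+0.2f, Streptococcus %+0.2f, Treponema %+0.2f",
    lfc[["Methanobrevibacter"]], lfc[["Anaerolinea"]],
    lfc[["Streptococcus"]], lfc[["Treponema"]]))
}
tab <- do.call(rbind, rows)
write_report(tab, "results/comparison/lfc_by_lambda.tsv")

oral <- classify_oral(profile, oral_list)
message(sprintf(
  "All four genera are oral (oral fraction %.2f); the skew above is taphonomic, not compositional: the archaeon with the shortest target overamplifies as degradation deepens while 194 bp targets drop out.",
  oral$oral_fraction))
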