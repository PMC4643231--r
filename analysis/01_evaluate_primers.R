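#!/usr/bin/env Rscript
# In-silico evaluation of the V3 (U341F/534R) and V4 (515F/806R) universal
# primer pairs on a synthetic oral-microbiome 16S database.
#
# The database plants, for each genus in the packaged oral-taxon panel, the
# genus's predicted V3 amplicon length on a conserved full-length template
# (archaeal clade shortest), so the evaluation exercises the real pipeline
# — site scoring, amplicon extraction, length summaries, coverage,
# OTU-clustering resolution — on data with known truth.

suppressPackageStartupMessages(library(paleoamp))
dir.create("results/primer_evaluation", recursive = TRUE,
           showWarnings = FALSE)
seed <- 20260924

taxa <- oral_taxon_table()
taxa$genus <- vapply(strsplit(taxa$taxon, " "), `[`, character(1), 1)
taxa <- taxa[!duplicated(taxa$genus) & taxa$domain != "Chloroplast", ]
message(sprintf("Building synthetic database: %d genera, V3 lengths %d-%d bp",
                nrow(taxa), min(taxa$v3_length_bp), max(taxa$v3_length_bp)))

pair_v3 <- default_primer_pairs()$V3_U341F_534R
clades <- lapply(seq_len(nrow(taxa)), function(i)
  clade_spec(sprintf("%s;%s_phylum;C;O;F;%s", taxa$domain[i],
                     taxa$domain[i], taxa$genus[i]),
             n_otus = 3, amplicon_length = taxa$v3_length_bp[i],
             divergence = 0.01))
db <- generate_reference_db(clades, pair_v3, seed = seed)

# --- length variation ---
dist <- amplicon_length_distribution(db, pair_v3, rank = "genus")
write_report(dist, "results/primer_evaluation/v3_length_by_genus.tsv")
message(sprintf(
  "V3 per-genus medians span %d-%d bp (a %d bp spread); archaeal genus %s is shortest at %d bp",
  min(dist$median), max(dist$median), max(dist$median) - min(dist$median),
  dist$group[which.min(dist$median)], min(dist$median)))

# --- taxonomic coverage ---
cov <- taxonomic_coverage(db, pair_v3)
write_report(cov, "results/primer_evaluation/v3_coverage_by_phylum.tsv")
message(sprintf("V3 coverage: %.0f%% of records amplify overall",
                100 * sum(cov$n_amplified) / sum(cov$n_total)))

# --- taxonomic resolution ---
amps <- amplify_database(db, pair_v3)
full <- taxonomic_resolution(db$sequences)
res <- taxonomic_resolution(setNames(amps$sequence[amps$amplified],
                                     amps$record_id[amps$amplified]),
                            reference_total = full$n_otus)
write_report(data.frame(n_input = res$n_input, n_otus = res$n_otus,
                        full_length_otus = full$n_otus,
                        resolution_fraction = res$resolution_fraction),
             "results/primer_evaluation/v3_resolution.tsv")
message(sprintf(
  "V3 resolution: %d amplicon OTUs vs %d full-length OTUs (%.0f%%); the synthetic generator concentrates all variation inside the amplified loop, so amplicons here retain the full OTU structure — real databases spread variation across the gene and amplicons resolve fewer OTUs",
  res$n_otus, full$n_otus, 100 * res$resolution_fraction))

# --- V4 comparison: length-invariant target, ~292 bp ---
pair_v4 <- default_primer_pairs()$V4_515F_806R
set.seed(seed)
clades_v4 <- lapply(seq_len(nrow(taxa)), function(i)
  clade_spec(sprintf("%s;%s_phylum;C;O;F;%s", taxa$domain[i],
                     taxa$domain[i], taxa$genus[i]),
             n_otus = 3,
             amplicon_length = 292L + sample(-2:3, 1),  # 290-295 bp
             divergence = 0.01))
db_v4 <- generate_reference_db(clades_v4, pair_v4, seed = seed)
dist_v4 <- amplicon_length_distribution(db_v4, pair_v4, rank = "genus")
write_report(dist_v4, "results/primer_evaluation/v4_length_by_genus.tsv")
message(sprintf(
  "V4 per-genus medians span %d-%d bp: longer than V3 but nearly length-invariant",
  min(dist_v4$median), max(dist_v4$median)))
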