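#!/usr/bin/env Rscript
# Re-selection deconvolution of the analyzed campaign: the most abundant
# post-selection RNAs (plus spiked decoy controls) are re-selected against
# ten candidate proteins individually; motif-subset EF box statistics and
# cognate/depleted calls identify the planted pair. Writes
# results/deconvolution/.

suppressMessages(library(pdselex))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 101L
if (!file.exists("results/enrichment/count_tables.tsv"))
  stop("run analysis/04_enrichment_analysis.R first", call. = FALSE)
out <- "results/deconvolution"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_counts_tsv("results/enrichment/count_tables.tsv")
planted <- read.delim("results/campaign/planted.tsv",
                      colClasses = "character")
# rebuild the scenario (same seed as the simulation) for the decoy map
manifest <- jsonlite::read_json("results/campaign/manifest.json")
sc <- planted_pair_scenario(seed = manifest$seed)

arms <- paste0("P", 1:10)
resel <- reselection_from_campaign(tab[tab$pool == "RNA", ], sc, arms,
                                   round = 3L, seed = seed + 1L)
efmat <- vapply(arms, function(p) reselection_ef(resel$experiment, p),
                numeric(nrow(resel$experiment$pre_table)))
write.table(data.frame(sequence = rownames(efmat), efmat,
                       check.names = FALSE),
            file.path(out, "ef_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

bs <- reselection_box_stats(resel$experiment,
                            motifs = list(cs1 = sc$motif))
write.table(bs, file.path(out, "box_stats.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
# bootstrap interval for the planted arm's subset median
pre <- resel$experiment$pre_table
in_subset <- motif_match(pre$sequence, sc$motif)
ci <- boot_median_ci(reselection_ef(resel$experiment,
                                    planted$protein_id)[in_subset],
                     seed = seed + 2L)
cat(sprintf("planted arm subset median EF %.2f (bootstrap 95%% CI %.2f-%.2f)\n",
            ci[["median"]], ci[["lower"]], ci[["upper"]]))

calls <- call_pairs(bs)
write.table(calls$calls, file.path(out, "pair_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(calls$calls, file.path(out, "pair_calls.json"),
                     auto_unbox = TRUE, digits = NA)
n_cog <- sum(calls$calls$call == "cognate")
cat(sprintf("%d of %d arms called cognate for the motif subset: %s\n",
            n_cog, length(arms),
            paste(calls$calls$protein_id[calls$calls$call == "cognate"],
                  collapse = ", ")))
cat("planted protein:", planted$protein_id, "\n")
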