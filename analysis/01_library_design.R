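#!/usr/bin/env Rscript
# Library design arithmetic: NNK codon statistics and the combinatorial
# search space of the two libraries. Writes results/library/.

suppressMessages(library(pdselex))
out <- "results/library"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

p <- nnk_amino_acid_distribution()
write.table(data.frame(residue = names(p), probability = as.numeric(p)),
            file.path(out, "nnk_aa_distribution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("NNK amino-acid distribution: modal residues",
    paste(names(p)[p == max(p)], collapse = ", "),
    sprintf("at %.4f each; P(stop) = %.4f\n", max(p), p[["*"]]))

div_prot <- theoretical_diversity(8, 20)
div_rna <- theoretical_diversity(20, 4)
cat(sprintf("protein library diversity 20^8 = %.3g\n", div_prot))
cat(sprintf("RNA loop diversity 4^20 = %.3g\n", div_rna))
cat(sprintf("combination space (1.1e12 RNAs x 4.0e8 displayed proteins) = %.2g\n",
            combination_space(1.1e12, 4.0e8)))
write.table(data.frame(
  quantity = c("protein_diversity_20^8", "rna_diversity_4^20",
               "combination_space"),
  value = c(div_prot, div_rna, combination_space(1.1e12, 4.0e8))),
  file.path(out, "diversity.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
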