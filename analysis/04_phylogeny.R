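#!/usr/bin/env Rscript
# Step 4 — per-gene UPGMA phylogenies with bootstrap support.
#
# Kimura two-parameter distances (pairwise deletion over ambiguity codes)
# across both breeds, the reference and the outgroups; UPGMA clustering;
# 1000 column-resampling replicates for branch support. One Newick per gene.

library(breeddiff)

data_dir <- "results/data"
seed <- 20230120
B <- 1000
sheet <- read_sample_sheet(file.path(data_dir, "samples.tsv"))
genes <- sub("\\.fasta$", "", list.files(data_dir, pattern = "\\.fasta$"))

dir.create("results/trees", recursive = TRUE, showWarnings = FALSE)
for (g in genes) {
  aln <- exclude_gap_columns(
    read_gene_fasta(file.path(data_dir, paste0(g, ".fasta")), sheet, gene = g))
  tree <- bootstrap_upgma(aln, B = B, seed = seed)
  writeLines(to_newick(tree), file.path("results/trees", paste0(g, ".nwk")))
  # support for the monophyly of each breed, when that clade exists
  keys <- c(ShaverBrown = "N5|N6|N7", Shamo = "S6|S7|S9")
  sup <- function(node, key) {
    if (!is.null(node$label)) return(NULL)
    if (paste(sort(tree_leaves(node)), collapse = "|") == key)
      return(node$support)
    c(sup(node$children[[1]], key), sup(node$children[[2]], key))
  }
  msg <- vapply(names(keys), function(b) {
    s <- sup(tree, keys[[b]])
    if (is.null(s)) paste0(b, ": not monophyletic")
    else paste0(b, ": ", s, "%")
  }, "")
  cat(g, "->", paste(msg, collapse = ", "), "\n")
}
cat("Newick trees with", B, "bootstrap replicates -> results/trees/\n")
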