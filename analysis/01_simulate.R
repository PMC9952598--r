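#!/usr/bin/env Rscript
# Step 1 — simulate the study-shaped dataset.
#
# Two breeds of three diploid hens each (egg-laying Shaver Brown N5/N6/N7,
# gamecock Shamo S6/S7/S9), a Red Jungle Fowl reference, and five Galliformes
# outgroups, over nine adrenergic-receptor genes at the analyzed lengths.
# Twenty-four amino-acid mutations are planted (4 Shaver-specific, 13
# Shamo-specific, 7 common; 23 heterozygous) plus synonymous background
# polymorphism, so the per-gene segregating-site totals and the downstream
# tables have the published shape. Writes FASTAs, the sample sheet, the
# synthetic topology annotation, and the truth tables.

library(breeddiff)

seed <- 20230120
out <- "results/data"

spec <- study_spec(seed = seed)
gen <- synth_generate(spec, seed = seed)
synth_write(gen, out)

cat("Simulated", length(gen$alignments), "genes for",
    sum(gen$sample_sheet$role == "ingroup"), "ingroup samples,",
    "1 reference and", sum(gen$sample_sheet$role == "outgroup"),
    "outgroups ->", out, "\n")
cat("Planted mutations:", nrow(gen$truth$mutations),
    "| heterozygous:", sum(gen$truth$mutations$n_het_carriers > 0),
    "| expected candidates after screening:",
    sum(gen$truth$mutations$selected), "\n")
cat("Per-gene segregating sites:",
    paste(gen$truth$per_gene$segregating_sites, collapse = ", "), "\n")
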