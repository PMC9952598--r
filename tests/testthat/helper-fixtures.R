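# Fixtures built in code: small alignments, random ingroup alignments for
# property tests, randomized synthetic specs, random ultrametric trees.

BASES <- c("A", "C", "G", "T")
HET_CODES <- c("R", "Y", "M", "K", "S", "W")
GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]

# alignment from named sequence strings; default everyone ingroup, breed by
# first letter of the id unless populations given
make_aln <- function(seqs, populations = NULL, roles = NULL, gene = "g1") {
  ids <- names(seqs)
  if (is.null(populations)) populations <- substr(ids, 1, 1)
  if (is.null(roles)) roles <- rep("ingroup", length(ids))
  gene_alignment(gene, seqs,
                 data.frame(sample_id = ids, population = populations,
                            role = roles))
}

# random two-subpopulation ingroup alignment; no column is all-missing within
# a subpopulation (frequencies stay defined)
random_ingroup_aln <- function(max_samples = 6, max_len = 30) {
  n <- sample(4:max_samples, 1)
  len <- sample(10:max_len, 1)
  pops <- rep(c("popA", "popB"), c(floor(n / 2), ceiling(n / 2)))
  ids <- paste0("s", seq_len(n))
  draw_col <- function() {
    repeat {
      col <- sample(c(BASES, HET_CODES, "N"), n, replace = TRUE,
                    prob = c(rep(0.8 / 4, 4), rep(0.15 / 6, 6), 0.05))
      ok <- vapply(unique(pops), function(p) any(col[pops == p] != "N"),
                   logical(1))
      if (all(ok)) return(col)
    }
  }
  seqs <- vapply(seq_len(len), function(i) draw_col(), character(n))
  rownames(seqs) <- ids
  gene_alignment("rand", seqs,
                 data.frame(sample_id = ids, population = pops,
                            role = "ingroup"))
}

# random codon pair one substitution apart with distinct non-stop residues
random_aa_change <- function() {
  repeat {
    rc <- sample(SENSE, 1)
    pos <- sample(1:3, 1)
    ac <- rc
    substr(ac, pos, pos) <- sample(setdiff(BASES, substr(rc, pos, pos)), 1)
    if (GC[[ac]] != "*" && GC[[ac]] != GC[[rc]])
      return(c(ref = unname(GC[[rc]]), alt = unname(GC[[ac]])))
  }
}

# randomized synthetic spec: 1-3 genes, 1-3 planted mutations each, a little
# background, two breeds x 3 samples, 2 outgroups
random_synth_spec <- function() {
  n_genes <- sample(1:3, 1)
  genes <- stats::setNames(3 * sample(20:40, n_genes), paste0("gene", seq_len(n_genes)))
  breeds <- list(eggline = c("E1", "E2", "E3"), gameline = c("G1", "G2", "G3"))
  ingroup <- unlist(breeds, use.names = FALSE)
  outgroups <- c("out1", "out2")
  rows <- list()
  for (g in names(genes)) {
    n_mut <- sample(0:3, 1)
    if (n_mut == 0) next
    positions <- sample(2:(genes[[g]] / 3 - 1), n_mut)
    for (p in positions) {
      aa <- random_aa_change()
      zyg <- sample(c("het", "hom"), 1, prob = c(0.8, 0.2))
      max_c <- if (zyg == "hom") 5 else 6
      carriers <- sample(ingroup, sample(1:max_c, 1))
      anc <- if (stats::runif(1) < 0.3) sample(outgroups, 1) else ""
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, aa_pos = p, ref_aa = aa[["ref"]], alt_aa = aa[["alt"]],
        carriers = paste(sort(carriers), collapse = ","), zygosity = zyg,
        ancestral_in = anc, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  background <- data.frame(gene = names(genes),
                           n_het = sample(0:2, n_genes, replace = TRUE),
                           n_hom = sample(0:1, n_genes, replace = TRUE))
  synth_spec(genes, breeds, reference = "REF", outgroups = outgroups,
             planted = planted, background = background,
             divergence = stats::runif(1, 0.01, 0.1))
}

# run the mutation-scanning stages on one generated gene and return the table
# in truth-table column order
recover_mutations <- function(gen, g) {
  aln <- exclude_gap_columns(gen$alignments[[g]])
  fs <- gen$frame_start[[g]]
  muts <- call_aa_mutations(aln, "REF", frame_start = fs)
  if (nrow(muts) == 0) return(muts)
  ing <- subset_members(aln, role = "ingroup")
  partition <- stats::setNames(ing$meta$population, ing$meta$sample_id)
  muts <- classify_mutations(muts, partition)
  og <- if (any(aln$meta$role == "outgroup"))
    subset_members(aln, role = "outgroup") else NULL
  muts <- screen_ancestral(muts, og, frame_start = fs)
  muts <- annotate_region(muts, gen$topology)
  select_candidates(muts)
}

# random ultrametric tree over n leaves: random merge order, strictly
# increasing heights; returns list(tree-as-clade-height-map, distance matrix)
random_ultrametric <- function(n) {
  labels <- paste0("L", seq_len(n))
  clusters <- as.list(labels)
  heights <- list()
  h <- 0
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    pick <- sample(length(clusters), 2)
    h <- h + stats::runif(1, 0.05, 0.5)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    d[a, b] <- 2 * h; d[b, a] <- 2 * h
    merged <- c(a, b)
    heights[[paste(sort(merged), collapse = "|")]] <- h
    clusters <- c(clusters[-pick], list(merged))
  }
  list(heights = heights, d = d)
}

# clade-key -> height map of an upgma_tree
clade_heights <- function(node, acc = NULL) {
  if (!is.null(node$label)) return(acc)
  key <- paste(sort(tree_leaves(node)), collapse = "|")
  acc <- c(acc, stats::setNames(node$height, key))
  acc <- clade_heights(node$children[[1]], acc)
  clade_heights(node$children[[2]], acc)
}
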