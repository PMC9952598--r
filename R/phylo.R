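# Kimura two-parameter distances, UPGMA clustering, bootstrap supports.
#
# Distances use pairwise deletion: a site enters a pair's comparison only when
# both symbols are unambiguous bases (ambiguity codes and N are missing for
# distance purposes; gap columns are excluded globally beforehand). With P the
# transition and Q the transversion proportion over compared sites,
#   d = -(1/2) * ln((1 - 2P - Q) * sqrt(1 - 2Q)).
# UPGMA merges the closest pair, averaging distances weighted by cluster
# size; ties break on the smallest (row, column) index pair so reruns are
# byte-identical. Bootstrap resamples alignment columns with replacement and
# scores each original internal node by the percentage of replicate trees
# containing its leaf set.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two sequences
#'
#' @param s1,s2 Character vectors of IUPAC symbols (equal length) or strings.
#' @return Substitution-corrected distance.
#' @export
k2p_distance <- function(s1, s2) {
  if (length(s1) == 1) s1 <- strsplit(s1, "")[[1]]
  if (length(s2) == 1) s2 <- strsplit(s2, "")[[1]]
  if (length(s1) != length(s2)) stop("sequences differ in length", call. = FALSE)
  use <- s1 %in% .BASES & s2 %in% .BASES
  n <- sum(use)
  if (n == 0) stop("no comparable sites after pairwise deletion", call. = FALSE)
  a <- s1[use]; b <- s2[use]
  diff <- a != b
  ts <- sum(diff & TRANSITIONS[a] == b)
  P <- ts / n
  Q <- (sum(diff) - ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated (P=", signif(P, 4), ", Q=", signif(Q, 4), ")",
         call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln A gap-excluded `gene_alignment`.
#' @return Symmetric matrix with zero diagonal, labelled by sample id.
#' @export
k2p_matrix <- function(aln) {
  ids <- rownames(aln$seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2p_distance(aln$seqs[i, ], aln$seqs[j, ])
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a merged
#' cluster to any other is the size-weighted arithmetic mean of its parts
#' (i.e. the unweighted average over leaf pairs). Node height is half the
#' merge distance, so the tree is ultrametric. Ties break on the smallest
#' (row, column) index pair in the current matrix.
#'
#' @param d Symmetric distance matrix with labels.
#' @return An `upgma_tree`: nested list with `label` at leaves and
#'   `children`, `height`, optional `support` at internal nodes.
#' @export
upgma <- function(d) {
  if (!all(is.finite(d))) stop("non-finite distances", call. = FALSE)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need >= 2 labels", call. = FALSE)
  nodes <- lapply(labels, function(l) list(label = l, height = 0))
  sizes <- rep(1, n)
  while (length(nodes) > 1) {
    m <- length(nodes)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- list(children = list(nodes[[i]], nodes[[j]]), height = best_d / 2)
    new_size <- sizes[i] + sizes[j]
    keep <- setdiff(seq_len(m), c(i, j))
    new_d <- (sizes[i] * d[i, keep] + sizes[j] * d[j, keep]) / new_size
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    nodes <- c(nodes[keep], list(merged))
    sizes <- c(sizes[keep], new_size)
  }
  structure(nodes[[1]], class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", length(tree_leaves(x)), "leaves, root height",
      signif(x$height, 6), "\n")
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Leaf labels under a node
#' @param node An `upgma_tree` or subtree.
#' @return Character vector of leaf labels.
#' @export
tree_leaves <- function(node) {
  if (!is.null(node$label)) return(node$label)
  c(tree_leaves(node$children[[1]]), tree_leaves(node$children[[2]]))
}

# sorted leaf-set keys of every internal node (clades of a rooted tree)
tree_clades <- function(node) {
  if (!is.null(node$label)) return(character(0))
  key <- paste(sort(tree_leaves(node)), collapse = "|")
  c(key, tree_clades(node$children[[1]]), tree_clades(node$children[[2]]))
}

#' Serialize a tree to Newick
#'
#' Branch lengths are parent height minus child height; internal-node labels
#' carry integer bootstrap supports when present.
#'
#' @param tree An `upgma_tree`.
#' @param digits Significant digits for branch lengths.
#' @return Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree, digits = 10) {
  fmt <- function(node, parent_height) {
    blv <- parent_height - node$height
    if (blv > -1e-9 && blv <= 0) blv <- 0  # float noise / -0 at zero-length merges
    bl <- sprintf("%.*g", digits, blv)
    if (!is.null(node$label)) return(paste0(node$label, ":", bl))
    sup <- if (!is.null(node$support)) formatC(node$support, format = "d") else ""
    paste0("(", fmt(node$children[[1]], node$height), ",",
           fmt(node$children[[2]], node$height), ")", sup, ":", bl)
  }
  sup <- if (!is.null(tree$support)) formatC(tree$support, format = "d") else ""
  paste0("(", fmt(tree$children[[1]], tree$height), ",",
         fmt(tree$children[[2]], tree$height), ")", sup, ";")
}

#' Convert to an ape phylo object
#' @param tree An `upgma_tree`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(tree) ape::read.tree(text = to_newick(tree))

#' UPGMA tree with bootstrap supports
#'
#' Builds the K2P+UPGMA tree from the full alignment, then resamples columns
#' with replacement `B` times, rebuilds the tree per replicate, and assigns
#' each internal node the percentage of successful replicates whose tree
#' contains the same leaf set. Replicates where any pairwise distance
#' saturates are discarded (with a warning); more than 50% discarded is an
#' error. Deterministic for a fixed seed.
#'
#' @param aln A gap-excluded `gene_alignment`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer RNG seed.
#' @return An `upgma_tree` with `support` on internal nodes and attributes
#'   `n_replicates` (successful) and `n_discarded`.
#' @export
bootstrap_upgma <- function(aln, B = 1000, seed = 20230120) {
  stopifnot(B >= 1)
  tree <- upgma(k2p_matrix(aln))
  L <- aln_length(aln)
  counts <- stats::setNames(numeric(length(tree_clades(tree))), tree_clades(tree))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  discarded <- 0
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- gene_alignment(aln$gene, aln$seqs[, cols, drop = FALSE],
                              aln$meta, seq_len(L))
    rep_tree <- tryCatch(upgma(k2p_matrix(rep_aln)), error = function(e) NULL)
    if (is.null(rep_tree)) { discarded <- discarded + 1; next }
    hits <- intersect(tree_clades(rep_tree), names(counts))
    counts[hits] <- counts[hits] + 1
  }
  if (discarded > B / 2)
    stop("more than half of bootstrap replicates saturated (", discarded,
         "/", B, ")", call. = FALSE)
  if (discarded > 0)
    warning(discarded, " of ", B, " bootstrap replicates discarded (saturation)")
  ok <- B - discarded
  supports <- round(100 * counts / ok)
  annotate <- function(node) {
    if (!is.null(node$label)) return(node)
    key <- paste(sort(tree_leaves(node)), collapse = "|")
    node$support <- unname(supports[key])
    node$children <- lapply(node$children, annotate)
    node
  }
  tree <- annotate(tree)
  attr(tree, "n_replicates") <- ok
  attr(tree, "n_discarded") <- discarded
  class(tree) <- "upgma_tree"
  tree
}
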