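# N_ST index of nucleotide differentiation.
#
# Each sample is one diploid genotype: an unambiguous base contributes two
# copies of that allele, a two-base IUPAC code one copy of each. Working with
# fractional weights (1 per sample, split over the symbol's expansion) gives
# identical frequencies since the factor of two cancels. N is missing data at
# that site for that sample: excluded, frequencies renormalized over the
# remaining samples.
#
# Per segregating site i and subpopulation j:
#   H_Ti  = 1 - (P_Ai^2 + P_Ti^2 + P_Gi^2 + P_Ci^2)   (pooled ingroup)
#   H_Sij = same, from subpopulation j's frequencies
#   N_STij = (H_Ti - H_Sij) / H_Ti
# and per gene, N_STj = mean of N_STij over the n segregating sites.
# Negative values are reported unmodified.

#' Per-site allele frequencies from IUPAC genotypes
#'
#' @param aln A gap-excluded `gene_alignment`.
#' @param site Original 1-based alignment column (must be retained).
#' @param members Sample ids to include (default: all members).
#' @return Named numeric vector `c(A=,T=,G=,C=)` summing to 1.
#' @export
site_allele_frequencies <- function(aln, site, members = NULL) {
  if (is.null(members)) members <- rownames(aln$seqs)
  idx <- site_index(aln, site)
  col <- aln$seqs[members, idx]
  w <- rowSums(vapply(col, iupac_weights, numeric(4)))
  total <- sum(w)
  if (total == 0)
    stop("all members missing (N) at site ", site, ": frequencies undefined",
         call. = FALSE)
  w / total
}

#' Heterozygosity from allele frequencies
#'
#' `1 - sum(p^2)`; 0 at a fixed site, at most 0.75 (four equifrequent alleles).
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return Heterozygosity in \[0, 0.75\].
#' @export
heterozygosity <- function(freqs) {
  stopifnot(all(freqs >= 0), abs(sum(freqs) - 1) < 1e-9)
  1 - sum(freqs^2)
}

#' Segregating sites of an ingroup alignment
#'
#' A column segregates when the pooled expanded-allele set (N ignored) has at
#' least two distinct bases; it is flagged heterozygous when at least one
#' sample carries a two-base code there.
#'
#' @param aln A gap-excluded `gene_alignment` of the ingroup samples.
#' @return Data frame with columns `site` (original coordinate) and
#'   `heterozygous` for each segregating column.
#' @export
segregating_sites <- function(aln) {
  seg <- logical(aln_length(aln))
  het <- logical(aln_length(aln))
  for (k in seq_len(aln_length(aln))) {
    col <- aln$seqs[, k]
    alleles <- unique(unlist(lapply(col[col != "N"], iupac_expand)))
    seg[k] <- length(alleles) >= 2
    het[k] <- any(vapply(col, is_het_code, logical(1)))
  }
  data.frame(site = aln$retained_columns[seg], heterozygous = het[seg])
}

#' Site-level N_ST between subpopulations
#'
#' @param aln A gap-excluded ingroup `gene_alignment`.
#' @param site Original 1-based column; must be segregating (H_T > 0).
#' @param partition Named character vector `sample_id -> subpopulation`
#'   (default: the alignment's `population` column).
#' @return List with `site`, `h_t`, and named vectors `h_s`, `nst` per
#'   subpopulation.
#' @export
nst_at_site <- function(aln, site, partition = NULL) {
  partition <- resolve_partition(aln, partition)
  pooled <- site_allele_frequencies(aln, site, members = names(partition))
  h_t <- heterozygosity(pooled)
  if (h_t == 0)
    stop("site ", site, " is monomorphic in the pooled ingroup", call. = FALSE)
  pops <- sort(unique(partition))
  h_s <- stats::setNames(numeric(length(pops)), pops)
  for (p in pops) {
    f <- site_allele_frequencies(aln, site, members = names(partition)[partition == p])
    h_s[p] <- heterozygosity(f)
  }
  list(site = site, h_t = h_t, h_s = h_s, nst = (h_t - h_s) / h_t)
}

#' Per-gene N_ST report
#'
#' Computes segregating and heterozygous site counts, the mutation rate
#' (percent of analyzed columns segregating), and N_ST per subpopulation
#' averaged over the segregating sites. A gene with no segregating site
#' reports N_ST = 0 for every subpopulation.
#'
#' @param aln A gap-excluded ingroup `gene_alignment`.
#' @param partition Named vector `sample_id -> subpopulation`; defaults to the
#'   alignment's `population` column. At least two subpopulations.
#' @return One-row data frame: `gene`, `length_bp`, `segregating_sites`,
#'   `heterozygous_sites`, `mutation_rate_pct` (numeric),
#'   `mutation_rate_label` (printed form), then one `nst_<pop>` column per
#'   subpopulation. The per-site table is attached as attribute `"sites"`.
#' @export
gene_nst <- function(aln, partition = NULL) {
  partition <- resolve_partition(aln, partition)
  pops <- sort(unique(partition))
  if (length(pops) < 2)
    stop("differentiation analysis needs >= 2 subpopulations", call. = FALSE)
  seg <- segregating_sites(subset_members(aln, ids = names(partition)))
  n <- nrow(seg)
  len <- aln_length(aln)
  if (n > 0) {
    per_site <- lapply(seg$site, function(s) nst_at_site(aln, s, partition))
    nst_j <- colMeans(do.call(rbind, lapply(per_site, `[[`, "nst")))
    site_tab <- data.frame(
      site = seg$site, heterozygous = seg$heterozygous,
      h_t = vapply(per_site, `[[`, numeric(1), "h_t"),
      do.call(rbind, lapply(per_site, `[[`, "nst")))
    names(site_tab)[-(1:3)] <- paste0("nst_", pops)
  } else {
    nst_j <- stats::setNames(numeric(length(pops)), pops)
    site_tab <- data.frame(site = integer(0), heterozygous = logical(0))
  }
  rate <- 100 * n / len
  out <- data.frame(gene = aln$gene, length_bp = len, segregating_sites = n,
                    heterozygous_sites = sum(seg$heterozygous),
                    mutation_rate_pct = rate,
                    mutation_rate_label = format_mutation_rate(rate),
                    stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("nst_", p)]] <- nst_j[[p]]
  attr(out, "sites") <- site_tab
  out
}

#' Format a mutation rate the way the report prints it
#'
#' Two decimal places with a trailing zero trimmed (at least one decimal
#' kept): 0.9972 -> "1.0", 1.6479 -> "1.65", 0.0746 -> "0.07".
#'
#' @param rate Numeric percentage.
#' @return Character label.
#' @export
format_mutation_rate <- function(rate) {
  lab <- formatC(round(rate, 2), format = "f", digits = 2)
  sub("(\\.\\d)0$", "\\1", lab)
}

# default partition = population labels of ingroup members; validates coverage
resolve_partition <- function(aln, partition) {
  if (is.null(partition)) {
    ing <- aln$meta$role == "ingroup"
    partition <- stats::setNames(aln$meta$population[ing], aln$meta$sample_id[ing])
  }
  if (length(partition) == 0) stop("empty partition", call. = FALSE)
  unknown <- setdiff(names(partition), rownames(aln$seqs))
  if (length(unknown) > 0)
    stop("partition names absent from alignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  partition
}
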