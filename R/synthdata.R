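# Synthetic two-breed + outgroup data with planted truth.
#
# Emulates the study design: two breeds of three diploid individuals each,
# direct-sequenced CDS alignments per gene where heterozygous positions carry
# IUPAC two-base codes, a wild-type reference, and Galliformes outgroups.
# Amino-acid mutations are planted at specified codons with specified
# carriers, zygosity, and ancestral presence in named outgroups; background
# polymorphism is strictly synonymous and avoids planted codons, so the
# amino-acid truth table is exact. Outgroups diverge by random substitution
# away from planted and background codons, keeping both the ancestral screen
# and the segregating-site truth exact (testability over realism).

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODON <- "TAA"

#' Specify a synthetic dataset
#'
#' @param genes Named integer vector: CDS length in bp per gene (multiples
#'   of 3, including start and stop codons).
#' @param breeds Named list of two character vectors: sample ids per breed.
#' @param reference Reference sample id.
#' @param outgroups Character vector of outgroup sample ids (possibly empty).
#' @param planted Data frame of planted amino-acid mutations with columns
#'   `gene`, `aa_pos`, `ref_aa`, `alt_aa`, `carriers` (comma-joined ids),
#'   `zygosity` (`het` or `hom`, applied to every carrier), `ancestral_in`
#'   (comma-joined outgroup ids, `""` for none).
#' @param background Data frame with columns `gene`, `n_het`, `n_hom`: counts
#'   of synonymous background segregating sites that are heterozygous
#'   (carriers get two-base codes) or homozygous (carriers get the alternate
#'   base outright).
#' @param divergence Expected substitutions per site between reference and
#'   each outgroup, in \[0, 0.3\]; transitions twice as likely as each
#'   transversion.
#' @param gap_columns Number of gap-bearing columns to splice in at random
#'   positions (each gapped in one random sample), to exercise gap exclusion.
#' @param seed Default RNG seed for [synth_generate()].
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(genes, breeds, reference = "REF",
                       outgroups = character(0), planted = NULL,
                       background = NULL, divergence = 0.05,
                       gap_columns = 0, seed = 20230120) {
  stopifnot(all(genes %% 3 == 0), all(genes >= 9),
            length(breeds) == 2, !is.null(names(breeds)),
            divergence >= 0, divergence <= 0.3)
  if (is.null(planted)) planted <- empty_planted()
  if (is.null(background))
    background <- data.frame(gene = names(genes), n_het = 0, n_hom = 0)
  planted$ancestral_in[is.na(planted$ancestral_in)] <- ""
  for (g in unique(planted$gene)) {
    p <- planted[planted$gene == g, ]
    if (anyDuplicated(p$aa_pos))
      stop("planted positions not distinct in gene ", g, call. = FALSE)
    if (any(p$aa_pos < 2 | p$aa_pos > genes[[g]] / 3 - 1))
      stop("planted position outside codons 2..", genes[[g]] / 3 - 1,
           " in gene ", g, call. = FALSE)
  }
  ingroup <- unlist(breeds, use.names = FALSE)
  for (i in seq_len(nrow(planted))) {
    ids <- strsplit(planted$carriers[i], ",")[[1]]
    if (length(setdiff(ids, ingroup)) > 0)
      stop("planted carriers not in ingroup: ",
           paste(setdiff(ids, ingroup), collapse = ", "), call. = FALSE)
    if (planted$zygosity[i] == "hom" && setequal(ids, ingroup))
      stop("homozygous mutation carried by every ingroup sample would not ",
           "segregate: ", planted$gene[i], " position ", planted$aa_pos[i],
           call. = FALSE)
  }
  bad_out <- setdiff(unlist(strsplit(planted$ancestral_in, ",")), c(outgroups, ""))
  if (length(bad_out) > 0)
    stop("ancestral_in names unknown outgroup(s): ",
         paste(bad_out, collapse = ", "), call. = FALSE)
  structure(list(genes = genes, breeds = breeds, reference = reference,
                 outgroups = outgroups, planted = planted,
                 background = background, divergence = divergence,
                 gap_columns = gap_columns, seed = seed),
            class = "synth_spec")
}

empty_planted <- function() {
  data.frame(gene = character(0), aa_pos = integer(0), ref_aa = character(0),
              alt_aa = character(0), carriers = character(0),
              zygosity = character(0), ancestral_in = character(0),
              stringsAsFactors = FALSE)
}

# smallest codon pair (ref, alt) differing at exactly one position with the
# requested translations; deterministic (lexicographic search)
choose_codon_pair <- function(ref_aa, alt_aa) {
  ref_codons <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == ref_aa])
  alt_codons <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == alt_aa])
  for (rc in ref_codons) {
    for (ac in alt_codons) {
      pos <- which(strsplit(rc, "")[[1]] != strsplit(ac, "")[[1]])
      if (length(pos) == 1) return(list(ref = rc, alt = ac, pos = pos))
    }
  }
  stop("no single-nucleotide codon change from ", ref_aa, " to ", alt_aa,
       call. = FALSE)
}

# synonymous single-nucleotide variants of a codon: list of (pos, base)
syn_variants <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  chars <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (b in setdiff(.BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      if (Biostrings::GENETIC_CODE[[paste(alt, collapse = "")]] == aa)
        out[[length(out) + 1]] <- list(pos = pos, base = b)
    }
  }
  out
}

#' Generate a synthetic dataset from a spec
#'
#' Byte-identical output for identical (spec, seed).
#'
#' @param spec A `synth_spec`.
#' @param seed RNG seed; defaults to the spec's.
#' @return List with `alignments` (named list of `gene_alignment`, all roles
#'   included), `sample_sheet`, `topology` (synthetic annotation placing the
#'   planted regions), `frame_start` (named vector, original column of the
#'   initiator ATG per gene), and `truth` (list `mutations`, `per_gene`); the
#'   per-gene table carries segregating/heterozygous counts and N_ST values
#'   from the internal brute-force oracle.
#' @export
synth_generate <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  breeds <- spec$breeds
  ingroup <- unlist(breeds, use.names = FALSE)
  all_ids <- c(ingroup, spec$reference, spec$outgroups)
  sheet <- data.frame(
    sample_id = all_ids,
    population = c(rep(names(breeds), lengths(breeds)), "reference",
                   rep("outgroup", length(spec$outgroups))),
    role = c(rep("ingroup", length(ingroup)), "reference",
             rep("outgroup", length(spec$outgroups))),
    stringsAsFactors = FALSE)

  alignments <- list()
  frame_start <- stats::setNames(integer(length(spec$genes)), names(spec$genes))
  truth_mut <- list()
  truth_gene <- list()
  partition <- stats::setNames(rep(names(breeds), lengths(breeds)), ingroup)

  for (g in names(spec$genes)) {
    len <- spec$genes[[g]]
    ncod <- len / 3
    codons <- c("ATG", sample(SENSE_CODONS, ncod - 2, replace = TRUE), STOP_CODON)
    ref_chars <- unlist(strsplit(codons, ""))

    planted <- spec$planted[spec$planted$gene == g, , drop = FALSE]
    # force reference codons at planted positions
    pair_of <- list()
    for (i in seq_len(nrow(planted))) {
      pair <- choose_codon_pair(planted$ref_aa[i], planted$alt_aa[i])
      pair_of[[i]] <- pair
      ref_chars[3 * (planted$aa_pos[i] - 1) + 1:3] <- strsplit(pair$ref, "")[[1]]
    }

    seqs <- matrix(rep(ref_chars, length(all_ids)), nrow = length(all_ids),
                   byrow = TRUE, dimnames = list(all_ids, NULL))
    used_codons <- c(1L, ncod, planted$aa_pos)
    n_het_sites <- 0L

    # planted amino-acid mutations
    for (i in seq_len(nrow(planted))) {
      pair <- pair_of[[i]]
      col <- 3 * (planted$aa_pos[i] - 1) + pair$pos
      ref_b <- substr(pair$ref, pair$pos, pair$pos)
      alt_b <- substr(pair$alt, pair$pos, pair$pos)
      carriers <- strsplit(planted$carriers[i], ",")[[1]]
      sym <- if (planted$zygosity[i] == "het") het_code_for(ref_b, alt_b) else alt_b
      seqs[carriers, col] <- sym
      if (planted$zygosity[i] == "het") n_het_sites <- n_het_sites + 1L
      anc <- setdiff(strsplit(planted$ancestral_in[i], ",")[[1]], "")
      if (length(anc) > 0)
        seqs[anc, 3 * (planted$aa_pos[i] - 1) + 1:3] <-
          matrix(rep(strsplit(pair$alt, "")[[1]], length(anc)),
                 nrow = length(anc), byrow = TRUE)
    }

    # synonymous background polymorphism away from planted codons
    bg <- spec$background[spec$background$gene == g, , drop = FALSE]
    n_bg_het <- if (nrow(bg) == 1) bg$n_het else 0L
    n_bg_hom <- if (nrow(bg) == 1) bg$n_hom else 0L
    for (kind in c(rep("het", n_bg_het), rep("hom", n_bg_hom))) {
      repeat {
        free <- setdiff(2:(ncod - 1), used_codons)
        if (length(free) == 0)
          stop("gene ", g, " too short for requested background sites",
               call. = FALSE)
        cod <- free[sample.int(length(free), 1)]
        ref_codon <- paste(ref_chars[3 * (cod - 1) + 1:3], collapse = "")
        vars <- syn_variants(ref_codon)
        if (length(vars) > 0) break
        used_codons <- c(used_codons, cod)  # no synonymous variant; skip it
      }
      used_codons <- c(used_codons, cod)
      v <- vars[[sample.int(length(vars), 1)]]
      col <- 3 * (cod - 1) + v$pos
      ref_b <- ref_chars[col]
      max_carriers <- if (kind == "het") length(ingroup) else length(ingroup) - 1
      carriers <- sample(ingroup, sample.int(max_carriers, 1))
      seqs[carriers, col] <- if (kind == "het") het_code_for(ref_b, v$base) else v$base
      if (kind == "het") n_het_sites <- n_het_sites + 1L
    }

    # outgroup divergence at untouched codons (transitions twice as likely)
    free_cols <- as.vector(vapply(setdiff(2:(ncod - 1), used_codons),
                                  function(cod) 3 * (cod - 1) + 1:3,
                                  numeric(3)))
    for (og in spec$outgroups) {
      hit <- free_cols[stats::runif(length(free_cols)) < spec$divergence]
      for (col in hit) {
        ref_b <- ref_chars[col]
        tv <- setdiff(.BASES, c(ref_b, TRANSITIONS[[ref_b]]))
        seqs[og, col] <- sample(c(TRANSITIONS[[ref_b]], tv), 1,
                                prob = c(0.5, 0.25, 0.25))
      }
    }

    # optional gap columns spliced at random positions
    fs <- 1L
    if (spec$gap_columns > 0) {
      total <- ncol(seqs) + spec$gap_columns
      gap_pos <- sort(sample.int(total, spec$gap_columns))
      full <- matrix("", nrow = nrow(seqs), ncol = total,
                     dimnames = list(all_ids, NULL))
      full[, setdiff(seq_len(total), gap_pos)] <- seqs
      for (p in gap_pos) {
        filler <- sample(.BASES, 1)
        full[, p] <- filler
        full[sample(all_ids, 1), p] <- "-"
      }
      seqs <- full
      fs <- which(!(seq_len(total) %in% gap_pos))[1]
    }
    frame_start[g] <- fs
    aln <- gene_alignment(g, seqs, sheet)
    alignments[[g]] <- aln

    # truth: per-gene counts and brute-force N_ST on the gap-excluded ingroup
    ing_aln <- subset_members(exclude_gap_columns(aln), role = "ingroup")
    oracle <- nst_oracle(ing_aln, partition)
    truth_gene[[g]] <- data.frame(
      gene = g, length_bp = len,
      segregating_sites = nrow(planted) + n_bg_het + n_bg_hom,
      heterozygous_sites = n_het_sites,
      t(stats::setNames(oracle$nst_by_pop,
                        paste0("nst_", names(oracle$nst_by_pop)))),
      stringsAsFactors = FALSE)

    # truth: expected mutation calls
    if (nrow(planted) > 0) {
      rows <- lapply(seq_len(nrow(planted)), function(i) {
        ids <- strsplit(planted$carriers[i], ",")[[1]]
        ids <- ingroup[ingroup %in% ids]
        carrier_breeds <- unique(partition[ids])
        cls <- if (length(carrier_breeds) == 2) "common" else
          paste0(carrier_breeds, "_specific")
        anc <- setdiff(strsplit(planted$ancestral_in[i], ",")[[1]], "")
        data.frame(
          gene = g, aa_pos = planted$aa_pos[i],
          ref_aa = planted$ref_aa[i], alt_aa = planted$alt_aa[i],
          label = paste0(planted$ref_aa[i], planted$aa_pos[i], planted$alt_aa[i]),
          carriers = paste(paste0(ids, ":", planted$zygosity[i]), collapse = ","),
          n_carriers = length(ids),
          n_het_carriers = if (planted$zygosity[i] == "het") length(ids) else 0L,
          breed_class = cls,
          fixed_in_breed = length(carrier_breeds) == 1 &&
            length(ids) == length(breeds[[carrier_breeds]]),
          individual_level = length(carrier_breeds) == 1 && length(ids) == 1,
          ancestry = if (length(spec$outgroups) == 0) "unscreened"
                     else if (length(anc) > 0) "ancestral_present" else "derived",
          stringsAsFactors = FALSE)
      })
      truth_mut[[g]] <- do.call(rbind, rows)
    }
  }

  truth_mutations <- if (length(truth_mut) > 0) do.call(rbind, truth_mut) else
    cbind(empty_planted()[0, c("gene", "aa_pos", "ref_aa", "alt_aa")],
          data.frame(label = character(0), carriers = character(0),
                     n_carriers = integer(0), n_het_carriers = integer(0),
                     breed_class = character(0), fixed_in_breed = logical(0),
                     individual_level = logical(0), ancestry = character(0)))
  topo <- synth_topology(spec)
  truth_mutations$region <- rep("unannotated", nrow(truth_mutations))
  truth_mutations <- annotate_region(truth_mutations, topo)
  truth_mutations$selected <-
    (truth_mutations$breed_class == "common" | truth_mutations$fixed_in_breed) &
    truth_mutations$ancestry == "derived" &
    truth_mutations$region != "outside" & truth_mutations$alt_aa != "*"
  ord <- order(match(truth_mutations$gene, names(spec$genes)),
               truth_mutations$aa_pos, truth_mutations$alt_aa)
  truth_mutations <- truth_mutations[ord, ]
  rownames(truth_mutations) <- NULL

  list(alignments = alignments, sample_sheet = sheet, topology = topo,
       frame_start = frame_start,
       truth = list(mutations = truth_mutations,
                    per_gene = do.call(rbind, truth_gene)))
}

# Synthetic membrane-topology annotation: every protein is one transmembrane
# segment except where the spec plants an extracellular mutation, which gets
# an enclosing "outside" segment.
synth_topology <- function(spec) {
  rows <- list()
  for (g in names(spec$genes)) {
    prot_len <- spec$genes[[g]] / 3 - 1
    rows[[g]] <- data.frame(gene = g, aa_start = 1, aa_end = prot_len,
                            region = "TMhelix", stringsAsFactors = FALSE)
  }
  topo <- do.call(rbind, rows)
  rownames(topo) <- NULL
  out <- attr(spec, "outside_positions")
  if (!is.null(out)) {
    for (i in seq_len(nrow(out))) {
      g <- out$gene[i]; p <- out$aa_pos[i]
      prot_len <- spec$genes[[g]] / 3 - 1
      seg <- topo[topo$gene != g, ]
      lo <- max(1, p - 10); hi <- min(prot_len, p + 10)
      add <- data.frame(gene = g,
                        aa_start = c(if (lo > 1) 1, lo, if (hi < prot_len) hi + 1),
                        aa_end = c(if (lo > 1) lo - 1, hi, if (hi < prot_len) prot_len),
                        region = c(if (lo > 1) "TMhelix", "outside",
                                   if (hi < prot_len) "TMhelix"))
      topo <- rbind(seg, add)
    }
    topo <- topo[order(match(topo$gene, names(spec$genes)), topo$aa_start), ]
    rownames(topo) <- NULL
  }
  validate_topology(topo)
}

#' Brute-force N_ST oracle
#'
#' Independent transcription of the heterozygosity and N_ST definitions,
#' counting diploid allele copies per sample (two per unambiguous base, one
#' per expanded base of a two-base code, none for N). Used to compute truth
#' tables and to cross-check [gene_nst()].
#'
#' @param aln Gap-excluded ingroup `gene_alignment`.
#' @param partition Named vector `sample_id -> subpopulation`.
#' @return List: `segregating` (original columns), `heterozygous` (count),
#'   `nst_by_pop` (named vector, 0 when no site segregates).
#' @export
nst_oracle <- function(aln, partition) {
  pops <- sort(unique(partition))
  count_copies <- function(symbols) {
    counts <- stats::setNames(numeric(4), .BASES)
    for (s in symbols) {
      if (s == "N" || s == "-") next
      exp <- iupac_expand(s)
      if (length(exp) == 1) counts[exp] <- counts[exp] + 2
      else for (b in exp) counts[b] <- counts[b] + 1
    }
    counts
  }
  seg_sites <- integer(0)
  het_count <- 0L
  nst_rows <- list()
  for (k in seq_len(aln_length(aln))) {
    col <- aln$seqs[names(partition), k]
    pooled <- count_copies(col)
    if (sum(pooled > 0) < 2) next
    seg_sites <- c(seg_sites, aln$retained_columns[k])
    if (any(col %in% c("R", "Y", "M", "K", "S", "W"))) het_count <- het_count + 1L
    p <- pooled / sum(pooled)
    h_t <- 1 - sum(p^2)
    nst <- stats::setNames(numeric(length(pops)), pops)
    for (pop in pops) {
      cnt <- count_copies(col[partition[names(partition)] == pop])
      q <- cnt / sum(cnt)
      h_s <- 1 - sum(q^2)
      nst[pop] <- (h_t - h_s) / h_t
    }
    nst_rows[[length(nst_rows) + 1]] <- nst
  }
  nst_by_pop <- if (length(nst_rows) > 0) colMeans(do.call(rbind, nst_rows))
                else stats::setNames(numeric(length(pops)), pops)
  list(segregating = seg_sites, heterozygous = het_count,
       nst_by_pop = nst_by_pop)
}

#' The study-shaped synthetic spec
#'
#' Nine adrenergic-receptor genes at the analyzed lengths, two breeds of three
#' hens each (egg-laying Shaver Brown N5/N6/N7; gamecock Shamo S6/S7/S9), a
#' Red Jungle Fowl reference, and five Galliformes outgroups. Twenty-four
#' amino-acid mutations are planted — 4 Shaver-specific, 13 Shamo-specific, 7
#' common — with carriers, zygosity (23 heterozygous, one homozygous),
#' ancestral presence, and extracellular positions arranged so that exactly 8
#' survive candidate selection. Background synonymous polymorphism brings the
#' per-gene segregating-site totals to 14, 9, 7, 22, 10, 1, 8, 9, 9 with
#' heterozygous-site counts 14, 6, 6, 22, 9, 1, 6, 9, 9.
#'
#' @param seed Default seed stored in the spec.
#' @return A `synth_spec`.
#' @export
study_spec <- function(seed = 20230120) {
  genes <- c(ADRA1A = 1404, ADRA1B = 1524, ADRA1D = 1536, ADRA2A = 1335,
             ADRA2B = 1038, ADRA2C = 1341, ADRB1 = 1434, ADRB2 = 1194,
             ADRB3 = 1314)
  breeds <- list(ShaverBrown = c("N5", "N6", "N7"),
                 Shamo = c("S6", "S7", "S9"))
  outgroups <- c("Gallus_gallus_gallus", "Coturnix_japonica",
                 "Meleagris_gallopavo", "Numida_meleagris",
                 "Phasianus_colchicus")
  P <- function(gene, aa_pos, ref, alt, carriers, zyg = "het", anc = "")
    data.frame(gene = gene, aa_pos = aa_pos, ref_aa = ref, alt_aa = alt,
               carriers = carriers, zygosity = zyg, ancestral_in = anc,
               stringsAsFactors = FALSE)
  planted <- rbind(
    # breed A (Shaver Brown) specific
    P("ADRA1A", 365, "S", "G", "N5,N6,N7"),
    P("ADRA1B", 258, "R", "Q", "N6,N7"),
    P("ADRA1B", 494, "V", "A", "N6,N7"),
    P("ADRB1", 444, "G", "S", "N6", anc = "Phasianus_colchicus"),
    # breed B (Shamo) specific
    P("ADRA1D", 58, "L", "W", "S6"),
    P("ADRA1D", 440, "T", "N", "S6,S7,S9"),
    P("ADRA2A", 296, "V", "I", "S7"),
    P("ADRA2B", 138, "R", "Q", "S6,S7"),
    P("ADRA2B", 210, "R", "H", "S9"),
    P("ADRA2B", 292, "V", "M", "S6,S7,S9", zyg = "hom"),
    P("ADRB1", 443, "N", "S", "S6,S7,S9"),
    P("ADRB1", 445, "S", "N", "S6,S7,S9"),
    P("ADRB1", 466, "R", "C", "S6,S7",
      anc = "Phasianus_colchicus,Meleagris_gallopavo"),
    P("ADRB2", 15, "A", "T", "S6,S7,S9"),
    P("ADRB2", 44, "T", "I", "S6,S7,S9", anc = "Phasianus_colchicus"),
    P("ADRB2", 232, "Q", "R", "S6,S7,S9", anc = "Phasianus_colchicus"),
    P("ADRB2", 277, "T", "M", "S6,S7"),
    # common to both breeds
    P("ADRA2A", 58, "V", "I", "N5,N7,S6,S9", anc = "Phasianus_colchicus"),
    P("ADRA2A", 273, "D", "E", "N5,N6,S7,S9"),
    P("ADRB1", 403, "R", "Q", "N5,N6,S6,S7", anc = "Numida_meleagris"),
    P("ADRB3", 342, "R", "C", "N5,N6,N7,S6,S7,S9"),
    P("ADRB3", 396, "S", "P", "N6,N7,S6,S9",
      anc = "Phasianus_colchicus,Coturnix_japonica"),
    P("ADRB3", 404, "Q", "L", "N5,N7,S7,S9"),
    P("ADRB3", 406, "P", "S", "N5,N6,N7,S6,S7,S9"))
  background <- data.frame(
    gene = names(genes),
    n_het = c(13, 4, 4, 19, 7, 1, 1, 5, 5),
    n_hom = c(0, 3, 1, 0, 0, 0, 2, 0, 0))
  spec <- synth_spec(genes, breeds, reference = "RJF", outgroups = outgroups,
                     planted = planted, background = background,
                     divergence = 0.05, seed = seed)
  attr(spec, "outside_positions") <- data.frame(
    gene = c("ADRA2B", "ADRB2"), aa_pos = c(292, 15))
  spec
}

#' Write a generated dataset to disk
#'
#' One FASTA per gene, a sample sheet, the topology annotation, and the truth
#' tables, all as plain text.
#'
#' @param gen Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(gen$alignments))
    write_gene_fasta(gen$alignments[[g]], file.path(dir, paste0(g, ".fasta")))
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(gen$sample_sheet, "samples.tsv")
  wt(gen$topology, "topology.tsv")
  wt(gen$truth$mutations, "truth_mutations.tsv")
  wt(gen$truth$per_gene, "truth_genes.tsv")
  invisible(dir)
}
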