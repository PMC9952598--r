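# Amino-acid mutation calling from heterozygous codons.
#
# A diploid sample directly sequenced carries IUPAC two-base codes at
# heterozygous positions; a codon with one ambiguous position therefore
# encodes up to two residues. Mutations are called per codon against a
# designated wild-type reference sample, aggregated per (position, alt
# residue), classified by breed-sharing pattern, screened against outgroup
# sequences for ancestral presence, and located in membrane-topology regions.
# Candidates for artificial selection are the breed-fixed or shared derived
# mutations not in the extracellular region.

#' Expand an IUPAC codon to its amino acids
#'
#' At most one ambiguous position is allowed; the residues of all unambiguous
#' codons in the expansion are returned (stop codons as `*`).
#'
#' @param codon Character vector of three IUPAC symbols, or a 3-character
#'   string.
#' @return Character vector of one-letter residues.
#' @export
expand_codon <- function(codon) {
  if (length(codon) == 1) codon <- strsplit(codon, "")[[1]]
  stopifnot(length(codon) == 3)
  codon <- normalize_symbols(codon, what = "codon")
  if (any(codon == "-")) stop("gap in codon", call. = FALSE)
  exps <- lapply(codon, iupac_expand)
  n_amb <- sum(lengths(exps) > 1)
  if (n_amb >= 2)
    stop("codon ", paste(codon, collapse = ""),
         " has >= 2 ambiguous positions", call. = FALSE)
  combos <- expand.grid(exps[[1]], exps[[2]], exps[[3]], stringsAsFactors = FALSE)
  codons <- apply(combos, 1, paste, collapse = "")
  unique(unname(Biostrings::GENETIC_CODE[codons]))
}

#' Call amino-acid mutations against a reference sample
#'
#' For each codon, each ingroup sample's expanded residue set is compared to
#' the reference residue. A sample carries a mutation when its set contains a
#' non-reference residue; zygosity is `het` when the set also contains the
#' reference residue or the codon is ambiguous, `hom` otherwise. Codons with
#' two or more ambiguous positions in a sample are flagged and excluded from
#' calls (attribute `"flagged"`), never combinatorially expanded.
#'
#' @param aln A gap-excluded `gene_alignment` containing the reference.
#' @param reference Sample id of the wild-type reference; its codons must be
#'   unambiguous.
#' @param frame_start Original alignment column of the initiator ATG
#'   (default 1). Codon positions are numbered 1-based from there.
#' @return Data frame of mutations: `gene`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   `label`, `carriers` (comma-joined `id:zygosity`), `n_carriers`,
#'   `n_het_carriers`, plus placeholder columns `breed_class`, `ancestry`,
#'   `region`, `selected` filled by the downstream steps.
#' @export
call_aa_mutations <- function(aln, reference, frame_start = 1) {
  if (!reference %in% rownames(aln$seqs))
    stop("reference sample '", reference, "' not in alignment", call. = FALSE)
  start_idx <- site_index(aln, frame_start)
  ncod <- (aln_length(aln) - start_idx + 1) %/% 3
  if ((aln_length(aln) - start_idx + 1) %% 3 != 0)
    stop("frame violation: ", aln_length(aln) - start_idx + 1,
         " columns from frame start is not a multiple of 3", call. = FALSE)
  ingroup <- aln$meta$sample_id[aln$meta$role == "ingroup"]
  calls <- list()
  flagged <- list()
  for (cod in seq_len(ncod)) {
    cols <- start_idx + 3 * (cod - 1) + 0:2
    ref_set <- tryCatch(expand_codon(aln$seqs[reference, cols]),
                        error = function(e) NULL)
    if (is.null(ref_set) || length(ref_set) != 1)
      stop("reference codon ambiguous at codon ", cod, call. = FALSE)
    ref_aa <- ref_set
    for (id in ingroup) {
      codon <- aln$seqs[id, cols]
      aas <- tryCatch(expand_codon(codon), error = function(e) e)
      if (inherits(aas, "error")) {
        flagged[[length(flagged) + 1]] <-
          data.frame(sample_id = id, aa_pos = cod,
                     codon = paste(codon, collapse = ""))
        next
      }
      alts <- setdiff(aas, ref_aa)
      for (alt in alts) {
        zyg <- if (ref_aa %in% aas || any(vapply(codon, function(s)
          length(iupac_expand(s)) > 1, logical(1)))) "het" else "hom"
        key <- paste(cod, alt, sep = "|")
        if (is.null(calls[[key]])) {
          calls[[key]] <- list(aa_pos = cod, ref_aa = ref_aa, alt_aa = alt,
                               carriers = character(0), zyg = character(0))
        }
        calls[[key]]$carriers <- c(calls[[key]]$carriers, id)
        calls[[key]]$zyg <- c(calls[[key]]$zyg, zyg)
      }
    }
  }
  out <- empty_mutation_table(aln$gene)
  if (length(calls) > 0) {
    ord <- order(vapply(calls, `[[`, numeric(1), "aa_pos"),
                 vapply(calls, `[[`, character(1), "alt_aa"))
    rows <- lapply(calls[ord], function(m) {
      data.frame(
        gene = aln$gene, aa_pos = m$aa_pos, ref_aa = m$ref_aa, alt_aa = m$alt_aa,
        label = paste0(m$ref_aa, m$aa_pos, m$alt_aa),
        carriers = paste(paste0(m$carriers, ":", m$zyg), collapse = ","),
        n_carriers = length(m$carriers),
        n_het_carriers = sum(m$zyg == "het"),
        breed_class = NA_character_, ancestry = "unscreened",
        region = "unannotated", selected = NA,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "flagged") <- if (length(flagged) > 0) do.call(rbind, flagged) else
    data.frame(sample_id = character(0), aa_pos = integer(0), codon = character(0))
  out
}

empty_mutation_table <- function(gene = character(0)) {
  data.frame(gene = gene[0], aa_pos = integer(0), ref_aa = character(0),
             alt_aa = character(0), label = character(0),
             carriers = character(0), n_carriers = integer(0),
             n_het_carriers = integer(0), breed_class = character(0),
             ancestry = character(0), region = character(0),
             selected = logical(0), stringsAsFactors = FALSE)
}

# parse "id:zyg,id:zyg" -> named character vector id -> zyg
parse_carriers <- function(carriers) {
  if (carriers == "") return(stats::setNames(character(0), character(0)))
  parts <- strsplit(strsplit(carriers, ",")[[1]], ":")
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

#' Classify mutations by breed-sharing pattern
#'
#' Carriers confined to one subpopulation give `<breed>_specific`; carriers in
#' both give `common`. Breed-specific mutations also get `fixed_in_breed`
#' (carried by every sample of that breed) and `individual_level` (exactly one
#' carrier) flags, which drive candidate selection.
#'
#' @param muts Mutation table from [call_aa_mutations()].
#' @param partition Named vector `sample_id -> breed`; exactly two breeds.
#' @return The table with `breed_class`, `fixed_in_breed`, `individual_level`
#'   filled in.
#' @export
classify_mutations <- function(muts, partition) {
  breeds <- sort(unique(partition))
  if (length(breeds) != 2)
    stop("classification requires exactly two subpopulations", call. = FALSE)
  n_by_breed <- table(partition)
  muts$fixed_in_breed <- FALSE
  muts$individual_level <- FALSE
  for (i in seq_len(nrow(muts))) {
    ids <- names(parse_carriers(muts$carriers[i]))
    if (length(ids) == 0) stop("mutation ", muts$label[i], " has no carriers")
    unknown <- setdiff(ids, names(partition))
    if (length(unknown) > 0)
      stop("carrier(s) not in partition: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    carrier_breeds <- unique(partition[ids])
    if (length(carrier_breeds) == 2) {
      muts$breed_class[i] <- "common"
    } else {
      b <- carrier_breeds
      muts$breed_class[i] <- paste0(b, "_specific")
      muts$fixed_in_breed[i] <- length(ids) == n_by_breed[[b]]
      muts$individual_level[i] <- length(ids) == 1
    }
  }
  muts
}

#' Screen mutations for ancestral presence in outgroups
#'
#' A mutation is `ancestral_present` when any outgroup sample's expanded
#' residue set at the codon contains the alternate residue, `derived` when at
#' least one outgroup covers the codon but none carries it, and `unscreened`
#' when no outgroup covers the position (N or gap in the codon, codon beyond
#' the outgroup sequence, or no outgroups supplied).
#'
#' @param muts Mutation table.
#' @param outgroup_aln `gene_alignment` of outgroup samples aligned to the
#'   same codon coordinates, or NULL.
#' @param frame_start Original column of the initiator ATG (default 1).
#' @return The table with `ancestry` filled in.
#' @export
screen_ancestral <- function(muts, outgroup_aln, frame_start = 1) {
  if (nrow(muts) == 0) return(muts)
  start_idx <- if (is.null(outgroup_aln)) NA_integer_ else
    tryCatch(site_index(outgroup_aln, frame_start), error = function(e) NA_integer_)
  for (i in seq_len(nrow(muts))) {
    muts$ancestry[i] <- "unscreened"
    if (is.null(outgroup_aln) || is.na(start_idx)) next
    idx <- start_idx + 3 * (muts$aa_pos[i] - 1) + 0:2
    if (any(idx > aln_length(outgroup_aln))) next
    covered <- FALSE
    present <- FALSE
    for (id in rownames(outgroup_aln$seqs)) {
      codon <- outgroup_aln$seqs[id, idx]
      if (any(codon %in% c("N", "-"))) next
      aas <- tryCatch(expand_codon(codon), error = function(e) NULL)
      if (is.null(aas)) next
      covered <- TRUE
      if (muts$alt_aa[i] %in% aas) present <- TRUE
    }
    muts$ancestry[i] <- if (present) "ancestral_present"
                        else if (covered) "derived" else "unscreened"
  }
  muts
}

#' Read a membrane-topology annotation table
#'
#' @param path TSV with columns `gene`, `aa_start`, `aa_end`, `region`
#'   (`inside`, `TMhelix`, `outside`); 1-based inclusive, non-overlapping
#'   intervals per gene.
#' @return Data frame, validated.
#' @export
read_topology <- function(path) {
  topo <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_topology(topo)
}

#' @rdname read_topology
#' @param topo Topology data frame to validate.
#' @export
validate_topology <- function(topo) {
  req <- c("gene", "aa_start", "aa_end", "region")
  if (!all(req %in% names(topo)))
    stop("topology table needs columns ", paste(req, collapse = ", "))
  bad <- setdiff(unique(topo$region), c("inside", "TMhelix", "outside"))
  if (length(bad) > 0) stop("unknown region(s): ", paste(bad, collapse = ", "))
  for (g in unique(topo$gene)) {
    seg <- topo[topo$gene == g, ]
    seg <- seg[order(seg$aa_start), ]
    if (any(seg$aa_end < seg$aa_start) ||
        any(seg$aa_start[-1] <= seg$aa_end[-nrow(seg)]))
      stop("overlapping or inverted topology segments for gene ", g,
           call. = FALSE)
  }
  topo
}

#' Annotate mutations with membrane-topology regions
#'
#' @param muts Mutation table.
#' @param topo Topology data frame (see [read_topology()]), or NULL to leave
#'   every mutation `unannotated`.
#' @return The table with `region` filled in.
#' @export
annotate_region <- function(muts, topo) {
  if (nrow(muts) == 0 || is.null(topo)) return(muts)
  topo <- validate_topology(topo)
  for (i in seq_len(nrow(muts))) {
    seg <- topo[topo$gene == muts$gene[i] &
                topo$aa_start <= muts$aa_pos[i] &
                topo$aa_end >= muts$aa_pos[i], ]
    muts$region[i] <- if (nrow(seg) == 1) seg$region else "unannotated"
  }
  muts
}

#' Select candidate mutations under artificial selection
#'
#' Retains mutations that are (breed-specific and carried by every sample of
#' that breed, or common to both breeds), absent from all outgroups
#' (`derived`), not in the extracellular region, and not a stop-codon gain.
#' Individual-level and partially shared breed-specific mutations are
#' excluded as possible individual (non-breed) differences.
#'
#' @param muts Classified, screened, annotated mutation table.
#' @return The table with `selected` filled in.
#' @export
select_candidates <- function(muts) {
  if (nrow(muts) == 0) return(muts)
  muts$selected <- (muts$breed_class == "common" | muts$fixed_in_breed) &
    muts$ancestry == "derived" &
    muts$region != "outside" &
    muts$alt_aa != "*"
  muts
}
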