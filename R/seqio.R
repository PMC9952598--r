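# Gene alignments: reading, writing, gap-column exclusion.
#
# A gene_alignment holds equal-length IUPAC sequences for one gene across
# samples, as a character matrix (rows = samples), plus a metadata table
# (sample_id, population, role) and a map from current column index to the
# original 1-based alignment column. All reported coordinates are original
# alignment coordinates via that map.

#' Construct a gene alignment
#'
#' @param gene Gene name.
#' @param seqs Character matrix of IUPAC symbols, rows named by sample_id,
#'   or a named list/vector of sequence strings.
#' @param meta Data frame with columns `sample_id`, `population`, `role`
#'   (role one of `ingroup`, `reference`, `outgroup`). Rows are matched to
#'   sequences by `sample_id`.
#' @param retained_columns Integer vector mapping current column index to the
#'   original 1-based column (default: identity).
#' @return Object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, seqs, meta, retained_columns = NULL) {
  if (!is.matrix(seqs)) {
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
    lens <- lengths(chars)
    if (length(unique(lens)) > 1) {
      short <- names(chars)[which(lens != max(lens))[1]]
      stop("ragged alignment: record '", short, "' has length ",
           lens[[short]], ", expected ", max(lens), call. = FALSE)
    }
    seqs <- do.call(rbind, chars)
    rownames(seqs) <- names(chars)
  }
  if (is.null(rownames(seqs))) stop("sequences must be named by sample_id")
  if (ncol(seqs) == 0) stop("empty alignment for gene ", gene)
  for (i in seq_len(nrow(seqs))) {
    seqs[i, ] <- normalize_symbols(seqs[i, ],
                                   what = paste0("record '", rownames(seqs)[i], "'"))
  }
  if (anyDuplicated(rownames(seqs)))
    stop("duplicate sample_id in gene ", gene, call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "role")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns sample_id, population, role")
  missing_meta <- setdiff(rownames(seqs), meta$sample_id)
  if (length(missing_meta) > 0)
    stop("no metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  bad_role <- setdiff(unique(meta$role), c("ingroup", "reference", "outgroup"))
  if (length(bad_role) > 0)
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  meta <- meta[match(rownames(seqs), meta$sample_id), req]
  rownames(meta) <- NULL
  if (is.null(retained_columns)) retained_columns <- seq_len(ncol(seqs))
  stopifnot(length(retained_columns) == ncol(seqs))
  structure(
    list(gene = gene, seqs = seqs, meta = meta,
         retained_columns = as.integer(retained_columns)),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment '", x$gene, "': ", nrow(x$seqs), " samples x ",
      ncol(x$seqs), " columns (",
      sum(x$meta$role == "ingroup"), " ingroup, ",
      sum(x$meta$role == "reference"), " reference, ",
      sum(x$meta$role == "outgroup"), " outgroup)\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `gene_alignment`.
#' @export
aln_length <- function(aln) ncol(aln$seqs)

#' Subset an alignment to samples by id or role
#'
#' @param aln A `gene_alignment`.
#' @param ids Sample ids to keep (optional).
#' @param role Roles to keep (optional).
#' @return A `gene_alignment` with the selected members.
#' @export
subset_members <- function(aln, ids = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(aln$seqs))
  if (!is.null(ids)) keep <- keep & rownames(aln$seqs) %in% ids
  if (!is.null(role)) keep <- keep & aln$meta$role %in% role
  if (!any(keep)) stop("subset leaves no members")
  gene_alignment(aln$gene, aln$seqs[keep, , drop = FALSE],
                 aln$meta[keep, , drop = FALSE], aln$retained_columns)
}

#' Read a per-gene FASTA into a gene alignment
#'
#' Records must be pre-aligned (equal length). Headers must contain the
#' sample_id as their first whitespace-delimited token; all other metadata
#' comes from the sample sheet.
#'
#' @param path FASTA file path.
#' @param meta Sample sheet data frame (`sample_id`, `population`, `role`),
#'   e.g. from [read_sample_sheet()].
#' @param gene Gene name; defaults to the file name without extension.
#' @return A `gene_alignment`.
#' @export
read_gene_fasta <- function(path, meta, gene = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene)) gene <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  seqs <- stats::setNames(as.character(ss), ids)
  gene_alignment(gene, seqs, meta)
}

#' Write a gene alignment to FASTA
#'
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @export
write_gene_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(apply(aln$seqs, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `population`, `role`.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Exclude columns containing gaps in any member
#'
#' Columns with a gap in any sequence are removed from the analysis; the
#' returned alignment's `retained_columns` maps each surviving column back to
#' its original 1-based coordinate, so downstream reports always cite
#' original-alignment positions. Idempotent.
#'
#' @param aln A `gene_alignment`.
#' @return A `gene_alignment` with gap-free columns only.
#' @export
exclude_gap_columns <- function(aln) {
  gapped <- apply(aln$seqs == "-", 2, any)
  if (all(gapped)) stop("every column contains a gap; empty alignment",
                        call. = FALSE)
  gene_alignment(aln$gene, aln$seqs[, !gapped, drop = FALSE], aln$meta,
                 aln$retained_columns[!gapped])
}

#' Write the retained-column map as TSV
#'
#' @param aln A `gene_alignment` (typically post gap exclusion).
#' @param path Output path.
#' @export
write_column_map <- function(aln, path) {
  utils::write.table(
    data.frame(column = seq_len(aln_length(aln)),
               original_column = aln$retained_columns),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# original 1-based column -> current index; error if excluded/out of range
site_index <- function(aln, site) {
  idx <- match(site, aln$retained_columns)
  if (is.na(idx)) stop("site ", site, " is not a retained column", call. = FALSE)
  idx
}
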