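# End-to-end analysis: per gene, gap exclusion -> N_ST report -> mutation
# calling, classification, ancestral screen, topology filter, candidate
# selection -> bootstrap UPGMA tree. Emits the study's report surfaces:
# a per-gene differentiation table, the full and selected mutation tables,
# and one Newick tree per gene, plus a JSON run manifest.

#' Build a run configuration
#'
#' @param gene_fastas Named character vector of per-gene FASTA paths, or a
#'   named list of ready `gene_alignment` objects.
#' @param sample_sheet Path to a TSV sample sheet or a data frame
#'   (`sample_id`, `population`, `role`).
#' @param reference Reference sample id (wild-type background for mutation
#'   calls; excluded from ingroup frequency computations).
#' @param topology Path to a topology TSV, a data frame, or NULL (regions left
#'   unannotated; the selection rule then ignores the region criterion).
#' @param frame_start Named vector: original alignment column of the initiator
#'   ATG per gene (default 1 for all).
#' @param bootstrap Bootstrap replicate count for the trees.
#' @param seed RNG seed for the bootstrap.
#' @param out_dir Output directory, or NULL to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(gene_fastas, sample_sheet, reference,
                       topology = NULL, frame_start = NULL,
                       bootstrap = 1000, seed = 20230120, out_dir = NULL) {
  structure(list(gene_fastas = gene_fastas, sample_sheet = sample_sheet,
                 reference = reference, topology = topology,
                 frame_start = frame_start, bootstrap = bootstrap,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, gene, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for gene ", gene, ": ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full analysis
#'
#' @param cfg A `run_config`.
#' @return List with `nst_report` (one row per gene), `mutations` (all calls),
#'   `selected` (retained candidates), `trees` (named list of `upgma_tree`),
#'   and `manifest`. Written to `cfg$out_dir` when set: `nst_report.tsv`,
#'   `mutations.tsv`, `selected.tsv`, `<gene>.nwk`, `manifest.json`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sheet <- if (is.character(cfg$sample_sheet)) read_sample_sheet(cfg$sample_sheet)
           else cfg$sample_sheet
  topo <- if (is.null(cfg$topology)) NULL
          else if (is.character(cfg$topology)) read_topology(cfg$topology)
          else validate_topology(cfg$topology)
  if (is.null(topo))
    warning("no topology annotation: regions unannotated, ",
            "selection ignores the region criterion")
  genes <- names(cfg$gene_fastas)
  if (is.null(genes)) stop("gene_fastas must be named by gene")

  nst_rows <- list(); mut_rows <- list(); trees <- list()
  for (g in genes) {
    aln <- stage("read", g, {
      x <- cfg$gene_fastas[[g]]
      if (inherits(x, "gene_alignment")) x else read_gene_fasta(x, sheet, gene = g)
    })
    aln <- stage("gap_exclusion", g, exclude_gap_columns(aln))
    fs <- if (is.null(cfg$frame_start)) 1L else cfg$frame_start[[g]]
    ingroup <- stage("subset", g, subset_members(aln, role = "ingroup"))

    nst_rows[[g]] <- stage("nst", g, gene_nst(ingroup))

    muts <- stage("mutation_calling", g,
                  call_aa_mutations(aln, cfg$reference, frame_start = fs))
    if (nrow(muts) > 0) {
      partition <- stats::setNames(
        ingroup$meta$population, ingroup$meta$sample_id)
      muts <- stage("classification", g, classify_mutations(muts, partition))
      og <- if (any(aln$meta$role == "outgroup"))
        subset_members(aln, role = "outgroup") else NULL
      muts <- stage("ancestral_screen", g,
                    screen_ancestral(muts, og, frame_start = fs))
      muts <- stage("topology_annotation", g, annotate_region(muts, topo))
      muts <- stage("selection", g, select_candidates(muts))
      mut_rows[[g]] <- muts
    }

    trees[[g]] <- stage("phylogeny", g,
                        bootstrap_upgma(aln, B = cfg$bootstrap, seed = cfg$seed))
  }

  nst_report <- do.call(rbind, nst_rows)
  rownames(nst_report) <- NULL
  mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else
    empty_mutation_table()
  rownames(mutations) <- NULL
  selected <- mutations[which(mutations$selected), , drop = FALSE]
  manifest <- list(reference = cfg$reference, bootstrap = cfg$bootstrap,
                   seed = cfg$seed, genes = genes,
                   n_samples = nrow(sheet),
                   package_version = as.character(utils::packageVersion("breeddiff")))
  out <- list(nst_report = nst_report, mutations = mutations,
              selected = selected, trees = trees, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_reports(out, cfg$out_dir)
  out
}

write_reports <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(out$nst_report, "nst_report.tsv")
  wt(out$mutations, "mutations.tsv")
  wt(out$selected, "selected.tsv")
  for (g in names(out$trees))
    writeLines(to_newick(out$trees[[g]]), file.path(dir, paste0(g, ".nwk")))
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
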