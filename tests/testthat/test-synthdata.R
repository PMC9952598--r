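# Synthetic-data generator: determinism, planted-truth recovery, oracle
# agreement, gap exercise, study-shaped defaults.

test_that("identical spec and seed give byte-identical output", {
  spec <- synth_spec(c(geneA = 90), list(b1 = c("x1", "x2"), b2 = c("y1", "y2")),
                     reference = "REF", outgroups = "og1",
                     planted = data.frame(gene = "geneA", aa_pos = 5,
                                          ref_aa = "S", alt_aa = "G",
                                          carriers = "x1,x2", zygosity = "het",
                                          ancestral_in = ""),
                     background = data.frame(gene = "geneA", n_het = 2, n_hom = 1))
  g1 <- synth_generate(spec, seed = 4)
  g2 <- synth_generate(spec, seed = 4)
  expect_identical(g1$alignments$geneA$seqs, g2$alignments$geneA$seqs)
  expect_identical(g1$truth, g2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_write(g1, d1); synth_write(g2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  g3 <- synth_generate(spec, seed = 5)
  expect_false(identical(g1$alignments$geneA$seqs, g3$alignments$geneA$seqs))
})

test_that("construction guarantees hold on a minimal planted spec", {
  spec <- synth_spec(c(g = 300), list(brown = c("n1", "n2", "n3"),
                                      shamo = c("s1", "s2", "s3")),
                     reference = "REF", outgroups = c("pheasant", "turkey"),
                     planted = data.frame(gene = "g", aa_pos = 40,
                                          ref_aa = "S", alt_aa = "G",
                                          carriers = "n1,n2,n3",
                                          zygosity = "het", ancestral_in = ""))
  gen <- synth_generate(spec, seed = 1)
  ing <- subset_members(gen$alignments$g, role = "ingroup")
  seg <- segregating_sites(ing)
  expect_equal(nrow(seg), 1)
  expect_true(seg$heterozygous)
  muts <- recover_mutations(gen, "g")
  expect_equal(nrow(muts), 1)
  expect_equal(muts$label, "S40G")
  expect_equal(muts$n_carriers, 3)
  expect_equal(muts$n_het_carriers, 3)
  expect_equal(muts$ancestry, "derived")
  expect_true(muts$selected)

  # planting the alternate residue in an outgroup flips the screen verdict
  spec2 <- synth_spec(c(g = 300), list(brown = c("n1", "n2", "n3"),
                                       shamo = c("s1", "s2", "s3")),
                      reference = "REF", outgroups = c("pheasant", "turkey"),
                      planted = data.frame(gene = "g", aa_pos = 40,
                                           ref_aa = "S", alt_aa = "G",
                                           carriers = "n1,n2,n3",
                                           zygosity = "het",
                                           ancestral_in = "pheasant"))
  gen2 <- synth_generate(spec2, seed = 1)
  muts2 <- recover_mutations(gen2, "g")
  expect_equal(muts2$ancestry, "ancestral_present")
  expect_false(muts2$selected)
})

test_that("invalid specs are rejected", {
  breeds <- list(b1 = c("x1", "x2"), b2 = c("y1", "y2"))
  expect_error(synth_spec(c(g = 100), breeds), "3")
  dup <- data.frame(gene = "g", aa_pos = c(4, 4), ref_aa = "S", alt_aa = "G",
                    carriers = "x1", zygosity = "het", ancestral_in = "")
  expect_error(synth_spec(c(g = 90), breeds, planted = dup), "distinct")
  hom_all <- data.frame(gene = "g", aa_pos = 4, ref_aa = "S", alt_aa = "G",
                        carriers = "x1,x2,y1,y2", zygosity = "hom",
                        ancestral_in = "")
  expect_error(synth_spec(c(g = 90), breeds, planted = hom_all),
               "would not segregate")
  bad_og <- data.frame(gene = "g", aa_pos = 4, ref_aa = "S", alt_aa = "G",
                       carriers = "x1", zygosity = "het",
                       ancestral_in = "nosuch")
  expect_error(synth_spec(c(g = 90), breeds, planted = bad_og), "outgroup")
  imp <- synth_spec(c(g = 90), breeds,
                    planted = data.frame(gene = "g", aa_pos = 4, ref_aa = "M",
                                         alt_aa = "W", carriers = "x1",
                                         zygosity = "het", ancestral_in = ""))
  expect_error(synth_generate(imp, seed = 1), "codon")
})

test_that("the pipeline recovers planted truth exactly on random specs", {
  set.seed(300)
  cols <- c("gene", "aa_pos", "ref_aa", "alt_aa", "label", "carriers",
            "n_carriers", "n_het_carriers", "breed_class", "fixed_in_breed",
            "individual_level", "ancestry", "region", "selected")
  for (rep in 1:15) {
    spec <- random_synth_spec()
    gen <- synth_generate(spec, seed = rep)
    got <- do.call(rbind, lapply(names(gen$alignments),
                                 function(g) recover_mutations(gen, g)))
    truth <- gen$truth$mutations
    if (is.null(got) || nrow(got) == 0) {
      expect_equal(nrow(truth), 0)
      next
    }
    ord <- order(match(got$gene, names(spec$genes)), got$aa_pos, got$alt_aa)
    got <- got[ord, cols]
    rownames(got) <- NULL
    expect_equal(got, truth[, cols], ignore_attr = TRUE)
    # segregating-site truth
    for (g in names(gen$alignments)) {
      ing <- subset_members(exclude_gap_columns(gen$alignments[[g]]),
                            role = "ingroup")
      tg <- gen$truth$per_gene[gen$truth$per_gene$gene == g, ]
      seg <- segregating_sites(ing)
      expect_equal(nrow(seg), tg$segregating_sites)
      expect_equal(sum(seg$heterozygous), tg$heterozygous_sites)
    }
  }
})

test_that("popdiff agrees with the internal oracle on generated datasets", {
  set.seed(301)
  for (rep in 1:5) {
    gen <- synth_generate(random_synth_spec(), seed = 100 + rep)
    for (g in names(gen$alignments)) {
      ing <- subset_members(exclude_gap_columns(gen$alignments[[g]]),
                            role = "ingroup")
      partition <- stats::setNames(ing$meta$population, ing$meta$sample_id)
      r <- gene_nst(ing)
      o <- nst_oracle(ing, partition)
      for (p in unique(partition))
        expect_equal(r[[paste0("nst_", p)]], o$nst_by_pop[[p]],
                     tolerance = 1e-12)
    }
  }
})

test_that("requested gap columns exercise exclusion without breaking truth", {
  spec <- synth_spec(c(g = 240), list(brown = c("n1", "n2"),
                                      shamo = c("s1", "s2")),
                     reference = "REF", outgroups = "og",
                     planted = data.frame(gene = "g", aa_pos = 10,
                                          ref_aa = "R", alt_aa = "Q",
                                          carriers = "n1,n2", zygosity = "het",
                                          ancestral_in = ""),
                     background = data.frame(gene = "g", n_het = 2, n_hom = 0),
                     gap_columns = 7)
  gen <- synth_generate(spec, seed = 9)
  aln <- gen$alignments$g
  expect_equal(aln_length(aln), 247)
  expect_true(any(aln$seqs == "-"))
  clean <- exclude_gap_columns(aln)
  expect_equal(aln_length(clean), 240)
  muts <- recover_mutations(gen, "g")
  expect_equal(muts$label, "R10Q")
  expect_equal(muts$carriers, "n1:het,n2:het")
})

test_that("the study-shaped spec regenerates the published table shapes", {
  gen <- synth_generate(study_spec(), seed = 2)
  truth <- gen$truth$mutations
  expect_equal(nrow(truth), 24)
  expect_equal(as.integer(table(truth$breed_class)[
    c("ShaverBrown_specific", "Shamo_specific", "common")]), c(4L, 13L, 7L))
  expect_equal(sum(truth$n_het_carriers > 0), 23)
  expect_equal(sum(truth$selected), 8)
  expect_setequal(truth$label[truth$selected],
                  c("S365G", "T440N", "D273E", "N443S", "S445N",
                    "R342C", "Q404L", "P406S"))
  pg <- gen$truth$per_gene
  expect_equal(pg$segregating_sites, c(14, 9, 7, 22, 10, 1, 8, 9, 9))
  expect_equal(pg$heterozygous_sites, c(14, 6, 6, 22, 9, 1, 6, 9, 9))
  expect_equal(pg$length_bp, c(1404, 1524, 1536, 1335, 1038, 1341, 1434, 1194, 1314))
})
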