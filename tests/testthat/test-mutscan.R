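# Codon expansion, mutation calling, breed classification, ancestral
# screening, topology filtering, candidate selection.

# minimal two-breed + reference + outgroup alignment builder around one
# variable codon: ATG | codon | TAA
codon_aln <- function(ref_codon, sample_codons, outgroup_codons = NULL) {
  seqs <- c(REF = paste0("ATG", ref_codon, "TAA"))
  for (id in names(sample_codons))
    seqs[id] <- paste0("ATG", sample_codons[[id]], "TAA")
  roles <- c("reference", rep("ingroup", length(sample_codons)))
  pops <- c("reference", substr(names(sample_codons), 1, 1))
  if (!is.null(outgroup_codons)) {
    for (id in names(outgroup_codons))
      seqs[id] <- paste0("ATG", outgroup_codons[[id]], "TAA")
    roles <- c(roles, rep("outgroup", length(outgroup_codons)))
    pops <- c(pops, rep("outgroup", length(outgroup_codons)))
  }
  make_aln(seqs, populations = pops, roles = roles)
}

test_that("codon expansion translates each unambiguous expansion", {
  expect_equal(expand_codon("AGC"), "S")
  expect_setequal(expand_codon("RGC"), c("S", "G"))
  expect_setequal(expand_codon("TAM"), c("Y", "*"))  # stop included as '*'
  expect_error(expand_codon("RRC"), "ambiguous")
  expect_error(expand_codon("A-C"), "gap")
})

test_that("mutation calls report carriers with zygosity against the reference", {
  aln <- codon_aln("AGC", list(n1 = "RGC", n2 = "GGC", s1 = "AGC"))
  muts <- call_aa_mutations(aln, "REF")
  expect_equal(nrow(muts), 1)
  expect_equal(muts$label, "S2G")
  expect_equal(muts$ref_aa, "S")
  expect_equal(muts$alt_aa, "G")
  expect_equal(muts$carriers, "n1:het,n2:hom")
  expect_equal(muts$n_het_carriers, 1)

  none <- call_aa_mutations(codon_aln("AGC", list(n1 = "AGC", s1 = "AGC")), "REF")
  expect_equal(nrow(none), 0)
})

test_that("multi-ambiguous codons are flagged, never expanded", {
  aln <- codon_aln("AGC", list(n1 = "RRC", s1 = "AGC"))
  muts <- call_aa_mutations(aln, "REF")
  expect_equal(nrow(muts), 0)
  flagged <- attr(muts, "flagged")
  expect_equal(flagged$sample_id, "n1")
  expect_equal(flagged$aa_pos, 2)
})

test_that("ambiguous reference codons and frame violations are errors", {
  aln <- codon_aln("RGC", list(n1 = "AGC", s1 = "AGC"))
  expect_error(call_aa_mutations(aln, "REF"), "reference codon ambiguous")
  short <- make_aln(c(REF = "ATGA", n1 = "ATGA"),
                    populations = c("reference", "n"),
                    roles = c("reference", "ingroup"))
  expect_error(call_aa_mutations(short, "REF"), "frame")
  expect_error(call_aa_mutations(codon_aln("AGC", list(n1 = "AGC")), "nope"),
               "not in alignment")
})

test_that("breed classification separates specific, common, individual-level", {
  partition <- c(n1 = "brown", n2 = "brown", n3 = "brown",
                 s1 = "shamo", s2 = "shamo", s3 = "shamo")
  m <- function(carriers) {
    tab <- call_aa_mutations(
      codon_aln("AGC", stats::setNames(
        as.list(rep("RGC", length(carriers))), carriers)), "REF")
    classify_mutations(tab, partition)
  }
  all_brown <- m(c("n1", "n2", "n3"))
  expect_equal(all_brown$breed_class, "brown_specific")
  expect_true(all_brown$fixed_in_breed)
  expect_false(all_brown$individual_level)

  one_shamo <- m("s2")
  expect_equal(one_shamo$breed_class, "shamo_specific")
  expect_false(one_shamo$fixed_in_breed)
  expect_true(one_shamo$individual_level)

  two_brown <- m(c("n2", "n3"))
  expect_equal(two_brown$breed_class, "brown_specific")
  expect_false(two_brown$fixed_in_breed)
  expect_false(two_brown$individual_level)

  shared <- m(c("n1", "n2", "s1", "s2", "s3"))
  expect_equal(shared$breed_class, "common")

  expect_error(
    classify_mutations(m("s2"), partition[c("n1", "n2", "n3", "s1")]),
    "partition")
  expect_error(classify_mutations(all_brown, c(partition, x = "third")),
               "exactly two")
})

test_that("ancestral screen distinguishes present, derived, unscreened", {
  base <- codon_aln("AGC", list(n1 = "RGC", n2 = "RGC"),
                    outgroup_codons = list(pheasant = "GGC", quail = "AGC"))
  muts <- call_aa_mutations(base, "REF")
  og <- subset_members(base, role = "outgroup")
  expect_equal(screen_ancestral(muts, og)$ancestry, "ancestral_present")

  der <- codon_aln("AGC", list(n1 = "RGC"),
                   outgroup_codons = list(pheasant = "AGC"))
  muts2 <- call_aa_mutations(der, "REF")
  expect_equal(
    screen_ancestral(muts2, subset_members(der, role = "outgroup"))$ancestry,
    "derived")

  nn <- codon_aln("AGC", list(n1 = "RGC"),
                  outgroup_codons = list(pheasant = "NNN"))
  muts3 <- call_aa_mutations(nn, "REF")
  expect_equal(
    screen_ancestral(muts3, subset_members(nn, role = "outgroup"))$ancestry,
    "unscreened")
  expect_equal(screen_ancestral(muts3, NULL)$ancestry, "unscreened")
})

test_that("dropping outgroup data never turns ancestral_present into derived", {
  set.seed(77)
  for (rep in 1:10) {
    gen <- synth_generate(random_synth_spec(), seed = rep)
    for (g in names(gen$alignments)) {
      aln <- gen$alignments[[g]]
      muts <- call_aa_mutations(aln, "REF", frame_start = gen$frame_start[[g]])
      if (nrow(muts) == 0) next
      with_og <- screen_ancestral(
        muts, subset_members(aln, role = "outgroup"),
        frame_start = gen$frame_start[[g]])
      without <- screen_ancestral(muts, NULL)
      expect_true(all(without$ancestry == "unscreened"))
      expect_false(any(without$ancestry == "derived" &
                         with_og$ancestry == "ancestral_present"))
    }
  }
})

test_that("region lookup and the retention rule reproduce the filtering", {
  topo <- data.frame(gene = "g1",
                     aa_start = c(1, 10, 30), aa_end = c(9, 29, 40),
                     region = c("outside", "TMhelix", "inside"))
  muts <- data.frame(gene = "g1", aa_pos = c(2, 15, 35, 99),
                     ref_aa = "A", alt_aa = "T",
                     label = "x", carriers = "n1:het", n_carriers = 1L,
                     n_het_carriers = 1L, breed_class = "common",
                     ancestry = "derived", region = "unannotated",
                     selected = NA, fixed_in_breed = FALSE,
                     individual_level = FALSE)
  ann <- annotate_region(muts, topo)
  expect_equal(ann$region, c("outside", "TMhelix", "inside", "unannotated"))
  sel <- select_candidates(ann)
  expect_equal(sel$selected, c(FALSE, TRUE, TRUE, TRUE))

  bad <- data.frame(gene = "g1", aa_start = c(1, 5), aa_end = c(6, 9),
                    region = "inside")
  expect_error(validate_topology(bad), "overlapping")
})

test_that("selection keeps breed-fixed or common, derived, non-extracellular", {
  tab <- data.frame(
    gene = "g", aa_pos = 1:5, ref_aa = "A",
    alt_aa = c("T", "T", "T", "T", "*"),
    label = "x", carriers = "c:het", n_carriers = 1L, n_het_carriers = 1L,
    breed_class = c("brown_specific", "brown_specific", "common", "common", "common"),
    ancestry = c("derived", "ancestral_present", "derived", "derived", "derived"),
    region = c("TMhelix", "TMhelix", "outside", "unannotated", "inside"),
    selected = NA,
    fixed_in_breed = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    individual_level = FALSE)
  out <- select_candidates(tab)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_true(all(which(out$selected) %in% seq_len(nrow(tab))))
})
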