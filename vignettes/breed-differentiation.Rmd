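---
title: "Detecting artificial-selection signatures between chicken breeds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificial-selection signatures between chicken breeds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breeddiff)
```

## The problem

Domesticated chicken breeds kept under very different selection regimes — an
egg-laying line (Shaver Brown) and a cockfighting line (Shamo) — are expected
to accumulate breed-specific variants in genes tied to the selected behaviour,
such as the nine adrenergic-receptor (ADR) genes. With small panels (three
hens per breed) sequenced directly as diploids, heterozygous positions appear
in the consensus sequence as IUPAC two-base codes (R, Y, M, K, S, W) rather
than as phased genotypes. `breeddiff` implements an analysis chain built
around that data shape:

1. per-site allele frequencies and the N~ST~ index of nucleotide
   differentiation between the breed subpopulations;
2. amino-acid mutation calling from (mostly heterozygous) codons against a
   wild-type Red Jungle Fowl reference, classification by breed-sharing
   pattern, screening against Galliformes outgroups for ancestral presence,
   and filtering by membrane-topology region;
3. UPGMA phylogenies from Kimura two-parameter (K2P) distances with bootstrap
   supports.

## The differentiation model

Each sample is one diploid genotype. An unambiguous base contributes two
copies of that allele at a site; a two-base code contributes one copy of each
of its bases; N is missing data for that sample at that site (the site's
frequencies are renormalized over the remaining samples, and N alone never
makes a site segregating). Writing $P_A, P_T, P_G, P_C$ for the resulting
allele frequencies, heterozygosity at site $i$ is

$$H_i = 1 - (P_A^2 + P_T^2 + P_G^2 + P_C^2),$$

zero at a fixed site and at most 0.75. With $H_{T i}$ computed from the
pooled ingroup and $H_{S ij}$ from subpopulation $j$ alone,

$$N_{ST\,ij} = \frac{H_{T i} - H_{S ij}}{H_{T i}}, \qquad
  N_{ST\,j} = \frac{1}{n}\sum_{i=1}^{n} N_{ST\,ij},$$

where the average runs over the $n$ **segregating** sites of the gene only.
Averaging over all columns would shrink every value by the factor
(segregating sites / gene length) and could never reach the magnitudes the
statistic is meant to resolve; with no segregating site the gene reports 0
for every subpopulation rather than an undefined value. $N_{ST\,j} = 1$ means
subpopulation $j$ is fixed at every segregating site while the pooled sample
is polymorphic; negative values arise when a subpopulation is *more*
heterozygous than the pool and are reported unmodified — they are typically
small and not distinguishable from zero, but clamping them would bias the
gene averages.

A gene's mutation rate is $100 \cdot S / L$ (segregating sites over analyzed
columns, in percent). The report prints it at two decimals with a trailing
zero trimmed (`1.0`, `1.65`, `0.07`), matching how such tables are usually
typeset.

```{r nst-example}
aln <- gene_alignment(
  "toy",
  c(n1 = "ATGA", n2 = "ATGA", n3 = "ATGA",
    s1 = "RTGA", s2 = "RTGA", s3 = "RTGA"),
  data.frame(sample_id = c("n1", "n2", "n3", "s1", "s2", "s3"),
             population = rep(c("brown", "shamo"), each = 3),
             role = "ingroup"))
gene_nst(aln)[, c("segregating_sites", "nst_brown", "nst_shamo")]
```

Here the brown breed is fixed (A) at the single segregating site, so its
N~ST~ is 1; the uniformly heterozygous shamo breed is more diverse than the
pool, giving −1/3.

## Mutation calling and the candidate filter

Codons are read from the initiator ATG in original-alignment coordinates
(after gap-column exclusion, which drops any column gapped in any sequence
and keeps a map back to the original 1-based positions). A codon with one
ambiguous position expands to up to two residues; a sample carries a mutation
when its residue set contains a non-reference residue, with zygosity `het`
when the set still contains the reference residue (or the codon is
ambiguous) and `hom` otherwise. Codons with two or more ambiguous positions
are flagged and excluded rather than combinatorially expanded: they never
occur in well-behaved direct-sequencing data, and silent expansion would
invent phantom double mutants. Reference codons must be unambiguous; stop
gains are reported with `*` and never selected.

Classification against a two-breed partition is exhaustive and exclusive:
carriers in one breed give `<breed>_specific` (flagged `fixed_in_breed` when
every sample of that breed carries it, `individual_level` when exactly one
does), carriers in both give `common`. The ancestral screen checks whether
any outgroup's expanded residue set at the codon contains the alternate
residue (`ancestral_present`); if at least one outgroup covers the codon and
none carries it, the mutation is `derived`; with no coverage it stays
`unscreened`. Removing outgroup data can therefore only move a verdict to
`unscreened`, never manufacture `derived`.

Candidates of artificial selection are the mutations that are (breed-fixed
or common) **and** derived **and** not extracellular (`outside` in the
membrane-topology annotation; `unannotated` positions pass, and a run without
an annotation simply warns). Partially shared breed-specific mutations —
carried by two of three samples, say — keep their class in the full table but
are excluded from the candidate set as possible individual rather than breed
differences. This single rule set reproduces both the full 24-site table and
the 8-site candidate table of the study design from one pass.

## Phylogenies

Pairwise K2P distances use pairwise deletion: a site enters a pair's
comparison only when both symbols are plain bases. Expanding heterozygotes
into pseudo-haplotypes is not part of this analysis tradition, and with 1–22
polymorphic sites per ~1.0–1.5 kb gene, pairwise deletion loses almost
nothing. With transition proportion $P$ and transversion proportion $Q$,

$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with a saturation error when either log argument is non-positive. UPGMA
merges the closest pair, averaging distances weighted by cluster size (the
unweighted average over leaf pairs), node height = merge distance / 2, ties
broken on the smallest (row, column) index pair so reruns are byte-identical.
Bootstrap resamples columns with replacement, rebuilds K2P + UPGMA, and
scores each original internal node by the percentage of successful replicates
containing its leaf set; replicates with saturated distances are discarded
with a warning (the support denominator is the successful count), and more
than 50% discarded is an error. Every sample — both breeds, the reference,
and each outgroup — is a leaf; there is no consensus collapsing and no
rooting beyond UPGMA's inherent root.

## The synthetic-data generator

`study_spec()` encodes the study conditions: nine genes at the analyzed
lengths (1404–1536 bp), 2 breeds × 3 samples, a reference, five Galliformes
outgroups at 0.05 expected substitutions per site, 24 planted amino-acid
mutations (4 Shaver-specific, 13 Shamo-specific, 7 common; 23 heterozygous;
ancestral presence and the two extracellular positions set from the study's
narrative), and synonymous background polymorphism bringing the per-gene
segregating-site totals to 14, 9, 7, 22, 10, 1, 8, 9, 9. Where the study does
not pin a detail down, the spec fixes one realistic choice: the single
homozygous mutation is ADRA2B V292M, and the three breed-specific mutations
whose carrier counts are not narrated (ADRA2B R138Q, ADRB1 R466C, ADRB2
T277M) carry in two of three samples, so that exactly eight candidates
survive the filter.

Design choices that favour testability over realism, deliberately:

- **Background polymorphism is strictly synonymous** and avoids planted
  codons, so the amino-acid truth table is exact — every called mutation is a
  planted one.
- **Outgroup divergence avoids planted and background codons** (transitions
  twice as likely as each transversion, no indels); otherwise random outgroup
  substitutions could fabricate ancestral matches or extra segregating
  sites. Gap columns are only inserted on request (`gap_columns`), to
  exercise the exclusion logic in isolation.
- The per-gene truth includes N~ST~ values computed by `nst_oracle()`, an
  independent brute-force transcription of the definitions (explicit diploid
  allele-copy counting), against which the production `gene_nst()` is checked
  to 1e−12.

What the generator does **not** emulate: linkage between sites, realistic
site-frequency spectra, indels inside the CDS, sequencing error, or the
actual genotype configurations behind the study's N~ST~ values — background
carriers are random. Consequently the synthetic dataset reproduces the
*structural* results (mutation counts per class, heterozygosity pattern,
candidate set, segregating-site totals, printed mutation rates) exactly, but
its per-gene N~ST~ values are whatever the random background implies, not the
study's; tests that pass here say the estimator is correct, not that real
data would give any particular value.

## Numerical and scale choices

- Frequencies sum to 1 within 1e−9 validation tolerance; oracle-equivalence
  tests assert 1e−12; ultrametricity of UPGMA trees is checked at 1e−9.
- Branch lengths serialize at 10 significant digits; exact zeros (including
  IEEE −0 from zero-distance merges) print as `0`.
- The property suites run on small problems chosen to finish quickly while
  still exercising every code path: 1000 random alignments of ≤6 samples ×
  ≤30 bp for the oracle equivalence, 10–15 randomized synthetic specs of 1–3
  genes at 60–120 codons for truth recovery, and bootstrap checks at B =
  100. The analysis scripts run the full study shape with B = 1000.
- RNG: the generator and the bootstrap take explicit seeds, save and restore
  `.Random.seed`, and are byte-reproducible for a fixed seed.

## Limitations

- N~ST~ here comes with no significance test (none is defined for this
  design); values near zero, positive or negative, should be read as "no
  differentiation".
- The topology filter consumes a pre-computed annotation (e.g. TMHMM
  output); the package does not predict topology, fetch accessions, or run
  BLAST — outgroup FASTAs are user-supplied.
- Amino-acid numbering assumes the alignment starts at the initiator ATG
  (configurable via `frame_start`); partial CDS inputs must be trimmed or
  offset by the caller.
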