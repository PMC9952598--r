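# IUPAC nucleotide ambiguity model.
#
# Diploid individuals sequenced directly yield one chromatogram per gene;
# heterozygous positions appear as two-base ambiguity codes. Each symbol
# expands to the set of unambiguous bases it denotes, and each expanded base
# carries fractional allele weight 1/|expansion|, so an unambiguous call
# contributes its whole weight to one base and a heterozygote splits 0.5/0.5.
# N is missing data; '-' is an alignment gap.

.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
  K = c("G", "T"), S = c("C", "G"), W = c("A", "T"),
  N = c("A", "C", "G", "T"),
  `-` = character(0)
)

.IUPAC_SYMBOLS <- names(.IUPAC_EXPANSION)
.BASES <- c("A", "T", "G", "C")

#' Expand an IUPAC symbol to its unambiguous bases
#'
#' @param symbol Single character in `A,C,G,T,R,Y,M,K,S,W,N,-`.
#' @return Character vector of unambiguous bases (empty for a gap).
#' @examples
#' iupac_expand("R") # A G
#' @export
iupac_expand <- function(symbol) {
  exp <- .IUPAC_EXPANSION[[symbol]]
  if (is.null(exp)) stop("illegal IUPAC symbol: '", symbol, "'", call. = FALSE)
  exp
}

#' Fractional allele weights of an IUPAC symbol
#'
#' Each base in the expansion carries weight 1/|expansion|. N and gap return
#' an all-zero vector (missing data / no allele observed).
#'
#' @param symbol Single IUPAC character.
#' @return Named numeric vector over A, T, G, C.
#' @export
iupac_weights <- function(symbol) {
  w <- stats::setNames(numeric(4), .BASES)
  if (symbol %in% c("N", "-")) return(w)
  exp <- iupac_expand(symbol)
  w[exp] <- 1 / length(exp)
  w
}

# TRUE for the six two-base heterozygote codes
is_het_code <- function(symbol) symbol %in% c("R", "Y", "M", "K", "S", "W")

# Validate a character vector of symbols; returns normalized uppercase vector.
# U (RNA) is accepted and normalized to T. Stops naming the first bad position.
normalize_symbols <- function(x, what = "sequence") {
  x <- toupper(x)
  x[x == "U"] <- "T"
  bad <- which(!(x %in% .IUPAC_SYMBOLS))
  if (length(bad) > 0) {
    stop("illegal symbol '", x[bad[1]], "' in ", what,
         " at column ", bad[1], call. = FALSE)
  }
  x
}

# Map two-base genotype to its IUPAC code (used by the synthetic generator)
het_code_for <- function(b1, b2) {
  pair <- paste(sort(c(b1, b2)), collapse = "")
  code <- c(AG = "R", CT = "Y", AC = "M", GT = "K", CG = "S", AT = "W")[pair]
  if (is.na(code)) stop("no two-base code for ", b1, "/", b2, call. = FALSE)
  unname(code)
}
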