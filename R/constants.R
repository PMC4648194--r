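# Shared constants: alphabets, substitution matrix access, residue masses,
# and the fixed back-translation codon table.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

DNA4 <- c("A", "C", "G", "T")

# Average (not monoisotopic) residue masses in Da; water added once per chain.
AA_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01528

# Back-translation table: one fixed codon per residue (the most frequent
# codon in enterobacteria under translation table 11). Deterministic and
# invertible: translating any of these codons returns the source residue.
CODON_FOR_AA <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG"
)

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 amino-acid substitution matrix (24 x 24, including
#' the ambiguity codes B/Z/X and the stop symbol) as shipped by Biostrings.
#' Cached after first access.
#'
#' @return A symmetric numeric matrix with residue one-letter row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.rg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .rg_cache$blosum62 <- e$BLOSUM62
  }
  .rg_cache$blosum62
}

# Encode an amino-acid string as 1-based indices into the substitution
# matrix alphabet. Rejects characters outside that alphabet, reporting the
# first offending position.
aa_encode <- function(seq, alphabet = rownames(blosum62()), what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    abort(sprintf("non-standard residue '%s' at position %d in %s",
                  chars[pos], pos, what))
  }
  idx
}

# Strict 20-letter check used by the mutator (ambiguity codes not allowed).
check_aa20 <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0) {
    abort(sprintf("non-standard residue '%s' at position %d in %s",
                  chars[bad[1]], bad[1], what))
  }
  invisible(chars)
}

#' Molecular mass of a protein in kDa
#'
#' Sum of average residue masses plus one water, divided by 1000.
#'
#' @param seq Amino-acid string over the 20 standard residues.
#' @return Mass in kilodaltons.
#' @export
protein_mass_kda <- function(seq) {
  chars <- check_aa20(seq)
  unname(sum(AA_RESIDUE_MASS[chars]) + WATER_MASS) / 1000
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Translate a nucleotide ORF (length divisible by 3) under code 11;
# alternative start codons are reported as M.
translate_orf <- function(nt) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  ))
  if (substr(nt, 1, 3) %in% START_CODONS) substr(aa, 1, 1) <- "M"
  aa
}
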