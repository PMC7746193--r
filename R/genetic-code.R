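#' @keywords internal
"_PACKAGE"

# Standard genetic code, written out in full so that translation and codon
# SNV enumeration do not depend on an external table at run time. Stop is '*'.
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

NUCLEOTIDES <- c("A", "C", "G", "T")

# The 20 amino-acid one-letter codes, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Translate an in-frame nucleotide string
#'
#' @param nt character scalar over A/C/G/T, length divisible by 3.
#' @return character scalar of amino acids ('*' for stop codons).
#' @keywords internal
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- STANDARD_CODE[codons]
  if (anyNA(aa)) stop("illegal nucleotide in coding sequence", call. = FALSE)
  paste(aa, collapse = "")
}

# Lazily built lookup of all 64 codons x 9 single-nucleotide substitutions,
# with the consequence of each. Used by both variant classification and
# codon SNV enumeration so the two stay consistent.
.snv_env <- new.env(parent = emptyenv())

codon_snv_table <- function() {
  if (!is.null(.snv_env$tab)) return(.snv_env$tab)
  codons <- names(STANDARD_CODE)
  rows <- vector("list", 64L * 9L)
  k <- 0L
  for (cod in codons) {
    ref_aa <- STANDARD_CODE[[cod]]
    base <- strsplit(cod, "")[[1]]
    for (off in 1:3) {
      for (alt in setdiff(NUCLEOTIDES, base[off])) {
        mut <- base
        mut[off] <- alt
        alt_cod <- paste(mut, collapse = "")
        alt_aa <- STANDARD_CODE[[alt_cod]]
        cons <- if (alt_aa == ref_aa) "synonymous"
                else if (alt_aa == "*") "nonsense"
                else "missense"
        k <- k + 1L
        rows[[k]] <- data.frame(codon = cod, offset = off,
                                ref_nt = base[off], alt_nt = alt,
                                consequence = cons,
                                stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  .snv_env$tab <- tab
  tab
}
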