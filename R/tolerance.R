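# Per-residue dN/dS mutational-tolerance landscape. Observed missense and
# synonymous SNV counts from a population variant table are normalised by
# the mutational opportunity of the local sequence: the number of possible
# missense and synonymous single-nucleotide substitutions obtained by
# exhaustive codon enumeration. Values < 1 indicate depletion of missense
# variation, i.e. intolerance.

#' Enumerate the consequences of all 9 SNVs of a codon
#'
#' @param codon 3-letter codon (sense codon; stop codons are an error).
#' @return named integer vector `c(synonymous=, missense=, nonsense=)`,
#'   summing to 9.
#' @examples
#' enumerate_codon_snvs("TGG")  # 0 syn, 7 mis, 2 non
#' @export
enumerate_codon_snvs <- function(codon) {
  codon <- toupper(codon)
  aa <- STANDARD_CODE[codon]
  if (is.na(aa)) stop("not a codon: ", codon, call. = FALSE)
  if (aa == "*") stop("stop codon has no residue: ", codon, call. = FALSE)
  tab <- codon_snv_table()
  cons <- tab$consequence[tab$codon == codon]
  c(synonymous = sum(cons == "synonymous"),
    missense = sum(cons == "missense"),
    nonsense = sum(cons == "nonsense"))
}

#' Possible-SNV counts for every codon of a CDS
#'
#' @param cds a `CodingSequence`.
#' @return data.frame with columns `position`, `possible_syn`,
#'   `possible_mis`, `possible_non` (each row sums to 9).
#' @export
possible_counts <- function(cds) {
  n <- cds$protein_length
  codons <- substring(cds$nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  tab <- codon_snv_table()
  per_codon <- table(factor(tab$codon, levels = names(STANDARD_CODE)),
                     factor(tab$consequence,
                            levels = c("synonymous", "missense", "nonsense")))
  m <- per_codon[codons, , drop = FALSE]
  data.frame(position = seq_len(n),
             possible_syn = as.integer(m[, "synonymous"]),
             possible_mis = as.integer(m[, "missense"]),
             possible_non = as.integer(m[, "nonsense"]))
}

#' Observed missense/synonymous SNV counts per residue
#'
#' Each variant record counts once, regardless of its allele count
#' ("424 variants" style counting, not allele counting). Nonsense,
#' frameshift and in-frame records contribute to neither count.
#'
#' @param variants a `VariantTable` (consequences assigned).
#' @param protein_length number of residues to cover.
#' @return data.frame with columns `position`, `obs_mis`, `obs_syn`.
#' @export
observed_counts <- function(variants, protein_length) {
  pos <- seq_len(protein_length)
  obs_mis <- obs_syn <- integer(protein_length)
  if (nrow(variants)) {
    mis <- variants$protein_pos[variants$consequence %in% "missense"]
    syn <- variants$protein_pos[variants$consequence %in% "synonymous"]
    t1 <- table(factor(mis, levels = pos))
    t2 <- table(factor(syn, levels = pos))
    obs_mis <- as.integer(t1)
    obs_syn <- as.integer(t2)
  }
  data.frame(position = pos, obs_mis = obs_mis, obs_syn = obs_syn)
}

# Windowed running sum with truncation at the ends.
window_sum <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

#' Per-residue dN/dS tolerance landscape
#'
#' For each position i, observed and possible counts are summed over a
#' window of `window` codons centred on i (truncated at the protein ends)
#' and combined as
#' `dnds_i = ((m + c) / (s + c)) / (M / S)`
#' with m, s the observed missense/synonymous counts, M, S the possible
#' counts and c a pseudocount keeping the ratio finite. `window = 1` gives
#' raw per-codon values.
#'
#' @param possible data.frame from [possible_counts()].
#' @param observed data.frame from [observed_counts()].
#' @param window odd window width in codons (default 21).
#' @param pseudocount c > 0 added to both observed counts (default 0.5).
#' @return object of class `ToleranceLandscape`: data.frame with columns
#'   `position`, `possible_mis`, `possible_syn`, `possible_non`,
#'   `obs_mis`, `obs_syn`, `dnds`. Positions whose window holds no
#'   possible missense or synonymous SNV get `NA` dnds.
#' @export
dnds_landscape <- function(possible, observed, window = 21L,
                           pseudocount = 0.5) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (nrow(possible) != nrow(observed))
    stop("possible/observed length mismatch", call. = FALSE)
  half <- window %/% 2L
  M <- window_sum(possible$possible_mis, half)
  S <- window_sum(possible$possible_syn, half)
  m <- window_sum(observed$obs_mis, half)
  s <- window_sum(observed$obs_syn, half)
  dnds <- ((m + pseudocount) / (s + pseudocount)) / (M / S)
  dnds[M == 0 | S == 0] <- NA_real_
  out <- data.frame(position = possible$position,
                    possible_mis = possible$possible_mis,
                    possible_syn = possible$possible_syn,
                    possible_non = possible$possible_non,
                    obs_mis = observed$obs_mis,
                    obs_syn = observed$obs_syn,
                    dnds = dnds)
  attr(out, "window") <- window
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ToleranceLandscape", "data.frame")
  out
}

#' Per-position dN/dS values inside a domain
#'
#' @param landscape a `ToleranceLandscape`.
#' @param dom list with `start`, `end`.
#' @return numeric vector (named by position, ordered) of defined dnds
#'   values in the domain; the number of undefined positions is attached
#'   as attribute `n_undefined`.
#' @export
domain_dnds_values <- function(landscape, dom) {
  sel <- landscape$position >= dom$start & landscape$position <= dom$end
  v <- landscape$dnds[sel]
  names(v) <- landscape$position[sel]
  out <- v[!is.na(v)]
  attr(out, "n_undefined") <- sum(is.na(v))
  out
}

#' Write a tolerance landscape as TSV
#'
#' @param landscape a `ToleranceLandscape`.
#' @param path output path.
#' @export
write_landscape <- function(landscape, path) {
  df <- as.data.frame(landscape)
  df$dnds <- ifelse(is.na(df$dnds), NA, sprintf("%.6f", df$dnds))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
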