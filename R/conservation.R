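# Per-column conservation scoring of a reference protein from an ortholog
# MSA. ConSurf-style empirical-Bayes rate inference is deliberately replaced
# by a tree-free weighted-entropy score binned into the familiar 1-9 grades
# (9 = most conserved); see the methods vignette for the rationale and the
# limits of the approximation.

# Integer coding of alignment symbols: 1..20 amino acids, 21 gap, 22 X.
aln_codes <- function(aln) {
  m <- aln_matrix(aln)
  codes <- match(m, c(AA_ALPHABET, "-", "X"))
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}

#' Position-based sequence weights
#'
#' Henikoff & Henikoff position-based weighting: in each column, a sequence
#' carrying residue a receives 1/(r * s_a), where r is the number of
#' distinct residues in the column and s_a the number of sequences carrying
#' a. Gap and X cells contribute nothing. Weights are normalised to sum
#' to 1. Uneven taxon sampling (e.g. an alignment dominated by mammals) is
#' thereby down-weighted.
#'
#' @param aln an `AlignmentSet` (>= 2 sequences).
#' @return named numeric vector of weights, one per sequence, summing to 1.
#' @export
sequence_weights <- function(aln) {
  if (length(aln$ids) < 2L) stop("need >= 2 sequences", call. = FALSE)
  codes <- aln_codes(aln)
  nseq <- nrow(codes)
  ncol_ <- ncol(codes)
  # counts[a, j]: sequences carrying amino acid a in column j
  counts <- vapply(seq_len(20L), function(a) colSums(codes == a),
                   numeric(ncol_))
  counts <- t(matrix(counts, nrow = ncol_, ncol = 20L))  # 20 x ncol
  r <- colSums(counts > 0L)                # distinct residues per column
  w <- numeric(nseq)
  col_idx <- rep(seq_len(ncol_), each = nseq)
  ok <- codes <= 20L
  s_a <- counts[cbind(as.vector(codes)[ok], col_idx[as.vector(ok)])]
  contrib <- 1 / (r[col_idx[as.vector(ok)]] * s_a)
  seq_idx <- rep(seq_len(nseq), times = ncol_)[as.vector(ok)]
  w <- vapply(split(contrib, seq_idx), sum, numeric(1))
  full <- numeric(nseq)
  full[as.integer(names(w))] <- w
  if (sum(full) == 0) stop("alignment has no residues", call. = FALSE)
  full <- full / sum(full)
  names(full) <- aln$ids
  full
}

#' Per-position conservation scores
#'
#' Conservation of reference position i is `1 - H_i / ln(20)` where `H_i`
#' is the Shannon entropy of the weighted amino-acid frequencies in the
#' alignment column mapped to i (gaps and X excluded, weights renormalised
#' over the residues present). A column whose gap fraction exceeds
#' `max_gap_fraction` gets an undefined (`NA`) score.
#'
#' @param aln an `AlignmentSet`.
#' @param weights optional per-sequence weights; default
#'   [sequence_weights()].
#' @param max_gap_fraction columns with a larger fraction of gap/X cells
#'   are left unscored (default 0.5).
#' @return object of class `ConservationProfile`: data.frame with columns
#'   `position`, `score`, `grade`, `gap_fraction` over reference positions.
#' @export
column_conservation <- function(aln, weights = sequence_weights(aln),
                                max_gap_fraction = 0.5) {
  codes <- aln_codes(aln)
  map <- column_position_map(aln)
  keep <- which(!is.na(map))
  codes <- codes[, keep, drop = FALSE]
  nseq <- nrow(codes)
  npos <- length(keep)
  freq <- vapply(seq_len(20L), function(a) colSums(weights * (codes == a)),
                 numeric(npos))
  if (npos == 1L) freq <- matrix(freq, nrow = 1L)
  gap_fraction <- colMeans(codes > 20L)
  tot <- rowSums(freq)
  p <- freq / ifelse(tot > 0, tot, 1)
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  H <- -rowSums(plogp)
  score <- 1 - H / log(20)
  score[tot == 0 | gap_fraction > max_gap_fraction] <- NA_real_
  prof <- data.frame(position = map[keep], score = score,
                     grade = grade_profile(score),
                     gap_fraction = gap_fraction)
  class(prof) <- c("ConservationProfile", "data.frame")
  prof
}

#' Bin conservation scores into grades 1-9
#'
#' Nine equal-width bins spanning the observed score range; grade 9 is the
#' most conserved bin, grade 1 the least. A constant profile is assigned
#' the middle grade 5. `NA` scores stay `NA`.
#'
#' @param scores numeric vector of conservation scores.
#' @return integer vector of grades in 1..9 (NA where score is NA).
#' @export
grade_profile <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) return(rep(NA_integer_, length(scores)))
  lo <- min(scores[ok])
  hi <- max(scores[ok])
  g <- rep(NA_integer_, length(scores))
  if (hi == lo) {
    g[ok] <- 5L
    return(g)
  }
  b <- 1L + as.integer(floor(9 * (scores[ok] - lo) / (hi - lo)))
  b[b > 9L] <- 9L
  g[ok] <- b
  g
}

#' Grade counts within a domain
#'
#' @param profile a `ConservationProfile`.
#' @param dom list with `start`, `end`.
#' @return integer vector of counts named "1".."9"; the number of ungraded
#'   (NA) positions in the domain is attached as attribute `n_ungraded`.
#' @export
grade_distribution <- function(profile, dom) {
  sel <- profile$position >= dom$start & profile$position <= dom$end
  g <- profile$grade[sel]
  counts <- vapply(1:9, function(k) sum(g == k, na.rm = TRUE), integer(1))
  names(counts) <- as.character(1:9)
  attr(counts, "n_ungraded") <- sum(is.na(g))
  counts
}

#' Percent identity between two aligned sequences
#'
#' Identity is computed over columns where both rows are non-gap;
#' an X never counts as a match.
#'
#' @param aln an `AlignmentSet`.
#' @param id_a,id_b sequence ids.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(aln, id_a, id_b) {
  if (!id_a %in% aln$ids || !id_b %in% aln$ids)
    stop("sequence id not in alignment", call. = FALSE)
  a <- strsplit(unname(aln$seqs[id_a]), "")[[1]]
  b <- strsplit(unname(aln$seqs[id_b]), "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both))
    stop("no jointly non-gap columns; identity undefined", call. = FALSE)
  100 * sum(a == b & a != "X" & both) / sum(both)
}

#' Write a conservation profile as TSV
#'
#' Columns: position, score, grade, gap_fraction.
#'
#' @param profile a `ConservationProfile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = profile$position,
                   score = ifelse(is.na(profile$score), NA,
                                  sprintf("%.6f", profile$score)),
                   grade = profile$grade,
                   gap_fraction = sprintf("%.6f", profile$gap_fraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
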