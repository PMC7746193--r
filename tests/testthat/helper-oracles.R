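# Independent oracles and tiny fixture builders shared across the suite.
# Oracles deliberately use different code paths from the package
# (Biostrings translation, brute-force enumeration) so that agreement is
# informative.

# Brute-force SNV consequence counts for a codon, via Biostrings.
oracle_codon_snvs <- function(codon) {
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                               no.init.codon = TRUE))
  out <- c(synonymous = 0L, missense = 0L, nonsense = 0L)
  for (off in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, off, off))) {
      mut <- codon
      substr(mut, off, off) <- alt
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                               no.init.codon = TRUE))
      kind <- if (aa == ref_aa) "synonymous"
              else if (aa == "*") "nonsense" else "missense"
      out[kind] <- out[kind] + 1L
    }
  }
  out
}

# All 61 sense codons per Biostrings' standard code.
sense_codons <- function() {
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste0,
                      collapse = "")
  aa <- vapply(all_codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), character(1))
  all_codons[aa != "*"]
}

# Brute-force two-sample KS distance over the pooled support.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Brute-force Mann-Whitney W by pair counting.
oracle_mwu_W <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s
}

# Brute-force hotspot scan: test every (i, j) substring.
oracle_hotspots <- function(means, threshold, min_run) {
  n <- length(means)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(means[i:j] > threshold) &&
          (i == 1 || means[i - 1] <= threshold) &&
          (j == n || means[j + 1] <= threshold) &&
          (j - i + 1) >= min_run)
        runs[[length(runs) + 1]] <- c(i, j)
    }
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

# Tiny in-memory alignment builder.
make_aln <- function(seqs, ids = NULL, reference_id = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  if (is.null(reference_id)) reference_id <- ids[1]
  waldscan:::new_alignment(ids, seqs, reference_id)
}

# Small deterministic synthetic bundle for fast pipeline tests.
small_config <- function(seed = 7, ...) {
  args <- list(
    seed = seed, protein_length = 120L,
    domains = data.frame(name = c("d1", "d2"),
                         start = c(11L, 66L), end = c(60L, 115L)),
    n_taxa = 12L,
    rho = c(d1 = 0.5, d2 = 1.5),
    f_dom = c(d1 = 0.2, d2 = 0.8),
    stretches = data.frame(start = 25L, end = 30L, boost = 40))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}
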