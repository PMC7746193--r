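# Domain types, coordinate conventions and readers/writers.
#
# Conventions used throughout the package:
#   * protein coordinates are 1-based inclusive;
#   * CDS coordinates are 1-based; codon i covers nucleotides 3i-2 .. 3i and
#     encodes residue i;
#   * the alignment gap symbol is '-'; 'X' is tolerated in input alignments
#     but never counted as a residue;
#   * TSV files are tab-delimited with '.' as the decimal mark and '#'
#     comment lines ignored.

# ---- ProteinAnnotation -------------------------------------------------

#' Protein domain annotation
#'
#' Holds the protein length and a set of named, non-overlapping domains in
#' 1-based inclusive residue coordinates.
#'
#' @param protein_id character scalar.
#' @param length protein length in residues.
#' @param domains data.frame with columns `name`, `start`, `end`.
#' @return an object of class `ProteinAnnotation`.
#' @examples
#' protein_annotation("PNKP", 521,
#'   data.frame(name = c("phosphatase", "kinase"),
#'              start = c(146, 341), end = c(337, 521)))
#' @export
protein_annotation <- function(protein_id, length, domains) {
  length <- as.integer(length)
  stopifnot(is.character(protein_id), length >= 1L,
            is.data.frame(domains),
            all(c("name", "start", "end") %in% names(domains)))
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (any(domains$start < 1L) || any(domains$end > length) ||
      any(domains$start > domains$end))
    stop("domain outside protein or start > end", call. = FALSE)
  if (anyDuplicated(domains$name))
    stop("duplicate domain names", call. = FALSE)
  ord <- order(domains$start)
  d <- domains[ord, , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
    stop("domains overlap", call. = FALSE)
  structure(list(protein_id = protein_id, length = length,
                 domains = domains[, c("name", "start", "end")]),
            class = "ProteinAnnotation")
}

#' @export
print.ProteinAnnotation <- function(x, ...) {
  cat("ProteinAnnotation:", x$protein_id, "(", x$length, "aa )\n")
  for (i in seq_len(nrow(x$domains)))
    cat(sprintf("  %-14s %d-%d (%d aa)\n", x$domains$name[i],
                x$domains$start[i], x$domains$end[i],
                x$domains$end[i] - x$domains$start[i] + 1L))
  invisible(x)
}

get_domain <- function(annot, name) {
  i <- match(name, annot$domains$name)
  if (is.na(i)) stop("unknown domain: ", name, call. = FALSE)
  list(name = name, start = annot$domains$start[i],
       end = annot$domains$end[i])
}

#' Read / write a domain annotation (JSON)
#'
#' The JSON schema is `{"protein_id": ..., "length": ...,
#' "domains": [{"name": ..., "start": ..., "end": ...}]}`.
#'
#' @param path file path.
#' @return `read_domains()` returns a [protein_annotation()] object.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  protein_annotation(x$protein_id, x$length, as.data.frame(x$domains))
}

#' @rdname read_domains
#' @param annot a `ProteinAnnotation`.
#' @export
write_domains <- function(annot, path) {
  jsonlite::write_json(
    list(protein_id = annot$protein_id, length = annot$length,
         domains = annot$domains),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- AlignmentSet ------------------------------------------------------

ALN_ALPHABET <- c(AA_ALPHABET, "-", "X")

new_alignment <- function(ids, seqs, reference_id) {
  stopifnot(length(ids) == length(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences have unequal lengths", call. = FALSE)
  if (!reference_id %in% ids)
    stop("reference_id not found in alignment: ", reference_id, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in alignment", call. = FALSE)
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% ALN_ALPHABET),
                 logical(1))
  if (any(bad))
    stop("illegal symbol in sequence(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, reference_id = reference_id,
                 n_columns = unname(widths[1L])),
            class = "AlignmentSet")
}

#' Read an aligned protein FASTA
#'
#' @param path FASTA file of aligned protein sequences (gap '-').
#' @param reference_id id (first whitespace-delimited token of the header)
#'   of the reference sequence; must be present.
#' @return an `AlignmentSet`.
#' @export
read_msa <- function(path, reference_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("alignment needs at least 2 records", call. = FALSE)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  new_alignment(ids, toupper(as.character(ss)), reference_id)
}

#' @rdname read_msa
#' @param aln an `AlignmentSet`.
#' @export
write_msa <- function(aln, path) {
  out <- character(2L * length(aln$ids))
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  out[c(FALSE, TRUE)] <- unname(aln$seqs)
  writeLines(out, path)
  invisible(path)
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat("AlignmentSet:", length(x$ids), "sequences x", x$n_columns,
      "columns; reference:", x$reference_id, "\n")
  invisible(x)
}

# Character matrix view (sequences x columns) of an alignment.
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(unname(aln$seqs), ""), use.names = FALSE),
              nrow = length(aln$ids), byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Map alignment columns to reference residue positions
#'
#' Columns where the reference row holds a gap map to nothing (`NA`).
#'
#' @param aln an `AlignmentSet`.
#' @return integer vector of length `n_columns`; entry j is the 1-based
#'   reference position written in column j, or `NA` if the reference is
#'   gapped there.
#' @export
column_position_map <- function(aln) {
  ref <- strsplit(unname(aln$seqs[aln$reference_id]), "")[[1]]
  res <- ref != "-"
  map <- rep(NA_integer_, length(ref))
  map[res] <- seq_len(sum(res))
  map
}

# ---- CodingSequence ----------------------------------------------------

#' Construct a coding sequence
#'
#' @param nt nucleotide string over A/C/G/T, in frame. A single terminal
#'   stop codon is allowed and excluded from the protein.
#' @return an object of class `CodingSequence` with elements `nt`,
#'   `protein` (translation, stop stripped) and `protein_length`.
#' @export
coding_sequence <- function(nt) {
  nt <- toupper(gsub("[ \n\r\t]", "", nt))
  if (nchar(nt) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", nt))
    stop("CDS contains non-ACGT symbols", call. = FALSE)
  prot <- translate_nt(nt)
  n <- nchar(prot)
  if (substr(prot, n, n) == "*") {
    prot <- substr(prot, 1L, n - 1L)
    n <- n - 1L
  }
  if (grepl("\\*", prot, fixed = FALSE))
    stop("CDS contains an internal stop codon", call. = FALSE)
  structure(list(nt = nt, protein = prot, protein_length = n,
                 codon_table = "standard"),
            class = "CodingSequence")
}

#' @export
print.CodingSequence <- function(x, ...) {
  cat("CodingSequence:", nchar(x$nt), "nt,", x$protein_length, "aa\n")
  invisible(x)
}

codon_at <- function(cds, i) substr(cds$nt, 3L * i - 2L, 3L * i)

#' Read a coding sequence from FASTA
#'
#' The first record is used.
#'
#' @param path nucleotide FASTA file.
#' @return a [coding_sequence()] object.
#' @export
read_cds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no record in CDS FASTA", call. = FALSE)
  coding_sequence(as.character(ss[[1L]]))
}

#' @rdname read_cds
#' @param cds a `CodingSequence`.
#' @param id header to write.
#' @export
write_cds <- function(cds, path, id = "cds") {
  writeLines(c(paste0(">", id), cds$nt), path)
  invisible(path)
}

# ---- VariantTable ------------------------------------------------------

#' Classify a single-nucleotide variant from the codon table
#'
#' @param cds a `CodingSequence`.
#' @param cds_pos 1-based CDS position (vectorised).
#' @param alt_nt alternate nucleotide (vectorised).
#' @return character vector: "synonymous", "missense" or "nonsense".
#' @export
classify_snv <- function(cds, cds_pos, alt_nt) {
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L + 1L
  cod <- substring(cds$nt, 3L * codon_idx - 2L, 3L * codon_idx)
  ref_aa <- STANDARD_CODE[cod]
  alt_cod <- mapply(function(cd, off, a) {
    substr(cd, off, off) <- a
    cd
  }, cod, offset, alt_nt, USE.NAMES = FALSE)
  alt_aa <- STANDARD_CODE[alt_cod]
  unname(ifelse(alt_aa == ref_aa, "synonymous",
                ifelse(alt_aa == "*", "nonsense", "missense")))
}

variant_columns <- c("cds_pos", "ref_nt", "alt_nt", "allele_count", "hom_count")

#' Read a population variant table
#'
#' Expects a tab-separated file with header columns `cds_pos`, `ref_nt`,
#' `alt_nt`, `allele_count`, `hom_count` (a `consequence` column is
#' accepted but recomputed when `cds` is given). Rows whose `ref_nt` does
#' not match the CDS are dropped; the number dropped is recorded in the
#' `n_rejected` attribute. Multi-allelic sites arrive as separate rows and
#' stay separate records.
#'
#' @param path TSV file path.
#' @param cds optional `CodingSequence` used to verify the reference allele
#'   and assign consequences.
#' @return data.frame of class `VariantTable` with columns `cds_pos`,
#'   `ref_nt`, `alt_nt`, `allele_count`, `hom_count`, `consequence`,
#'   `protein_pos`, and attribute `n_rejected`.
#' @export
read_variant_table <- function(path, cds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(variant_columns, names(df))
  if (length(missing_cols))
    stop("variant table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("cds_pos", "allele_count", "hom_count")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (nrow(df) && anyNA(v))
      stop("non-numeric values in column ", cc, call. = FALSE)
    df[[cc]] <- v
  }
  df$ref_nt <- toupper(df$ref_nt)
  df$alt_nt <- toupper(df$alt_nt)
  variant_table(df, cds = cds)
}

#' @rdname read_variant_table
#' @param df data.frame with the variant-table columns.
#' @export
variant_table <- function(df, cds = NULL) {
  if (nrow(df) && any(df$hom_count > df$allele_count))
    stop("hom_count exceeds allele_count", call. = FALSE)
  n_rejected <- 0L
  is_snv <- nchar(df$ref_nt) == 1L & nchar(df$alt_nt) == 1L
  if (!is.null(cds) && nrow(df)) {
    if (any(df$cds_pos < 1L | df$cds_pos > nchar(cds$nt)))
      stop("cds_pos outside CDS", call. = FALSE)
    cds_ref <- substring(cds$nt, df$cds_pos, df$cds_pos)
    bad <- is_snv & cds_ref != df$ref_nt
    n_rejected <- sum(bad)
    if (n_rejected)
      message("read_variant_table: rejected ", n_rejected,
              " record(s) with reference mismatch")
    df <- df[!bad, , drop = FALSE]
    is_snv <- is_snv[!bad]
    cons <- rep(NA_character_, nrow(df))
    if (any(is_snv))
      cons[is_snv] <- classify_snv(cds, df$cds_pos[is_snv], df$alt_nt[is_snv])
    if (any(!is_snv)) {
      shift <- abs(nchar(df$alt_nt[!is_snv]) - nchar(df$ref_nt[!is_snv]))
      cons[!is_snv] <- ifelse(shift %% 3L == 0L, "inframe", "frameshift")
    }
    df$consequence <- cons
  } else if (is.null(df$consequence)) {
    df$consequence <- rep(NA_character_, nrow(df))
  }
  df$protein_pos <- as.integer(ceiling(df$cds_pos / 3))
  rownames(df) <- NULL
  structure(df, class = c("VariantTable", "data.frame"),
            n_rejected = n_rejected)
}

#' @rdname read_variant_table
#' @param variants a `VariantTable`.
#' @export
write_variant_table <- function(variants, path) {
  df <- as.data.frame(variants)[, c(variant_columns, "consequence")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- ScoreMatrix -------------------------------------------------------

#' Read a per-position substitution score matrix
#'
#' Rows are residue positions, columns amino acids; each cell is a
#' disease-propensity score on a 0-100 scale. The column matching the
#' reference amino acid at a position is ignored (it may be empty/NA), so
#' every position carries exactly 19 substitution scores.
#'
#' @param path TSV file: column `pos` then one column per amino acid.
#' @param reference_protein amino-acid string of the reference protein;
#'   its length must equal the number of rows.
#' @return object of class `ScoreMatrix`: list with `mat` (positions x 20
#'   matrix, `NA` on the reference cell) and `ref` (reference residues).
#' @export
read_score_matrix <- function(path, reference_protein) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"pos" %in% names(df))
    stop("score matrix missing 'pos' column", call. = FALSE)
  aa_cols <- intersect(AA_ALPHABET, names(df))
  if (length(aa_cols) < 19L)
    stop("score matrix needs >= 19 amino-acid columns", call. = FALSE)
  m <- matrix(NA_real_, nrow = nrow(df), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  for (a in aa_cols) m[, a] <- as.numeric(df[[a]])
  m <- m[order(df$pos), , drop = FALSE]
  score_matrix(m, reference_protein)
}

#' @rdname read_score_matrix
#' @param mat numeric positions x 20 matrix with amino-acid column names.
#' @export
score_matrix <- function(mat, reference_protein) {
  ref <- strsplit(reference_protein, "")[[1]]
  if (nrow(mat) != length(ref))
    stop(sprintf("score matrix has %d positions but protein has %d residues",
                 nrow(mat), length(ref)), call. = FALSE)
  if (!all(AA_ALPHABET %in% colnames(mat)))
    stop("score matrix column names must be amino acids", call. = FALSE)
  mat <- mat[, AA_ALPHABET, drop = FALSE]
  mat[cbind(seq_along(ref), match(ref, AA_ALPHABET))] <- NA_real_
  vals <- mat[!is.na(mat)]
  if (any(vals < 0 | vals > 100))
    stop("score outside [0,100]", call. = FALSE)
  if (length(ref) && any(rowSums(!is.na(mat)) != 19L))
    stop("each position must carry exactly 19 substitution scores",
         call. = FALSE)
  structure(list(mat = mat, ref = ref), class = "ScoreMatrix")
}

#' @rdname read_score_matrix
#' @param smat a `ScoreMatrix`.
#' @export
write_score_matrix <- function(smat, path) {
  df <- data.frame(pos = seq_len(nrow(smat$mat)))
  for (a in AA_ALPHABET)
    df[[a]] <- ifelse(is.na(smat$mat[, a]), NA,
                      sprintf("%.4f", smat$mat[, a]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat("ScoreMatrix:", nrow(x$mat), "positions x 19 substitutions\n")
  invisible(x)
}

# ---- slicing -----------------------------------------------------------

#' Restrict a position-indexed series to a domain
#'
#' @param values numeric vector named by 1-based residue positions (missing
#'   positions are simply absent).
#' @param dom list with `start` and `end` (1-based inclusive), e.g. an
#'   entry of a `ProteinAnnotation`.
#' @param protein_length optional; when given, the domain is checked to lie
#'   inside the protein.
#' @return the sub-vector for positions `start..end`, in position order.
#' @examples
#' x <- stats::setNames(rnorm(521), 1:521)
#' length(slice_by_domain(x, list(start = 146, end = 337)))  # 192
#' @export
slice_by_domain <- function(values, dom, protein_length = NULL) {
  if (is.null(names(values)))
    names(values) <- seq_along(values)
  if (!is.null(protein_length) &&
      (dom$start < 1L || dom$end > protein_length))
    stop("domain outside protein", call. = FALSE)
  if (dom$start > dom$end) stop("domain start > end", call. = FALSE)
  keep <- names(values)[as.integer(names(values)) >= dom$start &
                          as.integer(names(values)) <= dom$end]
  v <- values[keep]
  v[order(as.integer(names(v)))]
}
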