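test_that("read_msa parses, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref some description", "ACDE", ">s2", "ACDE"), f)
  aln <- read_msa(f, "ref")
  expect_s3_class(aln, "AlignmentSet")
  expect_equal(aln$n_columns, 4L)
  expect_equal(aln$ids, c("ref", "s2"))

  # ragged alignment is a format error
  writeLines(c(">a", "ACDE", ">b", "ACDEF"), f)
  expect_error(read_msa(f, "a"), "unequal")
  # absent reference is a lookup error
  writeLines(c(">a", "ACDE", ">b", "ACDE"), f)
  expect_error(read_msa(f, "zz"), "reference_id")
  # illegal symbol
  writeLines(c(">a", "AC!E", ">b", "ACDE"), f)
  expect_error(read_msa(f, "a"), "illegal symbol")
  # fewer than 2 records
  writeLines(c(">a", "ACDE"), f)
  expect_error(read_msa(f, "a"), "2 records")

  # write -> read is the identity on a generated 70-record MSA
  cfg <- synthetic_config(seed = 3, protein_length = 60L,
                          domains = data.frame(name = "d1", start = 5L,
                                               end = 50L),
                          rho = c(d1 = 1), f_dom = c(d1 = 0.5),
                          n_taxa = 70L,
                          stretches = data.frame(start = integer(),
                                                 end = integer(),
                                                 boost = numeric()))
  ds <- simulate_dataset(cfg)
  write_msa(ds$aln, f)
  back <- read_msa(f, cfg$protein_id)
  expect_identical(back$seqs, ds$aln$seqs)
  expect_identical(back$ids, ds$aln$ids)
})

test_that("column_position_map skips reference gaps", {
  aln <- make_aln(c("ACD", "AAA"))
  expect_equal(column_position_map(aln), c(1L, 2L, 3L))
  aln <- make_aln(c("A-C", "AAA"))
  expect_equal(column_position_map(aln), c(1L, NA, 2L))
  aln <- make_aln(c("---", "AAA"))
  expect_true(all(is.na(column_position_map(aln))))
  # mapped positions strictly increasing, count = ungapped length
  aln <- make_aln(c("-AC--DE-F", "AAAAAAAAA"))
  m <- column_position_map(aln)
  expect_equal(m[!is.na(m)], 1:5)
})

test_that("coding_sequence enforces frame, alphabet and stop rules", {
  cds <- coding_sequence("ATGGAATGA")  # terminal stop allowed
  expect_equal(cds$protein, "ME")
  expect_equal(cds$protein_length, 2L)
  expect_error(coding_sequence("ATGG"), "divisible")
  expect_error(coding_sequence("ATGTAAGAA"), "internal stop")
  expect_error(coding_sequence("ATGNNN"), "non-ACGT")
  expect_equal(waldscan:::codon_at(cds, 2L), "GAA")
})

test_that("read_variant_table classifies, rejects mismatches, keeps multi-allelics", {
  cds <- coding_sequence("ATGGGGTGG")  # M G W
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cds_pos\tref_nt\talt_nt\tallele_count\thom_count",
               "1\tA\tG\t5\t1",    # ATG->GTG missense
               "6\tG\tA\t2\t0",    # GGG->GGA synonymous
               "6\tG\tT\t1\t0",    # multi-allelic: GGG->GGT synonymous
               "8\tG\tA\t1\t0",    # TGG->TAG nonsense
               "2\tA\tC\t1\t0"),   # ref mismatch (CDS has T at 2)
             f)
  expect_message(vt <- read_variant_table(f, cds), "rejected 1")
  expect_equal(nrow(vt), 4L)
  expect_equal(attr(vt, "n_rejected"), 1L)
  expect_equal(vt$consequence,
               c("missense", "synonymous", "synonymous", "nonsense"))
  expect_equal(vt$protein_pos, c(1L, 2L, 2L, 3L))

  # header-only table
  writeLines("cds_pos\tref_nt\talt_nt\tallele_count\thom_count", f)
  expect_equal(nrow(read_variant_table(f, cds)), 0L)

  # missing column is a format error
  writeLines(c("cds_pos\tref_nt\talt_nt\tallele_count", "1\tA\tG\t5"), f)
  expect_error(read_variant_table(f, cds), "hom_count")
  # non-numeric counts are a parse error
  writeLines(c("cds_pos\tref_nt\talt_nt\tallele_count\thom_count",
               "1\tA\tG\tmany\t0"), f)
  expect_error(read_variant_table(f, cds), "non-numeric")
})

test_that("variant write -> read round-trips", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(ds$variants, f)
  back <- read_variant_table(f, ds$cds)
  expect_equal(as.data.frame(back), as.data.frame(ds$variants))
})

test_that("consequence classification agrees with brute-force translation
           on all 61 sense codons x 9 SNVs", {
  for (cod in sense_codons()) {
    cds <- coding_sequence(cod)
    for (off in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(cod, off, off))) {
        ref_aa <- as.character(
          Biostrings::translate(Biostrings::DNAString(cod),
                                no.init.codon = TRUE))
        mut <- cod; substr(mut, off, off) <- alt
        aa <- as.character(
          Biostrings::translate(Biostrings::DNAString(mut),
                                no.init.codon = TRUE))
        want <- if (aa == ref_aa) "synonymous"
                else if (aa == "*") "nonsense" else "missense"
        expect_identical(classify_snv(cds, off, alt), want)
      }
    }
  }
})

test_that("read_score_matrix validates and round-trips", {
  prot <- "MGW"
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("pos", waldscan:::AA_ALPHABET), collapse = "\t")
  row_for <- function(pos, val, ref) {
    v <- rep(val, 20)
    v[match(ref, waldscan:::AA_ALPHABET)] <- NA
    paste(c(pos, ifelse(is.na(v), "", v)), collapse = "\t")
  }
  writeLines(c(hdr, row_for(1, 50, "M"), row_for(2, 50, "G"),
               row_for(3, 50, "W")), f)
  sm <- read_score_matrix(f, prot)
  expect_equal(unname(position_mean_dps(sm)), c(50, 50, 50))

  writeLines(c(hdr, row_for(1, 101, "M"), row_for(2, 50, "G"),
               row_for(3, 50, "W")), f)
  expect_error(read_score_matrix(f, prot), "outside")
  writeLines(c(hdr, row_for(1, 50, "M")), f)
  expect_error(read_score_matrix(f, prot), "3 residues")

  # generated matrix round-trips through the writer at its precision
  cfg <- small_config()
  ds <- simulate_dataset(cfg)
  write_score_matrix(ds$smat, f)
  back <- read_score_matrix(f, ds$cds$protein)
  expect_lt(max(abs(back$mat - ds$smat$mat), na.rm = TRUE), 5.1e-5)
})

test_that("protein_annotation and domain JSON behave", {
  annot <- protein_annotation("P", 521,
                              data.frame(name = c("phos", "kin"),
                                         start = c(146, 341),
                                         end = c(337, 521)))
  expect_equal(annot$length, 521L)
  expect_error(protein_annotation("P", 100,
                                  data.frame(name = "d", start = 50,
                                             end = 101)),
               "outside")
  expect_error(protein_annotation("P", 100,
                                  data.frame(name = c("a", "b"),
                                             start = c(1, 40),
                                             end = c(50, 90))),
               "overlap")
  f <- withr::local_tempfile(fileext = ".json")
  write_domains(annot, f)
  back <- read_domains(f)
  expect_equal(back$domains, annot$domains)
  expect_equal(back$length, annot$length)
})

test_that("slice_by_domain honours the printed domain sizes", {
  x <- stats::setNames(seq_len(521), 1:521)
  expect_length(slice_by_domain(x, list(start = 146, end = 337)), 192L)
  expect_length(slice_by_domain(x, list(start = 341, end = 521)), 181L)
  expect_length(slice_by_domain(x, list(start = 5, end = 5)), 1L)
  # missing positions are simply absent; order preserved
  y <- stats::setNames(c(10, 30, 20), c(1, 3, 2))
  expect_equal(unname(slice_by_domain(y, list(start = 2, end = 3))),
               c(20, 30))
  expect_error(slice_by_domain(x, list(start = 400, end = 600),
                               protein_length = 521),
               "outside")
})
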