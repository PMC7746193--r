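test_that("sequence_weights matches the position-based scheme", {
  # two identical sequences split the weight
  aln <- make_aln(c("ACDE", "ACDE"))
  expect_equal(unname(sequence_weights(aln)), c(0.5, 0.5))

  # single column [A, A, C]: raw 1/(2*2), 1/(2*2), 1/(2*1)
  aln <- make_aln(c("A", "A", "C"))
  expect_equal(unname(sequence_weights(aln)), c(0.25, 0.25, 0.5))

  # weights positive and sum to 1 on generated alignments
  for (s in 1:5) {
    ds <- simulate_dataset(small_config(seed = s, gap_rate = 0.05))
    w <- sequence_weights(ds$aln)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("column_conservation reproduces hand-computed entropies", {
  # all 'W': zero entropy, score 1
  aln <- make_aln(rep("W", 5))
  expect_equal(column_conservation(aln)$score, 1)

  # uniform over the 20 amino acids: maximal entropy, score 0
  aln <- make_aln(as.list(waldscan:::AA_ALPHABET) |> unlist())
  prof <- column_conservation(aln, weights = rep(1 / 20, 20))
  expect_equal(prof$score, 0, tolerance = 1e-12)

  # [A, A, C] with equal weights: 1 - H/ln20, H = -(2/3)ln(2/3)-(1/3)ln(1/3)
  aln <- make_aln(c("A", "A", "C"))
  prof <- column_conservation(aln, weights = rep(1 / 3, 3))
  H <- -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)
  expect_equal(prof$score, 1 - H / log(20), tolerance = 1e-12)
  expect_equal(prof$score, 0.7875, tolerance = 1e-4)

  # scores reported on reference positions only; gappy columns unscored
  aln <- make_aln(c("AW", "-W", "-W", "-W"))
  prof <- column_conservation(aln, max_gap_fraction = 0.5)
  expect_equal(prof$position, c(1L, 2L))
  expect_true(is.na(prof$score[1]))   # 75% gaps
  expect_equal(prof$score[2], 1)
})

test_that("conservation scores are invariant under sequence reordering", {
  ds <- simulate_dataset(small_config(seed = 11))
  aln <- ds$aln
  perm <- c(5, 1, 9, 2, 13, 3, 4, 6, 7, 8, 10, 11, 12)
  aln2 <- waldscan:::new_alignment(aln$ids[perm], unname(aln$seqs[perm]),
                                   aln$reference_id)
  p1 <- column_conservation(aln)
  p2 <- column_conservation(aln2)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})

test_that("grade_profile bins into nine equal-width grades", {
  expect_equal(grade_profile(c(0, 0.5, 1)), c(1L, 5L, 9L))
  expect_equal(grade_profile(rep(0.3, 4)), rep(5L, 4))
  s <- runif(50)
  g <- grade_profile(s)
  expect_equal(g[which.max(s)], 9L)
  expect_equal(g[which.min(s)], 1L)
  # monotone: higher score never gets a lower grade
  o <- order(s)
  expect_true(all(diff(g[o]) >= 0))
  expect_true(is.na(grade_profile(c(NA, 0.2, 0.8))[1]))
})

test_that("grade_distribution counts add up", {
  prof <- data.frame(position = 1:3, score = c(.9, .95, .8),
                     grade = c(9L, 9L, 8L), gap_fraction = 0)
  class(prof) <- c("ConservationProfile", "data.frame")
  d <- grade_distribution(prof, list(start = 1, end = 3))
  expect_equal(unname(d[c("8", "9")]), c(1L, 2L))
  expect_equal(sum(d), 3L)
  d0 <- grade_distribution(prof, list(start = 10, end = 20))
  expect_equal(sum(d0), 0L)

  # totals equal domain sizes on a PNKP-shaped profile
  cfg <- synthetic_config(seed = 2)
  ds <- simulate_dataset(cfg)
  prof <- column_conservation(ds$aln)
  da <- grade_distribution(prof, list(start = 146, end = 337))
  db <- grade_distribution(prof, list(start = 341, end = 521))
  expect_equal(sum(da) + attr(da, "n_ungraded"), 192L)
  expect_equal(sum(db) + attr(db, "n_ungraded"), 181L)
})

test_that("low-rate domain is enriched in grades 8-9 (50 seeds)", {
  hits <- vapply(1:50, function(s) {
    ds <- simulate_dataset(small_config(seed = s))
    prof <- column_conservation(ds$aln)
    da <- grade_distribution(prof, list(start = 11, end = 60))   # rho 0.5
    db <- grade_distribution(prof, list(start = 66, end = 115))  # rho 1.5
    pa <- sum(da[c("8", "9")]) / sum(da)
    pb <- sum(db[c("8", "9")]) / sum(db)
    pa > pb
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("conservation score tracks the true site rate (50 seeds)", {
  rho <- vapply(1:50, function(s) {
    cfg <- synthetic_config(seed = s, protein_length = 200L,
                            domains = data.frame(name = "d1", start = 1L,
                                                 end = 200L),
                            rho = c(d1 = 1), f_dom = c(d1 = 0.5),
                            n_taxa = 30L,
                            stretches = data.frame(start = integer(),
                                                   end = integer(),
                                                   boost = numeric()))
    cds <- simulate_protein_and_cds(cfg)
    rates <- simulate_site_rates(cfg)
    aln <- simulate_msa(cfg, cds$protein, rates)
    prof <- column_conservation(aln)
    stats::cor(rates, prof$score, method = "spearman")
  }, numeric(1))
  expect_lte(stats::median(rho), -0.6)
})

test_that("pairwise_identity counts jointly non-gap columns", {
  aln <- make_aln(c("AAAA", "AAAA", "AAAT", "AA-A", "AATA", "AXAA"))
  expect_equal(pairwise_identity(aln, "s1", "s2"), 100)
  expect_equal(pairwise_identity(aln, "s1", "s3"), 75)
  expect_equal(pairwise_identity(aln, "s4", "s5"), 100)  # gap column dropped
  expect_equal(pairwise_identity(aln, "s3", "s4"), 2 / 3 * 100)
  expect_equal(pairwise_identity(aln, "s1", "s6"), 75)   # X never matches
  expect_equal(pairwise_identity(aln, "s1", "s3"),
               pairwise_identity(aln, "s3", "s1"))
  gappy <- make_aln(c("A-", "-A"))
  expect_error(pairwise_identity(gappy, "s1", "s2"), "non-gap")
})

test_that("less diverged domain shows higher mean identity (50 seeds)", {
  hits <- vapply(1:50, function(s) {
    ds <- simulate_dataset(small_config(seed = s))
    m <- waldscan:::aln_matrix(ds$aln)
    ref <- m[1, ]
    ident <- function(cols) {
      sub <- m[-1, cols, drop = FALSE]
      mean(t(sub) == ref[cols])
    }
    ident(11:60) > ident(66:115)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
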