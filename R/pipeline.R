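# End-to-end pipeline: read the five inputs, compute the conservation
# profile, tolerance landscape and hotspot set, run the domain-comparison
# suite and produce the composite Wald's-domain verdict.

#' Default analysis parameters
#'
#' @param window dN/dS smoothing window in codons (odd; default 21).
#' @param pseudocount pseudocount for the dN/dS ratio (default 0.5).
#' @param percentile hotspot critical-value percentile (default 95).
#' @param min_run minimum hotspot run length (default 3).
#' @param dps_cutoff cutoff for the "high DPS" subset (default 50).
#' @param gof_model expectation model for the variant-count test
#'   ("equal", "length" or "possible"; default "equal").
#' @param max_gap_fraction conservation gap threshold (default 0.5).
#' @return named list of parameters.
#' @export
analysis_params <- function(window = 21L, pseudocount = 0.5,
                            percentile = 95, min_run = 3L,
                            dps_cutoff = 50, gof_model = "equal",
                            max_gap_fraction = 0.5) {
  list(window = as.integer(window), pseudocount = pseudocount,
       percentile = percentile, min_run = as.integer(min_run),
       dps_cutoff = dps_cutoff,
       gof_model = match.arg(gof_model, c("equal", "length", "possible")),
       max_gap_fraction = max_gap_fraction)
}

domain_summary <- function(name, dom, profile, landscape, hs,
                           possible, observed) {
  sel <- function(df) df$position >= dom$start & df$position <= dom$end
  grades <- profile$grade[sel(profile)]
  dvals <- domain_dnds_values(landscape, dom)
  pm <- sum(possible$possible_mis[sel(possible)])
  om <- sum(observed$obs_mis[sel(observed)])
  list(name = name, start = dom$start, end = dom$end,
       length = dom$end - dom$start + 1L,
       mean_grade = mean(grades, na.rm = TRUE),
       mean_dnds = if (length(dvals)) mean(dvals) else NA_real_,
       dnds_n_undefined = attr(dvals, "n_undefined"),
       hotspot_positions = hotspot_positions_in(hs, dom),
       observed_missense = om,
       possible_missense = pm,
       oe_ratio = om / pm)
}

#' Run the domain-comparison analysis on in-memory objects
#'
#' The computational core behind [run_full_analysis()]. Statistical tests
#' on dN/dS are computed on raw per-codon values (window 1) because window
#' smoothing induces serial correlation that the Kolmogorov-Smirnov and
#' Mann-Whitney tests do not survive; domain mean dN/dS summaries use the
#' smoothed landscape (see the methods vignette).
#'
#' @param aln an `AlignmentSet`.
#' @param cds a `CodingSequence`.
#' @param variants a `VariantTable`.
#' @param smat a `ScoreMatrix`.
#' @param annot a `ProteinAnnotation`.
#' @param domain_a,domain_b names of the two domains to compare.
#' @param params list from [analysis_params()].
#' @param identity_groups optional named list of per-protein identity
#'   differences for the ANOVA/Tukey block.
#' @return a `ComparisonReport` list; the computed `profile`, `landscape`,
#'   `hotspots` and per-position `dps_means` are attached as attributes.
#' @export
analyze_dataset <- function(aln, cds, variants, smat, annot,
                            domain_a, domain_b,
                            params = analysis_params(),
                            identity_groups = NULL) {
  if (cds$protein_length != annot$length)
    stop(sprintf("CDS encodes %d residues but annotation says %d",
                 cds$protein_length, annot$length), call. = FALSE)
  if (nrow(smat$mat) != annot$length)
    stop(sprintf("score matrix has %d positions but annotation says %d",
                 nrow(smat$mat), annot$length), call. = FALSE)
  ref_ungapped <- gsub("-", "", aln$seqs[aln$reference_id])
  if (nchar(ref_ungapped) != annot$length)
    stop(sprintf("alignment reference has %d residues but annotation says %d",
                 nchar(ref_ungapped), annot$length), call. = FALSE)
  dom_a <- get_domain(annot, domain_a)
  dom_b <- get_domain(annot, domain_b)

  profile <- column_conservation(aln,
                                 max_gap_fraction = params$max_gap_fraction)
  possible <- possible_counts(cds)
  observed <- observed_counts(variants, cds$protein_length)
  landscape <- dnds_landscape(possible, observed, window = params$window,
                              pseudocount = params$pseudocount)
  raw_landscape <- dnds_landscape(possible, observed, window = 1L,
                                  pseudocount = params$pseudocount)
  dps <- position_mean_dps(smat)
  crit <- critical_value(dps, percentile = params$percentile)
  hs <- call_hotspots(dps, crit, min_run = params$min_run)

  # conservation-grade homogeneity between the two domains
  gd <- rbind(grade_distribution(profile, dom_a),
              grade_distribution(profile, dom_b))
  rownames(gd) <- c(domain_a, domain_b)
  grade_chi2 <- chi2_homogeneity(gd)

  sum_a <- domain_summary(domain_a, dom_a, profile, landscape, hs,
                          possible, observed)
  sum_b <- domain_summary(domain_b, dom_b, profile, landscape, hs,
                          possible, observed)

  gof_w <- switch(params$gof_model,
                  equal = NULL,
                  length = c(sum_a$length, sum_b$length),
                  possible = c(sum_a$possible_missense,
                               sum_b$possible_missense))
  count_gof <- chi2_goodness_of_fit(
    c(sum_a$observed_missense, sum_b$observed_missense),
    model = params$gof_model, weights = gof_w)
  count_gof$oe_ratio <- stats::setNames(c(sum_a$oe_ratio, sum_b$oe_ratio),
                                        c(domain_a, domain_b))

  dps_a <- slice_by_domain(dps, dom_a)
  dps_b <- slice_by_domain(dps, dom_b)
  dps_ks <- list(full = ks_two_sample(dps_a, dps_b),
                 gt_cutoff = tryCatch(
                   ks_two_sample(high_dps_subset(dps_a, params$dps_cutoff),
                                 high_dps_subset(dps_b, params$dps_cutoff)),
                   error = function(e) list(D = NA_real_, p = NA_real_)))

  dnds_a <- domain_dnds_values(raw_landscape, dom_a)
  dnds_b <- domain_dnds_values(raw_landscape, dom_b)
  dnds_ks <- ks_two_sample(dnds_a, dnds_b)
  dnds_mwu <- mann_whitney_u(dnds_a, dnds_b)

  identity_anova <- if (!is.null(identity_groups))
    oneway_anova_tukey(identity_groups) else NULL

  verdict <- walds_domain_verdict(sum_a, sum_b, domain_a, domain_b)

  report <- list(
    params = params,
    domains = stats::setNames(list(sum_a, sum_b), c(domain_a, domain_b)),
    grade_distribution = stats::setNames(
      list(as.vector(gd[1, ]), as.vector(gd[2, ])), c(domain_a, domain_b)),
    grade_chi2 = grade_chi2,
    count_gof = count_gof,
    dps_ks = dps_ks,
    dnds_ks = dnds_ks,
    dnds_mwu = dnds_mwu,
    identity_anova = identity_anova,
    verdict = verdict)
  class(report) <- "ComparisonReport"
  attr(report, "profile") <- profile
  attr(report, "landscape") <- landscape
  attr(report, "hotspots") <- hs
  attr(report, "dps_means") <- dps
  report
}

#' @export
print.ComparisonReport <- function(x, ...) {
  a <- x$verdict$domain_a; b <- x$verdict$domain_b
  cat("Domain comparison:", a, "vs", b, "\n")
  fmt <- function(s) sprintf(
    "  %-14s len %3d  mean grade %.3f  mean dN/dS %.3f  O/E %.4f  hotspot aa %d",
    s$name, s$length, s$mean_grade, s$mean_dnds, s$oe_ratio,
    s$hotspot_positions)
  cat(fmt(x$domains[[a]]), "\n")
  cat(fmt(x$domains[[b]]), "\n")
  cat(sprintf("  grade homogeneity chi2 = %.3f (df %d, p = %.3g)\n",
              x$grade_chi2$statistic, x$grade_chi2$df, x$grade_chi2$p))
  cat(sprintf("  missense count GOF chi2 = %.3f (df %d, p = %.3g, model %s)\n",
              x$count_gof$statistic, x$count_gof$df, x$count_gof$p,
              x$count_gof$model))
  cat(sprintf("  DPS KS D = %.3f (p = %.3g); >cutoff D = %.3f (p = %.3g)\n",
              x$dps_ks$full$D, x$dps_ks$full$p,
              x$dps_ks$gt_cutoff$D, x$dps_ks$gt_cutoff$p))
  cat(sprintf("  dN/dS KS D = %.3f (p = %.3g); MWU W = %.1f (p = %.3g)\n",
              x$dnds_ks$D, x$dnds_ks$p, x$dnds_mwu$W, x$dnds_mwu$p))
  cat(sprintf("  Wald's domain: %s (%.1f - %.1f)\n",
              x$verdict$walds_domain, x$verdict$score_a, x$verdict$score_b))
  invisible(x)
}

#' Run the full analysis from input files
#'
#' Reads the five inputs, runs [analyze_dataset()] and, when `out_dir` is
#' given, writes `profile.tsv`, `landscape.tsv`, `hotspots.tsv`,
#' `report.json` and a human-readable `summary.txt`. Outputs are
#' byte-identical across runs on identical inputs and parameters.
#'
#' @param msa,cds,variants,scores,domains input file paths (aligned
#'   protein FASTA, in-frame nucleotide FASTA, variant TSV, score TSV,
#'   domain JSON).
#' @param reference_id id of the reference row in the MSA (default: the
#'   annotation's `protein_id`).
#' @param domain_a,domain_b names of the domains to compare (defaults: the
#'   first two domains of the annotation).
#' @param params list from [analysis_params()].
#' @param out_dir optional output directory (created if absent).
#' @return the `ComparisonReport`, invisibly when `out_dir` is given.
#' @export
run_full_analysis <- function(msa, cds, variants, scores, domains,
                              reference_id = NULL,
                              domain_a = NULL, domain_b = NULL,
                              params = analysis_params(),
                              out_dir = NULL) {
  for (p in c(msa, cds, variants, scores, domains))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  annot <- read_domains(domains)
  if (is.null(reference_id)) reference_id <- annot$protein_id
  if (is.null(domain_a)) domain_a <- annot$domains$name[1L]
  if (is.null(domain_b)) domain_b <- annot$domains$name[2L]
  aln <- read_msa(msa, reference_id)
  cds_obj <- read_cds(cds)
  vt <- read_variant_table(variants, cds = cds_obj)
  smat <- read_score_matrix(scores, cds_obj$protein)
  report <- analyze_dataset(aln, cds_obj, vt, smat, annot,
                            domain_a, domain_b, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(attr(report, "profile"), file.path(out_dir, "profile.tsv"))
    write_landscape(attr(report, "landscape"),
                    file.path(out_dir, "landscape.tsv"))
    write_hotspots(attr(report, "hotspots"),
                   file.path(out_dir, "hotspots.tsv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "summary.txt"))
    return(invisible(report))
  }
  report
}

#' Write a comparison report as JSON
#'
#' @param report a `ComparisonReport`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  attributes(x) <- list(names = names(x))
  x$identity_anova <- if (is.null(x$identity_anova)) NULL else
    x$identity_anova
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
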