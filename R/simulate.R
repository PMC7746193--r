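# Synthetic input bundles with known ground truth. The generator emulates
# the statistical structure the analysis assumes: gamma site-rate
# heterogeneity scaled per domain (conservation structure), a star
# phylogeny of orthologs at graded divergences, per-domain purifying
# selection thinning of missense SNVs, and a substitution score matrix
# coupled to site conservation with planted high-score stretches.

# Deterministic per-component sub-seed so that adding a component does not
# perturb the draws of the others. Kept below 2^31-1.
component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_len(nchar(component)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

#' Synthetic dataset configuration
#'
#' Defaults state the emulated world: a 521-residue two-domain protein
#' shaped like PNKP (domain 1 at 146-337 under strong purifying selection,
#' domain 2 at 341-521 tolerant), 30 ortholog taxa on a star phylogeny
#' with divergences averaging 0.5 substitutions/site, unit-mean gamma site
#' rates, a 30% SNV inclusion probability, missense retention 0.2 vs 0.8
#' in the two domains, and planted functional stretches mirroring the
#' published hotspot coordinates.
#'
#' @param seed integer seed; fully determines the dataset.
#' @param protein_id reference id used in all files.
#' @param protein_length residues (default 521).
#' @param domains data.frame name/start/end (default phosphatase-like
#'   146-337 and kinase-like 341-521).
#' @param n_taxa ortholog count (default 30).
#' @param divergence per-taxon divergences; default evenly spaced on
#'   0.05..0.95 (mean 0.5).
#' @param gamma_shape shape of the unit-mean gamma site-rate distribution
#'   (default 1).
#' @param rho named per-domain rate multipliers (default 0.5 / 1.5).
#' @param rho_other multiplier outside annotated domains (default 1).
#' @param pi_s synonymous SNV inclusion probability (default 0.3).
#' @param f_dom named per-domain missense retention fractions (default
#'   0.2 / 0.8).
#' @param f_other retention outside domains (default 1).
#' @param f_non nonsense retention (default 0.1).
#' @param hom_prob probability a variant with allele count >= 2 carries a
#'   homozygote (default 0.02).
#' @param allele_geom_p geometric parameter of allele counts, which are
#'   `1 + rgeom(p)` (default 0.5).
#' @param beta0,beta1 logistic coupling of score to conservation
#'   (defaults -2 and 4: the most conserved sites score ~88, the least
#'   ~12 before noise).
#' @param noise_sd per-substitution score noise sd (default 8).
#' @param stretches data.frame start/end/boost of planted functional
#'   stretches (defaults mirror 170-177, 217-219, 259-261, 377-379 with
#'   boost 40).
#' @param gap_rate per-cell gap injection probability in ortholog rows
#'   (default 0: gapless).
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1L,
                             protein_id = "synthetic_protein",
                             protein_length = 521L,
                             domains = data.frame(
                               name = c("phosphatase", "kinase"),
                               start = c(146L, 341L),
                               end = c(337L, 521L)),
                             n_taxa = 30L,
                             divergence = NULL,
                             gamma_shape = 1,
                             rho = c(phosphatase = 0.5, kinase = 1.5),
                             rho_other = 1,
                             pi_s = 0.3,
                             f_dom = c(phosphatase = 0.2, kinase = 0.8),
                             f_other = 1,
                             f_non = 0.1,
                             hom_prob = 0.02,
                             allele_geom_p = 0.5,
                             beta0 = -2,
                             beta1 = 4,
                             noise_sd = 8,
                             stretches = data.frame(
                               start = c(170L, 217L, 259L, 377L),
                               end = c(177L, 219L, 261L, 379L),
                               boost = 40),
                             gap_rate = 0) {
  if (is.null(divergence))
    divergence <- seq(0.05, 0.95, length.out = n_taxa)
  stopifnot(pi_s >= 0, pi_s <= 1, all(f_dom > 0), all(f_dom <= 1),
            f_non >= 0, f_non <= 1, all(divergence >= 0),
            gamma_shape > 0, n_taxa >= 1)
  if (!all(names(rho) %in% domains$name) ||
      !all(names(f_dom) %in% domains$name))
    stop("rho/f_dom names must match domain names", call. = FALSE)
  cfg <- list(seed = as.integer(seed), protein_id = protein_id,
              protein_length = as.integer(protein_length),
              domains = domains, n_taxa = as.integer(n_taxa),
              divergence = divergence, gamma_shape = gamma_shape,
              rho = rho, rho_other = rho_other, pi_s = pi_s,
              f_dom = f_dom, f_other = f_other, f_non = f_non,
              hom_prob = hom_prob, allele_geom_p = allele_geom_p,
              beta0 = beta0, beta1 = beta1, noise_sd = noise_sd,
              stretches = stretches, gap_rate = gap_rate)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' A null configuration with no domain differences
#'
#' Equal rate multipliers, equal missense retention and no planted
#' stretches; used for type-I-error calibration.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_config()].
#' @export
null_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed,
                   rho = c(phosphatase = 1, kinase = 1),
                   f_dom = c(phosphatase = 0.5, kinase = 0.5),
                   stretches = data.frame(start = integer(),
                                          end = integer(),
                                          boost = numeric()),
                   ...)
}

# Per-position value map: `by_domain` named per domain, `other` elsewhere.
position_values <- function(cfg, by_domain, other) {
  v <- rep(other, cfg$protein_length)
  for (i in seq_len(nrow(cfg$domains))) {
    nm <- cfg$domains$name[i]
    if (nm %in% names(by_domain))
      v[cfg$domains$start[i]:cfg$domains$end[i]] <- by_domain[[nm]]
  }
  v
}

# Synonymous codons per amino acid (sense codons only).
codons_by_aa <- function() {
  sense <- STANDARD_CODE[STANDARD_CODE != "*"]
  split(names(sense), unname(sense))
}

#' Simulate the reference protein and its coding sequence
#'
#' Residues are drawn uniformly from the 20 amino acids; the codon of each
#' residue is drawn uniformly among its synonymous codons, so the CDS
#' translates back to the protein and carries no internal stop.
#'
#' @param cfg a `SyntheticConfig`.
#' @return a [coding_sequence()] object.
#' @export
simulate_protein_and_cds <- function(cfg) {
  set.seed(component_seed(cfg$seed, "protein"))
  aa <- sample(AA_ALPHABET, cfg$protein_length, replace = TRUE)
  cba <- codons_by_aa()
  codons <- vapply(aa, function(a) {
    cs <- cba[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  coding_sequence(paste(codons, collapse = ""))
}

#' Simulate gamma site rates scaled per domain
#'
#' `r_i = rho_dom(i) * g_i` with `g_i ~ Gamma(shape, rate = shape)`
#' (mean 1).
#'
#' @param cfg a `SyntheticConfig`.
#' @return numeric vector of length `protein_length`.
#' @export
simulate_site_rates <- function(cfg) {
  set.seed(component_seed(cfg$seed, "rates"))
  g <- stats::rgamma(cfg$protein_length, shape = cfg$gamma_shape,
                     rate = cfg$gamma_shape)
  position_values(cfg, as.list(cfg$rho), cfg$rho_other) * g
}

#' Simulate the ortholog alignment (star phylogeny)
#'
#' Each taxon k at divergence d_k differs from the reference at site i
#' with probability `1 - exp(-r_i * d_k)`, substituting a uniformly drawn
#' different residue; no indels unless `gap_rate > 0`.
#'
#' @param cfg a `SyntheticConfig`.
#' @param reference amino-acid string of the reference protein.
#' @param site_rates per-site rates; default [simulate_site_rates()].
#' @return an `AlignmentSet` with the reference as first record.
#' @export
simulate_msa <- function(cfg, reference, site_rates = simulate_site_rates(cfg)) {
  set.seed(component_seed(cfg$seed, "msa"))
  L <- nchar(reference)
  stopifnot(L == length(site_rates))
  ref <- strsplit(reference, "")[[1]]
  ref_idx <- match(ref, AA_ALPHABET)
  seqs <- character(cfg$n_taxa)
  for (k in seq_len(cfg$n_taxa)) {
    p <- 1 - exp(-site_rates * cfg$divergence[k])
    row <- ref
    hit <- stats::runif(L) < p
    if (any(hit)) {
      # uniform over the 19 non-reference residues
      shift <- sample.int(19L, sum(hit), replace = TRUE)
      row[hit] <- AA_ALPHABET[(ref_idx[hit] - 1L + shift) %% 20L + 1L]
    }
    if (cfg$gap_rate > 0) {
      gap <- stats::runif(L) < cfg$gap_rate
      row[gap] <- "-"
    }
    seqs[k] <- paste(row, collapse = "")
  }
  ids <- c(cfg$protein_id,
           sprintf("taxon_%02d", seq_len(cfg$n_taxa)))
  new_alignment(ids, c(reference, seqs), cfg$protein_id)
}

#' Simulate a population variant table under purifying selection
#'
#' Every one of the 9 possible SNVs of every codon enters the table
#' independently with probability `pi_s` (synonymous), `pi_s * f_dom`
#' (missense) or `pi_s * f_non` (nonsense); retained variants get a
#' heavy-tailed allele count `1 + rgeom(allele_geom_p)` and, rarely, a
#' homozygote.
#'
#' @param cfg a `SyntheticConfig`.
#' @param cds the reference [coding_sequence()].
#' @return a `VariantTable`.
#' @export
simulate_population_variants <- function(cfg, cds) {
  set.seed(component_seed(cfg$seed, "variants"))
  L <- cds$protein_length
  tab <- codon_snv_table()
  codons <- substring(cds$nt, 3L * seq_len(L) - 2L, 3L * seq_len(L))
  idx <- lapply(seq_len(L), function(i) which(tab$codon == codons[i]))
  n_per <- lengths(idx)                      # 9 for every sense codon
  rows <- tab[unlist(idx), , drop = FALSE]
  protein_pos <- rep(seq_len(L), n_per)
  cds_pos <- 3L * (protein_pos - 1L) + rows$offset
  f_vec <- position_values(cfg, as.list(cfg$f_dom), cfg$f_other)
  p_keep <- ifelse(rows$consequence == "synonymous", cfg$pi_s,
            ifelse(rows$consequence == "missense",
                   cfg$pi_s * f_vec[protein_pos],
                   cfg$pi_s * cfg$f_non))
  keep <- stats::runif(length(p_keep)) < p_keep
  n <- sum(keep)
  allele_count <- 1L + stats::rgeom(n, cfg$allele_geom_p)
  hom_count <- ifelse(allele_count >= 2L &
                        stats::runif(n) < cfg$hom_prob, 1L, 0L)
  df <- data.frame(cds_pos = cds_pos[keep],
                   ref_nt = rows$ref_nt[keep],
                   alt_nt = rows$alt_nt[keep],
                   allele_count = allele_count,
                   hom_count = hom_count,
                   stringsAsFactors = FALSE)
  df <- df[order(df$cds_pos, df$alt_nt), , drop = FALSE]
  variant_table(df, cds = cds)
}

#' Simulate a saturation-mutagenesis score matrix
#'
#' The base score of position i is `100 * logistic(beta0 + beta1 * (1 -
#' u_i))` where `u_i` is the empirical percentile of the site rate (so
#' conserved sites score high); planted stretches add their boost; each
#' of the 19 substitutions gets independent Gaussian noise; everything is
#' clamped to \[0, 100\].
#'
#' @param cfg a `SyntheticConfig`.
#' @param site_rates per-site rates used for the coupling.
#' @param reference amino-acid string of the reference protein.
#' @return a `ScoreMatrix`.
#' @export
simulate_score_matrix <- function(cfg, site_rates, reference) {
  set.seed(component_seed(cfg$seed, "scores"))
  L <- length(site_rates)
  u <- (rank(site_rates, ties.method = "average") - 0.5) / L
  base <- 100 * stats::plogis(cfg$beta0 + cfg$beta1 * (1 - u))
  if (nrow(cfg$stretches))
    for (i in seq_len(nrow(cfg$stretches))) {
      sel <- cfg$stretches$start[i]:cfg$stretches$end[i]
      base[sel] <- base[sel] + cfg$stretches$boost[i]
    }
  noise <- matrix(stats::rnorm(L * 20L, 0, cfg$noise_sd), nrow = L)
  m <- pmin(pmax(base + noise, 0), 100)
  colnames(m) <- AA_ALPHABET
  score_matrix(m, reference)
}

#' Generate a complete in-memory synthetic dataset
#'
#' @param cfg a `SyntheticConfig`.
#' @return list with `cds`, `aln`, `variants`, `smat`, `annot`,
#'   `site_rates`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  cds <- simulate_protein_and_cds(cfg)
  site_rates <- simulate_site_rates(cfg)
  aln <- simulate_msa(cfg, cds$protein, site_rates)
  variants <- simulate_population_variants(cfg, cds)
  smat <- simulate_score_matrix(cfg, site_rates, cds$protein)
  annot <- protein_annotation(cfg$protein_id, cfg$protein_length,
                              cfg$domains)
  truth <- list(seed = cfg$seed,
                rho = as.list(cfg$rho), rho_other = cfg$rho_other,
                f_dom = as.list(cfg$f_dom), f_other = cfg$f_other,
                f_non = cfg$f_non, pi_s = cfg$pi_s,
                gamma_shape = cfg$gamma_shape,
                divergence = cfg$divergence,
                stretches = cfg$stretches,
                site_rates = site_rates)
  list(cds = cds, aln = aln, variants = variants, smat = smat,
       annot = annot, site_rates = site_rates, truth = truth)
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes `msa.fasta`, `cds.fasta`, `variants.tsv`, `scores.tsv`,
#' `domains.json` and `truth.json` into `out_dir`. Re-running with the
#' same configuration produces byte-identical files.
#'
#' @param cfg a `SyntheticConfig`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
generate_dataset <- function(cfg, out_dir) {
  ds <- simulate_dataset(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  paths <- c(msa = file.path(out_dir, "msa.fasta"),
             cds = file.path(out_dir, "cds.fasta"),
             variants = file.path(out_dir, "variants.tsv"),
             scores = file.path(out_dir, "scores.tsv"),
             domains = file.path(out_dir, "domains.json"),
             truth = file.path(out_dir, "truth.json"))
  write_msa(ds$aln, paths["msa"])
  write_cds(ds$cds, paths["cds"], id = cfg$protein_id)
  write_variant_table(ds$variants, paths["variants"])
  write_score_matrix(ds$smat, paths["scores"])
  write_domains(ds$annot, paths["domains"])
  truth <- ds$truth
  truth$site_rates <- round(truth$site_rates, 6)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  invisible(paths)
}
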