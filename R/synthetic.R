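# Synthetic cohort generator: emulates the statistical structure the
# analysis assumes -- multinomial chromosome counts under known karyotype,
# age-dependent DNA depth decay, age-invariant lognormal amelogenin signal,
# and sex-conditional osteological trait expression with juvenile
# missingness.

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the stated world of the reference study: DNA depth decays
#' by one order of magnitude over ~2,000 years (5e-4 log10 units/year) from a
#' log10 mean of 5.3 at age 0 with lognormal spread 1.1; the AMELX proteomic
#' signal is age-invariant lognormal with log10 mean 9.0 and sd 0.6 (printed
#' group means 9.03 +/- 0.56 and 9.08 +/- 0.63); unique AMELY peptide counts
#' for males are overdispersed around a mean of 80 (printed range 6..251,
#' mean 81); two site-like age clusters span 100-600 and 1,610-2,240 cal BP;
#' a small Y-mismapping fraction gives XX individuals nonzero Ry.
#'
#' @param n_samples Cohort size.
#' @param sex_ratio Probability of an XY individual.
#' @param depth_log10_mean_age0 log10 mean total mapped reads at age 0.
#' @param depth_decay_per_year log10 units of depth lost per calendar year.
#' @param depth_log10_sd Lognormal spread of depth (log10 units).
#' @param dna_failure_rate Probability a sample yields zero mapped reads
#'   (failed extraction); default 2/55 as in the reference cohort.
#' @param epsilon_y Y-mismapping fraction for XX individuals (relative to
#'   the X weight).
#' @param y_mappability Effective fraction of Y length that attracts reads
#'   (stands in for repeat content and X/Y homology).
#' @param protein_log10_mean,protein_log10_sd AMELX CI/mg lognormal
#'   parameters (age-invariant).
#' @param amely_log10_mean,amely_log10_sd AMELY CI/mg lognormal parameters
#'   for males.
#' @param amely_peptide_rate Mean unique AMELY peptides for XY individuals
#'   (negative-binomial, floor of 3 enforced).
#' @param amely_peptide_size Negative-binomial size (overdispersion).
#' @param enamel_mass_log10_mean,enamel_mass_log10_sd Enamel mass (mg)
#'   lognormal parameters.
#' @param juvenile_fraction Fraction of juveniles (osteologically
#'   indeterminate).
#' @param trait_effect Mean |score| of sex-conditional trait expression in
#'   adults (five-point scale).
#' @param trait_sd Trait score noise sd.
#' @param trait_missing_rate Per-trait missingness in adults.
#' @param age_clusters Two-column matrix (rows = clusters) of age spans
#'   (cal BP).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100L, sex_ratio = 0.5,
                       depth_log10_mean_age0 = 5.3,
                       depth_decay_per_year = 5e-4,
                       depth_log10_sd = 1.1,
                       dna_failure_rate = 2 / 55,
                       epsilon_y = 0.002, y_mappability = 0.25,
                       protein_log10_mean = 9.0, protein_log10_sd = 0.6,
                       amely_log10_mean = 8.3, amely_log10_sd = 0.6,
                       amely_peptide_rate = 80, amely_peptide_size = 1,
                       enamel_mass_log10_mean = 1.2,
                       enamel_mass_log10_sd = 0.2,
                       juvenile_fraction = 0.3,
                       trait_effect = 1.3, trait_sd = 0.7,
                       trait_missing_rate = 0.35,
                       age_clusters = rbind(c(100, 600), c(1610, 2240)),
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_samples >= 1, sex_ratio >= 0, sex_ratio <= 1,
            depth_log10_sd > 0, protein_log10_sd > 0,
            epsilon_y >= 0, epsilon_y < 1,
            y_mappability > 0, y_mappability <= 1,
            juvenile_fraction >= 0, juvenile_fraction <= 1,
            trait_missing_rate >= 0, trait_missing_rate < 1,
            dna_failure_rate >= 0, dna_failure_rate < 1,
            nrow(age_clusters) >= 1, ncol(age_clusters) == 2)
  structure(as.list(environment()), class = "sim_config")
}

# Per-chromosome sampling weights for a karyotype.
karyotype_weights <- function(karyotype, config) {
  lens <- hg19_chromosome_lengths()
  w <- 2 * lens
  if (karyotype == "XY") {
    w[["X"]] <- lens[["X"]]
    w[["Y"]] <- config$y_mappability * lens[["Y"]]
  } else {
    w[["X"]] <- 2 * lens[["X"]]
    w[["Y"]] <- config$epsilon_y * w[["X"]]
  }
  w
}

#' Simulate a chromosome count table under a known karyotype
#'
#' Multinomial draw of `total_reads` over the 24 canonical chromosomes with
#' probabilities proportional to copy number x effective length (hg19
#' lengths): autosomes carry two copies; XX carries two X copies and a
#' leakage fraction `epsilon_y` of the X weight on Y (mismapping); XY carries
#' one X and one Y scaled by `y_mappability`.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param total_reads Total mapped reads (0 allowed).
#' @param config A [sim_config()].
#' @param seed Optional seed (otherwise uses the ambient RNG stream).
#' @return A [chrom_counts()] object.
#' @export
simulate_chromosome_counts <- function(karyotype = c("XX", "XY"), total_reads,
                                       config, seed = NULL) {
  karyotype <- match.arg(karyotype)
  stopifnot(total_reads >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- karyotype_weights(karyotype, config)
  draws <- if (total_reads == 0) stats::setNames(rep(0, 24), names(w))
  else stats::setNames(drop(stats::rmultinom(1, total_reads, w)), names(w))
  chrom_counts(hg19_chromosome_lengths(), draws,
               sample_id = paste0("sim_", karyotype))
}

# Cache of classified isoform substrings (all lengths 8..20), built once per
# session from the bundled isoforms.
peptide_pools <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    iso <- amelogenin_isoforms()
    windows <- function(s) {
      n <- nchar(s)
      unlist(lapply(8:20, function(k) {
        if (n < k) return(character(0))
        starts <- seq_len(n - k + 1)
        unique(substring(s, starts, starts + k - 1))
      }))
    }
    all_w <- unique(c(windows(iso[["AMELX"]]), windows(iso[["AMELY"]])))
    spec <- assign_specificity(all_w, iso[["AMELX"]], iso[["AMELY"]])
    cache <<- split(all_w, spec)
    cache
  }
})

#' Simulate a peptide quantification table for one individual
#'
#' Draws AMELX-specific peptides for every individual and AMELY-specific
#' peptides only for XY individuals, as genuine substrings of the bundled
#' isoform pair (so specificity assignment is truly exercised), with shared
#' homologous peptides included as distractors. Intensities are lognormal and
#' statistically independent of any DNA depth; a random subset of rows carry
#' PTM annotations to exercise modification stripping.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with `observations` (data frame: `sequence`,
#'   `modifications`, `intensity`, `accession`) and `enamel_mass_mg`.
#' @export
simulate_peptide_table <- function(sex = c("XX", "XY"), config, seed = NULL) {
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  pools <- peptide_pools()
  mass <- 10^stats::rnorm(1, config$enamel_mass_log10_mean,
                          config$enamel_mass_log10_sd)
  draw_block <- function(pool, n_unique, total_intensity, accession) {
    n_unique <- min(n_unique, length(pool))
    seqs <- sample(pool, n_unique)
    # a few PTM variants: duplicate ~20% of sequences with an annotation
    extra <- seqs[stats::runif(n_unique) < 0.2]
    annotated <- c(seqs, vapply(extra, function(s) {
      pos <- sample(nchar(s) - 1, 1)
      paste0(substr(s, 1, pos), "(+.98)", substr(s, pos + 1, nchar(s)))
    }, character(1)))
    shares <- stats::rexp(length(annotated))
    data.frame(sequence = annotated, modifications = ifelse(
      annotated %in% seqs, "", "Deamidation (NQ)"),
      intensity = total_intensity * shares / sum(shares),
      accession = accession, stringsAsFactors = FALSE)
  }
  x_total <- mass * 10^stats::rnorm(1, config$protein_log10_mean,
                                    config$protein_log10_sd)
  n_x <- 5 + stats::rpois(1, 25)
  blocks <- list(draw_block(pools$X_specific, n_x, x_total, "AMELX_SYNTH"))
  if (sex == "XY") {
    n_y <- max(3, stats::rnbinom(1, size = config$amely_peptide_size,
                                 mu = config$amely_peptide_rate))
    y_total <- mass * 10^stats::rnorm(1, config$amely_log10_mean,
                                      config$amely_log10_sd)
    blocks <- c(blocks, list(draw_block(pools$Y_specific, n_y, y_total,
                                        "AMELY_SYNTH")))
  }
  n_shared <- stats::rpois(1, 8)
  if (n_shared > 0) {
    blocks <- c(blocks, list(draw_block(
      pools$shared, n_shared,
      mass * 10^stats::rnorm(1, config$protein_log10_mean - 0.5,
                             config$protein_log10_sd),
      "AMEL_SHARED")))
  }
  list(observations = do.call(rbind, blocks), enamel_mass_mg = mass)
}

simulate_osteo_scores <- function(sex, config) {
  traits <- unlist(osteo_trait_names(), use.names = FALSE)
  mu <- if (sex == "XY") config$trait_effect else -config$trait_effect
  raw <- round(stats::rnorm(length(traits), mu, config$trait_sd))
  raw <- pmin(2, pmax(-2, raw))
  raw[stats::runif(length(traits)) < config$trait_missing_rate] <- NA
  stats::setNames(raw, traits)
}

#' Simulate a full cohort and run the three-track pipeline over it
#'
#' Per individual: true sex and site-like age cluster are drawn; DNA depth
#' follows the age-decay model (with occasional failed extractions);
#' chromosome counts, a peptide table and (adults only) osteological trait
#' scores are generated; and the package's own estimators (Ry, Rx,
#' proteomic classification, trait aggregation) produce the recorded
#' estimates. The generative truth is returned separately and is never
#' written into the cohort, so downstream tests cannot leak it.
#'
#' @param config A [sim_config()] (its `seed` drives all randomness).
#' @param thresholds A [threshold_config()].
#' @return List with `cohort` (a `sex_cohort`, provenance `"synthetic"`,
#'   including per-sample `ry`, `rx`, CI columns, `prf`) and `truth`
#'   (data frame: `sample_id`, `sex`, `age_cal_bp`, `juvenile`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 20, seed = 7))
#' table(sim$truth$sex)
#' @export
simulate_cohort <- function(config, thresholds = threshold_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sexes <- ifelse(stats::runif(n) < config$sex_ratio, "XY", "XX")
  cluster <- sample(nrow(config$age_clusters), n, replace = TRUE)
  ages <- round(stats::runif(n, config$age_clusters[cluster, 1],
                             config$age_clusters[cluster, 2]))
  juvenile <- stats::runif(n) < config$juvenile_fraction
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SIM-%03d", i)
    failed <- stats::runif(1) < config$dna_failure_rate
    depth <- if (failed) 0 else round(10^stats::rnorm(
      1, config$depth_log10_mean_age0 - config$depth_decay_per_year * ages[i],
      config$depth_log10_sd))
    cc <- simulate_chromosome_counts(sexes[i], depth, config)
    ry <- compute_ry(cc, thresholds)
    rx <- compute_rx(cc, thresholds)
    pep <- simulate_peptide_table(sexes[i], config)
    prot <- proteomic_sex(pep$observations, pep$enamel_mass_mg, thresholds)
    oste_est <- if (juvenile[i]) {
      sex_estimate("oste", "indeterminate", "none", diagnostic = "juvenile")
    } else {
      aggregate_traits(simulate_osteo_scores(sexes[i], config))
    }
    rows[[i]] <- data.frame(
      sample_id = id, site = paste0("SIM", cluster[i]),
      age_cal_bp = ages[i], total_mapped_reads = depth,
      oste = format(oste_est), ry = format(ry$estimate),
      rx = format(rx$estimate), prot = format(prot$estimate),
      ry_point = ry$point, ry_lo = ry$ci_low, ry_hi = ry$ci_high,
      rx_point = rx$point, rx_lo = rx$ci_low, rx_hi = rx$ci_high,
      enamel_mass_mg = pep$enamel_mass_mg,
      amelx_ci_per_mg = prot$amelx_ci_per_mg,
      amely_ci_per_mg = prot$amely_ci_per_mg,
      prf = if (is.na(prot$prf)) pr_female_safe(prot$x_log10) else prot$prf,
      n_amely_unique = prot$n_amely_unique,
      low_data = ry$estimate$low_data,
      stringsAsFactors = FALSE)
  }
  cohort <- as_sex_cohort(do.call(rbind, rows), provenance = "synthetic")
  truth <- data.frame(sample_id = vapply(rows, `[[`, "", "sample_id"),
                      sex = sexes, age_cal_bp = ages, juvenile = juvenile,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

# Pr(F) for reporting even when classification went through the male rule:
# NA when x is missing or out of domain.
pr_female_safe <- function(x) {
  if (is.na(x) || x <= 0) NA_real_ else pr_female(x)
}
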