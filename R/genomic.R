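#' Classify a ratio confidence interval against two sex-region thresholds
#'
#' Shared decision geometry for the Ry and Rx statistics. Each statistic has
#' two disjoint one-sided definitive regions (for Ry the male region lies
#' above 0.075 and the female region below 0.016; for Rx the male region lies
#' below 0.60 and the female region above 0.80). The 95% CI is compared with
#' both boundaries:
#'
#' * CI entirely inside the male region: definitive XY;
#' * entirely inside the female region: definitive XX;
#' * entirely between the two regions: indeterminate;
#' * touching or crossing exactly one boundary: conditional with the sex of
#'   the crossed region ("consistent with ...");
#' * spanning both boundaries: indeterminate.
#'
#' An endpoint exactly equal to a threshold counts as crossing (conservative:
#' definitive calls require strict containment).
#'
#' @param point Point estimate (used only for reporting).
#' @param ci_low,ci_high Interval endpoints, `ci_low <= ci_high`.
#' @param male_region,female_region Lists `list(bound =, side =)` with `side`
#'   `"above"` or `"below"`; the regions must be disjoint.
#' @param method Method tag for the resulting estimate (`"ry"` or `"rx"`).
#' @param low_data Passed through to the estimate.
#' @return A [sex_estimate()].
#' @examples
#' classify_interval(0.1, 0.09, 0.12,
#'                   male_region = list(bound = 0.075, side = "above"),
#'                   female_region = list(bound = 0.016, side = "below"))
#' @export
classify_interval <- function(point, ci_low, ci_high, male_region, female_region,
                              method = "ry", low_data = FALSE) {
  stopifnot(ci_low <= ci_high)
  side <- function(r) match.arg(r$side, c("above", "below"))
  if (side(male_region) == side(female_region)) {
    stop("regions must lie on opposite sides", call. = FALSE)
  }
  inside <- function(r) {
    if (side(r) == "above") ci_low > r$bound else ci_high < r$bound
  }
  touches <- function(r) {
    if (side(r) == "above") ci_high >= r$bound else ci_low <= r$bound
  }
  if (inside(male_region) && !touches(female_region)) {
    return(sex_estimate(method, "XY", "definitive", low_data))
  }
  if (inside(female_region) && !touches(male_region)) {
    return(sex_estimate(method, "XX", "definitive", low_data))
  }
  tm <- touches(male_region)
  tf <- touches(female_region)
  if (tm && !tf) return(sex_estimate(method, "XY", "conditional", low_data))
  if (tf && !tm) return(sex_estimate(method, "XX", "conditional", low_data))
  # spans both boundaries, or lies strictly between them
  sex_estimate(method, "indeterminate", "none", low_data,
               diagnostic = if (tm && tf) "CI spans both thresholds"
               else "CI entirely between thresholds")
}

# Region pairs for the two statistics.
ry_regions <- function(config) {
  list(male = list(bound = config$ry_male, side = "above"),
       female = list(bound = config$ry_female, side = "below"))
}

rx_regions <- function(config) {
  list(male = list(bound = config$rx_male, side = "below"),
       female = list(bound = config$rx_female, side = "above"))
}

ratio_result <- function(statistic, point, ci_low, ci_high, estimate, config,
                         n_sex_reads = NA_integer_, per_autosome = NULL) {
  structure(
    list(statistic = statistic, point = point,
         ci_low = ci_low, ci_high = ci_high,
         n_sex_reads = n_sex_reads, per_autosome_ratios = per_autosome,
         estimate = estimate, thresholds_used = config),
    class = "ratio_result"
  )
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("%s = %s  95%% CI [%s, %s]  -> %s %s%s\n",
              x$statistic,
              formatC(x$point, digits = 4, format = "fg"),
              formatC(x$ci_low, digits = 4, format = "fg"),
              formatC(x$ci_high, digits = 4, format = "fg"),
              x$estimate$sex, x$estimate$certainty,
              if (x$estimate$low_data) " [low-data]" else ""))
  invisible(x)
}

#' Ry: Y-mapped reads over all sex-chromosome-mapped reads
#'
#' Computes `Ry = nY / (nX + nY)` with a normal-approximation (Wald) binomial
#' 95% interval `Ry +/- z * sqrt(Ry (1 - Ry) / (nX + nY))`, clipped to
#' `[0, 1]`, and classifies the interval against the male (> 0.075) and
#' female (< 0.016) regions. Expected near 0 for XX individuals (residual
#' mismapping only) and elevated for XY. No X/Y homology masking is applied;
#' the method relies on read depth, which is why the advisory low-data flag
#' (total mapped < `min_total_reads` and sex-chromosome reads <
#' `min_sexchrom_reads`) travels with the result.
#'
#' @param counts A [chrom_counts()] object.
#' @param config A [threshold_config()].
#' @return A `ratio_result` with fields `point`, `ci_low`, `ci_high`,
#'   `n_sex_reads`, `estimate`.
#' @examples
#' m <- setNames(c(rep(4000, 22), 900, 100), canonical_chromosomes())
#' compute_ry(chrom_counts(hg19_chromosome_lengths(), m))
#' @export
compute_ry <- function(counts, config = threshold_config()) {
  stopifnot(inherits(counts, "chrom_counts"))
  n_x <- counts$mapped[counts$chrom == "X"]
  n_y <- counts$mapped[counts$chrom == "Y"]
  n <- n_x + n_y
  low_data <- total_mapped(counts) < config$min_total_reads &&
    n < config$min_sexchrom_reads
  if (n == 0) {
    est <- sex_estimate("ry", "indeterminate", "none", low_data,
                        diagnostic = "no reads mapped to X or Y")
    return(ratio_result("RY", NA_real_, NA_real_, NA_real_, est, config,
                        n_sex_reads = 0L))
  }
  p <- n_y / n
  half <- config$ci_multiplier * sqrt(p * (1 - p) / n)
  lo <- max(0, p - half)
  hi <- min(1, p + half)
  reg <- ry_regions(config)
  est <- classify_interval(p, lo, hi, reg$male, reg$female,
                           method = "ry", low_data = low_data)
  ratio_result("RY", p, lo, hi, est, config, n_sex_reads = as.integer(n))
}

#' Rx: X-chromosome read rate relative to each autosome
#'
#' For each chromosome, the read rate is mapped reads divided by chromosome
#' length. Rx is the mean over the 22 autosomes of `rate_X / rate_i`, with a
#' 95% interval `mean +/- z * sd / sqrt(22)` (sample SD over the 22 ratios),
#' classified against the male (< 0.60) and female (> 0.80) regions. Expected
#' near 1 for XX (two X copies, like the autosomes) and near 0.5 for XY.
#'
#' @inheritParams compute_ry
#' @return A `ratio_result` with `per_autosome_ratios` (named, 22 entries).
#' @export
compute_rx <- function(counts, config = threshold_config()) {
  stopifnot(inherits(counts, "chrom_counts"))
  low_data <- total_mapped(counts) < config$min_total_reads &&
    sum(counts$mapped[counts$chrom %in% c("X", "Y")]) < config$min_sexchrom_reads
  autos <- counts[counts$chrom %in% as.character(1:22), ]
  x_row <- counts[counts$chrom == "X", ]
  if (any(autos$mapped == 0)) {
    est <- sex_estimate("rx", "indeterminate", "none", low_data,
                        diagnostic = paste0("autosome(s) with zero reads: ",
                                            paste(autos$chrom[autos$mapped == 0],
                                                  collapse = ",")))
    return(ratio_result("RX", NA_real_, NA_real_, NA_real_, est, config))
  }
  rate_x <- x_row$mapped / x_row$length_bp
  rates <- autos$mapped / autos$length_bp
  ratios <- stats::setNames(rate_x / rates, autos$chrom)
  point <- mean(ratios)
  half <- config$ci_multiplier * stats::sd(ratios) / sqrt(length(ratios))
  lo <- point - half
  hi <- point + half
  reg <- rx_regions(config)
  est <- classify_interval(point, lo, hi, reg$male, reg$female,
                           method = "rx", low_data = low_data)
  ratio_result("RX", point, lo, hi, est, config, per_autosome = ratios)
}

#' Down-sample a count table without replacement
#'
#' Draws `target_total` reads from the sample's mapped reads by multivariate
#' hypergeometric sampling across the 24 chromosomes, preserving expected
#' per-chromosome proportions. Deterministic under a fixed seed.
#'
#' @param counts A [chrom_counts()] object.
#' @param target_total Number of reads to retain (<= total mapped).
#' @param seed Integer seed.
#' @return A [chrom_counts()] object with the same lengths.
#' @export
downsample_counts <- function(counts, target_total, seed = NULL) {
  stopifnot(inherits(counts, "chrom_counts"))
  total <- total_mapped(counts)
  if (target_total > total) {
    stop("target_total (", target_total, ") exceeds total mapped (", total, ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  remaining_pool <- total
  remaining_draw <- target_total
  out <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    m <- counts$mapped[i]
    # reads of chromosome i among a draw of remaining_draw from remaining_pool
    k <- stats::rhyper(1, m, remaining_pool - m, remaining_draw)
    out[i] <- k
    remaining_pool <- remaining_pool - m
    remaining_draw <- remaining_draw - k
  }
  chrom_counts(stats::setNames(counts$length_bp, counts$chrom),
               stats::setNames(out, counts$chrom),
               sample_id = attr(counts, "sample_id"))
}

#' Classification reliability as a function of read depth
#'
#' Repeatedly down-samples a deeply sequenced (or synthetic) sample of known
#' karyotype to each depth on a grid, classifies every replicate, and
#' aggregates the fraction of definitive, conditional and indeterminate calls
#' plus (when the true karyotype is supplied) the fraction of calls
#' conflicting with truth.
#'
#' @param counts A [chrom_counts()] object.
#' @param depth_grid Integer vector of target total read depths.
#' @param replicates Replicates per depth.
#' @param seed Integer seed.
#' @param config A [threshold_config()].
#' @param statistic `"RY"` or `"RX"`.
#' @param truth Optional true karyotype, `"XX"` or `"XY"`.
#' @return Data frame with one row per depth: `depth`, `statistic`,
#'   `frac_definitive`, `frac_conditional`, `frac_indeterminate`,
#'   `frac_conflict` (NA without truth).
#' @export
depth_reliability_curve <- function(counts, depth_grid, replicates = 50,
                                    seed = 1L, config = threshold_config(),
                                    statistic = c("RY", "RX"), truth = NULL) {
  statistic <- match.arg(statistic)
  if (!length(depth_grid)) stop("empty depth grid", call. = FALSE)
  set.seed(seed)
  rows <- lapply(depth_grid, function(d) {
    calls <- replicate(replicates, {
      ds <- downsample_counts(counts, d)
      res <- if (statistic == "RY") compute_ry(ds, config) else compute_rx(ds, config)
      c(res$estimate$certainty, res$estimate$sex)
    })
    cert <- calls[1, ]
    sex <- calls[2, ]
    data.frame(
      depth = d, statistic = statistic,
      frac_definitive = mean(cert == "definitive"),
      frac_conditional = mean(cert == "conditional"),
      frac_indeterminate = mean(cert == "none"),
      frac_conflict = if (is.null(truth)) NA_real_
      else mean(sex != "indeterminate" & sex != truth),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
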