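# Cross-method concordance accounting over a sex_cohort.

method_cols <- function(cohort, method) {
  method <- match.arg(method, sex_methods())
  sx <- cohort[[paste0(method, "_sex")]]
  ct <- cohort[[paste0(method, "_certainty")]]
  if (is.null(sx)) stop("method not present in cohort: ", method, call. = FALSE)
  list(sex = sx, certainty = ct)
}

#' Per-method sensitivity summary
#'
#' For every method in the cohort: how many samples received a call
#' (non-indeterminate), split into definitive and conditional-tier
#' (probable/possible included), plus the fraction called of the whole
#' cohort.
#'
#' @param cohort A `sex_cohort`.
#' @return Data frame with one row per method: `method`, `n_called`,
#'   `n_definitive`, `n_conditional`, `n_indeterminate`, `fraction_called`.
#' @examples
#' sensitivity_summary(load_fixture_cohort())
#' @export
sensitivity_summary <- function(cohort) {
  stopifnot(inherits(cohort, "sex_cohort"), nrow(cohort) > 0)
  rows <- lapply(attr(cohort, "methods"), function(m) {
    mc <- method_cols(cohort, m)
    tier <- certainty_tier(mc$certainty)
    data.frame(
      method = m,
      n_called = sum(mc$sex != "indeterminate"),
      n_definitive = sum(tier == "definitive", na.rm = TRUE),
      n_conditional = sum(tier == "conditional", na.rm = TRUE),
      n_indeterminate = sum(mc$sex == "indeterminate"),
      fraction_called = mean(mc$sex != "indeterminate"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise agreement between two methods
#'
#' Denominator: samples where both methods are non-indeterminate. Agreements
#' are same-sex calls; conflicts are partitioned into definitive (both calls
#' definitive) and conditional (at least one call in the conditional tier;
#' osteological probable/possible count as conditional). Per-cell sample-id
#' lists are retained for audit.
#'
#' @param cohort A `sex_cohort`.
#' @param method_a,method_b Two of [sex_methods()].
#' @return An object of class `pairwise_agreement`: list with
#'   `n_both_called`, `n_agree`, `n_conflict_definitive`,
#'   `n_conflict_conditional`, and `ids` (list of sample-id vectors per
#'   cell).
#' @examples
#' pairwise_agreement(load_fixture_cohort(), "oste", "prot")
#' @export
pairwise_agreement <- function(cohort, method_a, method_b) {
  a <- method_cols(cohort, method_a)
  b <- method_cols(cohort, method_b)
  both <- a$sex != "indeterminate" & b$sex != "indeterminate"
  agree <- both & a$sex == b$sex
  conflict <- both & a$sex != b$sex
  both_def <- certainty_tier(a$certainty) == "definitive" &
    certainty_tier(b$certainty) == "definitive"
  conf_def <- conflict & both_def
  conf_cond <- conflict & !both_def
  ids <- cohort$sample_id
  structure(
    list(method_a = method_a, method_b = method_b,
         n_both_called = sum(both), n_agree = sum(agree),
         n_conflict_definitive = sum(conf_def),
         n_conflict_conditional = sum(conf_cond),
         ids = list(agree = ids[agree],
                    conflict_definitive = ids[conf_def],
                    conflict_conditional = ids[conf_cond])),
    class = "pairwise_agreement")
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  cat(sprintf("%s vs %s: %d/%d agree; conflicts: %d definitive, %d conditional\n",
              x$method_a, x$method_b, x$n_agree, x$n_both_called,
              x$n_conflict_definitive, x$n_conflict_conditional))
  invisible(x)
}

#' Conflicts with a reference method, stratified by read depth
#'
#' Splits samples where both the genomic method and the reference method are
#' called at a total-read threshold (strictly above vs at-or-below) and, within
#' each stratum, counts calls and reference conflicts per certainty tier.
#' Zero conflicts above threshold is reported, never assumed. Samples with a
#' missing read count are excluded and tallied.
#'
#' @param cohort A `sex_cohort` with `total_mapped_reads`.
#' @param genomic_method `"ry"` or `"rx"`.
#' @param reference_method Reference method. Default `"prot"`.
#' @param threshold Total-read threshold. Default 100,000.
#' @return An object of class `stratified_conflicts`: list with `threshold`
#'   and a `cells` data frame (`stratum` x `tier` -> `n`, `n_conflict`),
#'   plus `n_excluded_missing_reads`.
#' @examples
#' stratified_conflicts(load_fixture_cohort(), "rx")
#' @export
stratified_conflicts <- function(cohort, genomic_method,
                                 reference_method = "prot",
                                 threshold = 100000) {
  g <- method_cols(cohort, genomic_method)
  r <- method_cols(cohort, reference_method)
  reads <- cohort$total_mapped_reads
  usable <- !is.na(reads)
  both <- usable & g$sex != "indeterminate" & r$sex != "indeterminate"
  tier <- certainty_tier(g$certainty)
  stratum <- ifelse(reads > threshold, "above", "below")
  cells <- expand.grid(stratum = c("above", "below"),
                       tier = c("definitive", "conditional"),
                       stringsAsFactors = FALSE)
  cells$n <- NA_integer_
  cells$n_conflict <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sel <- both & stratum == cells$stratum[i] & tier == cells$tier[i]
    cells$n[i] <- sum(sel, na.rm = TRUE)
    cells$n_conflict[i] <- sum(sel & g$sex != r$sex, na.rm = TRUE)
  }
  structure(
    list(genomic_method = genomic_method, reference_method = reference_method,
         threshold = threshold, cells = cells,
         n_excluded_missing_reads = sum(!usable)),
    class = "stratified_conflicts")
}

#' @export
print.stratified_conflicts <- function(x, ...) {
  cat(sprintf("%s vs %s at %s reads:\n", x$genomic_method, x$reference_method,
              format(x$threshold, big.mark = ",")))
  print(x$cells, row.names = FALSE)
  if (x$n_excluded_missing_reads)
    cat(" excluded (missing reads):", x$n_excluded_missing_reads, "\n")
  invisible(x)
}

#' Read-depth census
#'
#' How many samples strictly exceed a total-read threshold.
#'
#' @param cohort A `sex_cohort`.
#' @param threshold Total-read threshold.
#' @return List `n_above`, `n_total`, `fraction`.
#' @examples
#' reads_threshold_census(load_fixture_cohort(), 100000)
#' @export
reads_threshold_census <- function(cohort, threshold = 100000) {
  reads <- cohort$total_mapped_reads
  stopifnot(!anyNA(reads))
  list(n_above = sum(reads > threshold), n_total = length(reads),
       fraction = mean(reads > threshold))
}

#' Pooled-variance t-test on log-transformed groups
#'
#' Log-transforms two groups of positive values (zeros/non-positives excluded
#' with a reported count) and applies the Student pooled-variance two-sample
#' t-test (df = n1 + n2 - 2), two-tailed — the preservation comparison used
#' for signal decay between site/period groups. Welch's correction is
#' deliberately not applied so the degrees of freedom stay at the pooled
#' value.
#'
#' @param values_a,values_b Numeric vectors.
#' @param base10 Use log10 (default) rather than natural log.
#' @return List `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `t`, `df`,
#'   `p`, `n_excluded`.
#' @export
log_group_compare <- function(values_a, values_b, base10 = TRUE) {
  lg <- if (base10) log10 else log
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  excl <- sum(a <= 0) + sum(b <= 0)
  a <- lg(a[a > 0])
  b <- lg(b[b > 0])
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 positive values", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  df <- n1 + n2 - 2
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(t), df)
  list(mean_a = mean(a), sd_a = stats::sd(a), n_a = n1,
       mean_b = mean(b), sd_b = stats::sd(b), n_b = n2,
       t = t, df = df, p = p, n_excluded = excl)
}

#' Log-log ordinary least squares regression
#'
#' Pairwise excludes non-positive values, regresses log10(y) on log10(x) and
#' reports the slope with its two-tailed p-value (df = n - 2) — the
#' preservation cross-correlation between DNA depth and proteomic signal.
#'
#' @param x_values,y_values Paired numeric vectors.
#' @return List `slope`, `intercept`, `df`, `p_slope`, `n_used`.
#' @export
log_regression <- function(x_values, y_values) {
  stopifnot(length(x_values) == length(y_values))
  ok <- !is.na(x_values) & !is.na(y_values) & x_values > 0 & y_values > 0
  if (sum(ok) < 3) stop("need >= 3 positive pairs", call. = FALSE)
  lx <- log10(x_values[ok])
  ly <- log10(y_values[ok])
  fit <- stats::lm(ly ~ lx)
  cf <- summary(fit)$coefficients
  p_slope <- if (nrow(cf) < 2 || is.na(cf["lx", 4])) NA_real_ else cf["lx", 4]
  slope <- if (nrow(cf) < 2) 0 else unname(cf["lx", 1])
  list(slope = slope, intercept = unname(cf[1, 1]),
       df = fit$df.residual, p_slope = p_slope, n_used = sum(ok))
}
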