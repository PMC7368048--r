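#' Classification thresholds for the three sex-estimation tracks
#'
#' Bundles every tunable cutoff used by the genomic and proteomic classifiers.
#' Defaults follow the published method thresholds: the Ry male/female bands
#' (> 0.075 male, < 0.016 female), the Rx bands (< 0.60 male, > 0.80 female),
#' the 100,000 total-read / 3,000 sex-chromosome-read confidence minima, the
#' "more than two unique AMELY peptides" male rule, and the Pr(F) = 0.5
#' indeterminate cutoff.
#'
#' @param ry_male Ry value above which the male (XY) region starts.
#' @param ry_female Ry value below which the female (XX) region starts.
#' @param rx_male Rx value below which the male region starts.
#' @param rx_female Rx value above which the female region starts.
#' @param ci_multiplier Half-width multiplier for 95% confidence intervals.
#' @param min_total_reads Advisory minimum total mapped reads for a confident
#'   genomic estimate.
#' @param min_sexchrom_reads Advisory minimum X+Y mapped reads; a sample
#'   clearing either minimum is not flagged as low-data.
#' @param min_amely_peptides Exclusive threshold on unique AMELY peptides for a
#'   male proteomic call (male requires count strictly greater).
#' @param prf_cutoff Pr(F) at or above which a female proteomic call is made.
#'
#' @return An object of class `threshold_config`.
#' @examples
#' cfg <- threshold_config()
#' cfg$ry_male
#' @export
threshold_config <- function(ry_male = 0.075, ry_female = 0.016,
                             rx_male = 0.60, rx_female = 0.80,
                             ci_multiplier = 1.96,
                             min_total_reads = 100000L,
                             min_sexchrom_reads = 3000L,
                             min_amely_peptides = 2L,
                             prf_cutoff = 0.5) {
  stopifnot(
    is.numeric(ry_male), is.numeric(ry_female), ry_female < ry_male,
    ry_male > 0, ry_male < 1, ry_female > 0, ry_female < 1,
    is.numeric(rx_male), is.numeric(rx_female), rx_male < rx_female,
    rx_male > 0, rx_female > 0,
    ci_multiplier > 0,
    min_total_reads >= 0, min_sexchrom_reads >= 0,
    min_amely_peptides >= 0,
    prf_cutoff > 0, prf_cutoff < 1
  )
  structure(
    list(
      ry_male = ry_male, ry_female = ry_female,
      rx_male = rx_male, rx_female = rx_female,
      ci_multiplier = ci_multiplier,
      min_total_reads = as.integer(min_total_reads),
      min_sexchrom_reads = as.integer(min_sexchrom_reads),
      min_amely_peptides = as.integer(min_amely_peptides),
      prf_cutoff = prf_cutoff
    ),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Sex-estimation thresholds\n")
  cat(sprintf("  Ry: male > %g, female < %g\n", x$ry_male, x$ry_female))
  cat(sprintf("  Rx: male < %g, female > %g\n", x$rx_male, x$rx_female))
  cat(sprintf("  CI multiplier: %g\n", x$ci_multiplier))
  cat(sprintf("  Confidence minima: %d total reads or %d sex-chromosome reads\n",
              x$min_total_reads, x$min_sexchrom_reads))
  cat(sprintf("  Male proteomic rule: > %d unique AMELY peptides; Pr(F) cutoff %g\n",
              x$min_amely_peptides, x$prf_cutoff))
  invisible(x)
}
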