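#' Parse a categorical sex label into a structured estimate
#'
#' Understands the compact dialect used in published cohort tables: `"F"` /
#' `"M"` for definitive calls, `"F*"` / `"M*"` for conditional calls
#' (asterisk = conditional), `"Indet"` for indeterminate, plus the expert
#' osteological phrases `"probable F"`, `"possible M"`, etc. For osteology the
#' asterisk dialect maps to the probable tier (the higher conditional tier);
#' for the genomic methods it maps to conditional.
#'
#' @param label Character label.
#' @param method One of [sex_methods()].
#' @return A [sex_estimate()].
#' @examples
#' parse_sex_label("F*", "rx")
#' parse_sex_label("probable M", "oste")
#' @export
parse_sex_label <- function(label, method) {
  method <- match.arg(method, sex_methods())
  lab <- trimws(label)
  if (is.na(lab) || lab %in% c("Indet", "indet", "Indeterminate", "")) {
    return(sex_estimate(method, "indeterminate", "none"))
  }
  tier <- NULL
  if (grepl("^probable ", lab)) {
    tier <- "probable"; lab <- sub("^probable ", "", lab)
  } else if (grepl("^possible ", lab)) {
    tier <- "possible"; lab <- sub("^possible ", "", lab)
  } else if (grepl("\\*$", lab)) {
    tier <- if (method == "oste") "probable" else "conditional"
    lab <- sub("\\*$", "", lab)
  } else {
    tier <- "definitive"
  }
  sex <- switch(lab, F = "XX", M = "XY",
                stop("unknown sex label: ", label, call. = FALSE))
  if (tier %in% c("probable", "possible") && method != "oste") tier <- "conditional"
  sex_estimate(method, sex, tier)
}

# Vectorized label parse -> list(sex=, certainty=) character vectors.
parse_label_columns <- function(labels, method) {
  est <- lapply(labels, parse_sex_label, method = method)
  list(sex = vapply(est, `[[`, "", "sex"),
       certainty = vapply(est, `[[`, "", "certainty"))
}

#' Assemble a cohort table from per-sample labels
#'
#' A cohort is a data frame with one row per individual carrying the verbatim
#' labels of each method plus their parsed sex/certainty columns, read
#' counts and covariates. All concordance statistics operate on this shape.
#'
#' @param df Data frame with columns `sample_id`, `site`,
#'   `total_mapped_reads`, and one label column per method (`oste`, `ry`,
#'   `rx`, `prot`). Optional columns (e.g. `age_cal_bp`, `amelx_ci_per_mg`)
#'   are carried through.
#' @param provenance One of `"fixture"`, `"user"`, `"synthetic"`.
#' @return A `sex_cohort` data frame with added `<method>_sex` and
#'   `<method>_certainty` columns.
#' @export
as_sex_cohort <- function(df, provenance = "user") {
  provenance <- match.arg(provenance, c("fixture", "user", "synthetic"))
  need <- c("sample_id", "site", "total_mapped_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(duplicated(df$sample_id))) stop("duplicated sample_id", call. = FALSE)
  methods_present <- intersect(sex_methods(), names(df))
  if (!length(methods_present)) stop("no method label columns present", call. = FALSE)
  df$total_mapped_reads <- as.numeric(df$total_mapped_reads)
  for (m in methods_present) {
    parsed <- parse_label_columns(df[[m]], m)
    df[[paste0(m, "_sex")]] <- parsed$sex
    df[[paste0(m, "_certainty")]] <- parsed$certainty
  }
  structure(df, provenance = provenance,
            methods = methods_present,
            class = c("sex_cohort", "data.frame"))
}

#' Load the packaged 55-sample reference cohort
#'
#' The bundled fixture transcribes a published table of 55 individuals from
#' two Central Californian ancestral Ohlone sites (abbreviated ST and RTKT),
#' ordered by increasing number of mapped human DNA reads, with the
#' categorical sex estimates of all four method tracks (osteology, Ry, Rx,
#' proteomics; conditional calls marked with an asterisk).
#'
#' @return A `sex_cohort` of 55 rows, provenance `"fixture"`.
#' @examples
#' coh <- load_fixture_cohort()
#' nrow(coh)
#' @export
load_fixture_cohort <- function() {
  path <- system.file("extdata", "table2_cohort.tsv", package = "paleosex",
                      mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  df$total_mapped_reads <- as.numeric(df$total_mapped_reads)
  as_sex_cohort(df, provenance = "fixture")
}

#' Full names of the fixture sites
#'
#' @return Named character vector mapping the site codes used in sample ids
#'   to full site names.
#' @export
site_names <- function() {
  c(ST = "Sii Tuupentak (CA-ALA-565/H)",
    RTKT = "Rummey Ta Kuccuwis Tiprectak (CA-ALA-704/H)")
}

#' Write a cohort report
#'
#' Serializes a cohort to TSV (header first, `#`-prefixed provenance comments)
#' or JSON. Both dialects round-trip losslessly through [read_report()].
#'
#' @param cohort A `sex_cohort`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param header Optional named character vector recorded as `# key: value`
#'   comment lines (TSV) or a `header` object (JSON), e.g. seed and
#'   threshold provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(cohort, path, format = c("tsv", "json"), header = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "sex_cohort"))
  if (nrow(cohort) == 0) stop("refusing to write an empty cohort", call. = FALSE)
  meta <- c(provenance = attr(cohort, "provenance"),
            methods = paste(attr(cohort, "methods"), collapse = ","),
            header)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
    utils::write.table(as.data.frame(cohort), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(
      list(header = as.list(meta), samples = as.data.frame(cohort)),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort report written by [write_report()]
#'
#' @param path Path to the TSV or JSON report.
#' @param format `"tsv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return A `sex_cohort`.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    lines <- readLines(path)
    meta_lines <- grep("^# ", lines, value = TRUE)
    meta <- stats::setNames(
      sub("^# [^:]+: ?", "", meta_lines),
      sub("^# ([^:]+):.*$", "\\1", meta_lines))
    df <- utils::read.delim(text = lines[!grepl("^# ", lines)],
                            colClasses = "character", na.strings = "NA")
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    meta <- unlist(obj$header)
    df <- obj$samples
    df[] <- lapply(df, function(col) if (is.logical(col) && all(is.na(col)))
      NA_character_ else col)
  }
  numeric_cols <- intersect(
    c("total_mapped_reads", "age_cal_bp", "enamel_mass_mg",
      "amelx_ci_per_mg", "amely_ci_per_mg", "x_log10", "prf", "ry_point",
      "ry_lo", "ry_hi", "rx_point", "rx_lo", "rx_hi", "n_amely_unique"),
    names(df))
  for (cl in numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
  methods_present <- intersect(sex_methods(), names(df))
  df <- df[, !grepl("_(sex|certainty)$", names(df)), drop = FALSE]
  as_sex_cohort(df, provenance = if (identical(unname(meta["provenance"]),
                                               "fixture")) "fixture"
                else if (identical(unname(meta["provenance"]), "synthetic"))
                  "synthetic" else "user")
}

#' @export
print.sex_cohort <- function(x, ...) {
  cat(sprintf("sex_cohort: %d samples (%s), methods: %s\n",
              nrow(x), attr(x, "provenance"),
              paste(attr(x, "methods"), collapse = ", ")))
  NextMethod()
}
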