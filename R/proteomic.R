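#' Bundled amelogenin isoform sequences
#'
#' Returns the packaged X/Y amelogenin isoform pair used for peptide
#' specificity assignment and by the synthetic peptide generator. The bundled
#' sequences are constructed stand-ins (shared core plus divergent segments,
#' marked `_SYNTH` and `synthetic` in the FASTA) — not the canonical UniProt
#' entries, which cannot be redistributed here. Substitute real isoforms via
#' the `path` argument for production use.
#'
#' @param path Optional path to a FASTA with two amino-acid records, X
#'   isoform first.
#' @return Named character vector `c(AMELX = ..., AMELY = ...)`.
#' @export
amelogenin_isoforms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "amelogenin_isoforms_synthetic.fasta",
                        package = "paleosex", mustWork = TRUE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 2) stop("isoform FASTA must contain exactly 2 records",
                              call. = FALSE)
  stats::setNames(as.character(seqs), c("AMELX", "AMELY"))
}

#' Strip post-translational modification annotations from a peptide string
#'
#' Removes common spectral-matching annotation dialects: inline parenthesized
#' or bracketed mass/PTM tokens (`"PEPT(+.98)IDE"`, `"PEPT[+15.99]IDE"`) and
#' trailing ` + Modification (residue)` descriptions, leaving the bare
#' uppercase residue sequence.
#'
#' @param x Character vector of annotated peptide strings.
#' @return Character vector of stripped sequences.
#' @examples
#' strip_modifications("PEPT(+.98)IDE")
#' strip_modifications("PEPTIDE + Oxidation (M)")
#' @export
strip_modifications <- function(x) {
  out <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", x)  # inline (+.98) / [+15.99]
  out <- sub("\\s+\\+.*$", "", out)              # trailing " + Oxidation"
  out <- gsub("[^A-Za-z]", "", out)
  toupper(out)
}

#' Assign chromosome specificity to peptides
#'
#' Classifies each peptide by substring containment against the X and Y
#' amelogenin isoforms, after stripping modification annotations: contained
#' only in X is `X_specific`, only in Y `Y_specific`, in both `shared`
#' (homologous, filtered from the combined signal), in neither `unmatched`.
#' With `il_equivalent = TRUE`, isoleucine and leucine are treated as equal
#' (they are isobaric and indistinguishable by mass).
#'
#' @param peptides Character vector of (possibly annotated) peptide sequences.
#' @param amelx,amely Isoform sequences; default the bundled pair.
#' @param il_equivalent Treat I and L as identical. Default `FALSE`.
#' @return Character vector over
#'   `{"X_specific","Y_specific","shared","unmatched"}`.
#' @examples
#' assign_specificity("GYINF", amelx = "MPLPPHPGHPGYINF", amely = "MPLPPHPGHPGYINL")
#' @export
assign_specificity <- function(peptides, amelx = NULL, amely = NULL,
                               il_equivalent = FALSE) {
  if (is.null(amelx) || is.null(amely)) {
    iso <- amelogenin_isoforms()
    if (is.null(amelx)) amelx <- iso[["AMELX"]]
    if (is.null(amely)) amely <- iso[["AMELY"]]
  }
  stripped <- strip_modifications(peptides)
  if (any(!nzchar(stripped))) stop("empty peptide sequence", call. = FALSE)
  canon <- function(s) if (il_equivalent) chartr("IL", "JJ", s) else s
  x_ref <- canon(toupper(amelx))
  y_ref <- canon(toupper(amely))
  pep <- canon(stripped)
  in_x <- vapply(pep, function(p) grepl(p, x_ref, fixed = TRUE), logical(1))
  in_y <- vapply(pep, function(p) grepl(p, y_ref, fixed = TRUE), logical(1))
  unname(ifelse(in_x & in_y, "shared",
                ifelse(in_x, "X_specific",
                       ifelse(in_y, "Y_specific", "unmatched"))))
}

#' Cumulative ion intensity per mg enamel
#'
#' Sums the intensities of every observation specific to the target
#' chromosome (all PTM variants of a peptide contribute) and divides by the
#' enamel mass. With a missing mass the raw sum is returned, flagged
#' `unnormalized` (attribute), so a CI/mg is never silently mislabelled.
#'
#' @param observations Data frame with columns `sequence`, `intensity` and
#'   `specificity` (from [assign_specificity()]).
#' @param target `"X"` or `"Y"`.
#' @param mass_mg Enamel mass in mg, or `NA`.
#' @return Numeric scalar (CI/mg, or raw cumulative intensity with attribute
#'   `unnormalized = TRUE` when mass is missing).
#' @export
cumulative_intensity <- function(observations, target = c("X", "Y"),
                                 mass_mg = NA_real_) {
  target <- match.arg(target)
  wanted <- paste0(target, "_specific")
  total <- sum(observations$intensity[observations$specificity == wanted])
  if (is.na(mass_mg)) {
    return(structure(total, unnormalized = TRUE))
  }
  stopifnot(mass_mg > 0)
  total / mass_mg
}

#' Four-parameter logistic model for the probability of female sex
#'
#' Parameters of `Pr(F) = 1 + (floor - 1) / (1 + (x / midpoint)^slope)`,
#' where `x` is log10 of the AMELX cumulative intensity per mg enamel. The
#' curve rises from `floor` (0.059) at low AMELX signal through
#' `(1 + floor)/2` at the midpoint (x = 7.54) toward 1.
#'
#' @param floor Lower asymptote.
#' @param midpoint x at which the curve is halfway between floor and ceiling.
#' @param slope Hill slope.
#' @return An object of class `prf_model`.
#' @export
prf_model <- function(floor = 0.059, midpoint = 7.54, slope = 13.99) {
  stopifnot(floor >= 0, floor < 1, midpoint > 0, slope > 0)
  structure(list(floor = floor, midpoint = midpoint, slope = slope,
                 ceiling = 1.0), class = "prf_model")
}

#' Probability of female sex from AMELX signal
#'
#' Evaluates the four-parameter logistic [prf_model()] at
#' `x = log10(AMELX CI/mg)`. Strictly increasing in `x`, with range
#' `(floor, 1)`.
#'
#' @param x log10 of the AMELX cumulative intensity per mg enamel; must be
#'   positive (the model is calibrated for CI/mg above 1).
#' @param model A [prf_model()].
#' @return Numeric vector of probabilities.
#' @examples
#' pr_female(7.54)          # (1 + 0.059) / 2
#' pr_female(c(6, 9))
#' @export
pr_female <- function(x, model = prf_model()) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("pr_female requires x > 0 (log10 CI/mg in the calibrated domain)",
         call. = FALSE)
  }
  model$ceiling + (model$floor - model$ceiling) /
    (1 + (x / model$midpoint)^model$slope)
}

#' Classify proteomic sex from AMELY peptide count and AMELX signal
#'
#' The male rule takes precedence: strictly more than
#' `config$min_amely_peptides` unique AMELY peptides is a definitive XY call
#' (Y-chromosome-diagnostic detection). Otherwise Pr(F) is evaluated from the
#' AMELX signal: at or above `config$prf_cutoff` is a definitive XX call, and
#' anything lower — or an absent/zero AMELX signal — is indeterminate.
#' Proteomic estimates in this framework are always definitive when called.
#'
#' @param n_amely_unique Count of distinct Y-specific stripped sequences.
#' @param amelx_ci_per_mg AMELX cumulative intensity per mg enamel.
#' @param config A [threshold_config()].
#' @param model A [prf_model()].
#' @return A [sex_estimate()] with attribute `prf` (the computed Pr(F), or
#'   `NA`).
#' @export
classify_proteomic <- function(n_amely_unique, amelx_ci_per_mg,
                               config = threshold_config(),
                               model = prf_model()) {
  if (!is.na(n_amely_unique) && n_amely_unique > config$min_amely_peptides) {
    return(structure(sex_estimate("prot", "XY", "definitive"), prf = NA_real_))
  }
  if (is.na(amelx_ci_per_mg) || amelx_ci_per_mg <= 1) {
    return(structure(
      sex_estimate("prot", "indeterminate", "none",
                   diagnostic = "no usable AMELX signal"),
      prf = NA_real_))
  }
  prf <- pr_female(log10(amelx_ci_per_mg), model)
  est <- if (prf >= config$prf_cutoff) {
    sex_estimate("prot", "XX", "definitive")
  } else {
    sex_estimate("prot", "indeterminate", "none",
                 diagnostic = sprintf("Pr(F) = %.3f below cutoff", prf))
  }
  structure(est, prf = prf)
}

#' Full proteomic sex-estimation pipeline for one sample
#'
#' Assigns specificity, counts unique AMELY peptides (distinct stripped
#' sequences; PTM variants count once but all contribute intensity), computes
#' both CI/mg values, evaluates Pr(F) and classifies.
#'
#' @param observations Data frame from [read_peptide_table()] (columns
#'   `sequence`, `modifications`, `intensity`, `accession`).
#' @param mass_mg Enamel mass in mg (`NA` allowed: intensities stay
#'   unnormalized and classification falls back to the peptide-count rule
#'   only).
#' @param config A [threshold_config()].
#' @param model A [prf_model()].
#' @param amelx,amely Isoform sequences (default bundled pair).
#' @param il_equivalent Passed to [assign_specificity()].
#' @return An object of class `proteomic_result`: list with
#'   `n_amely_unique`, `amelx_ci_per_mg`, `amely_ci_per_mg`, `x_log10`,
#'   `prf`, `estimate`, `specificity_report`.
#' @export
proteomic_sex <- function(observations, mass_mg = NA_real_,
                          config = threshold_config(), model = prf_model(),
                          amelx = NULL, amely = NULL, il_equivalent = FALSE) {
  obs <- observations
  if (nrow(obs) == 0) {
    est <- sex_estimate("prot", "indeterminate", "none",
                        diagnostic = "no amelogenin observations")
    return(structure(
      list(n_amely_unique = 0L, amelx_ci_per_mg = 0, amely_ci_per_mg = 0,
           x_log10 = NA_real_, prf = NA_real_, estimate = est,
           specificity_report = c(X_specific = 0L, Y_specific = 0L,
                                  shared = 0L, unmatched = 0L)),
      class = "proteomic_result"))
  }
  obs$specificity <- assign_specificity(obs$sequence, amelx, amely,
                                        il_equivalent = il_equivalent)
  obs$stripped <- strip_modifications(obs$sequence)
  n_amely <- length(unique(obs$stripped[obs$specificity == "Y_specific"]))
  ci_x <- cumulative_intensity(obs, "X", mass_mg)
  ci_y <- cumulative_intensity(obs, "Y", mass_mg)
  unnorm <- isTRUE(attr(ci_x, "unnormalized"))
  x_log10 <- if (!unnorm && ci_x > 1) log10(as.numeric(ci_x)) else NA_real_
  est <- classify_proteomic(n_amely, if (unnorm) NA_real_ else as.numeric(ci_x),
                            config, model)
  spec_report <- vapply(c("X_specific", "Y_specific", "shared", "unmatched"),
                        function(s) sum(obs$specificity == s), integer(1))
  structure(
    list(n_amely_unique = n_amely,
         amelx_ci_per_mg = as.numeric(ci_x), amely_ci_per_mg = as.numeric(ci_y),
         unnormalized = unnorm,
         x_log10 = x_log10, prf = attr(est, "prf"), estimate = est,
         specificity_report = spec_report),
    class = "proteomic_result")
}

#' @export
print.proteomic_result <- function(x, ...) {
  cat(sprintf("proteomic_result: %d unique AMELY peptides, AMELX CI%s = %.3g -> %s %s\n",
              x$n_amely_unique, if (isTRUE(x$unnormalized)) " (unnormalized)" else "/mg",
              x$amelx_ci_per_mg, x$estimate$sex, x$estimate$certainty))
  if (!is.na(x$prf)) cat(sprintf("  Pr(F) = %.3f\n", x$prf))
  invisible(x)
}

#' Contamination QC on blank runs
#'
#' A blank passes when it contains zero Y-specific spectra and at most
#' `x_tolerance` X-specific spectra (a single stray AMELX spectrum is within
#' ordinary carryover levels; any AMELY spectrum is disqualifying).
#'
#' @param blank_observations Data frame with a `sequence` column (and
#'   optionally `intensity`).
#' @param x_tolerance Maximum tolerated X-specific spectra. Default 1.
#' @param amelx,amely Isoform sequences (default bundled pair).
#' @param il_equivalent Passed to [assign_specificity()].
#' @return List with `pass` (logical), `n_x_specific`, `n_y_specific`,
#'   and `message`.
#' @export
blank_qc <- function(blank_observations, x_tolerance = 1L,
                     amelx = NULL, amely = NULL, il_equivalent = FALSE) {
  if (nrow(blank_observations) == 0) {
    return(list(pass = TRUE, n_x_specific = 0L, n_y_specific = 0L,
                message = "empty blank"))
  }
  spec <- assign_specificity(blank_observations$sequence, amelx, amely,
                             il_equivalent = il_equivalent)
  nx <- sum(spec == "X_specific")
  ny <- sum(spec == "Y_specific")
  pass <- ny == 0 && nx <= x_tolerance
  list(pass = pass, n_x_specific = nx, n_y_specific = ny,
       message = if (pass) "blank within tolerance"
       else sprintf("contamination: %d AMELY and %d AMELX specific spectra", ny, nx))
}

#' Read a peptide quantification table
#'
#' Parses a CSV export from spectral-matching software with columns
#' `sequence`, `modifications`, `intensity`, `protein_accession` (extra
#' columns ignored; header required). Intensities accept scientific notation
#' and must be non-negative.
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `sequence`, `modifications`, `intensity`,
#'   `accession`.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sequence", "modifications", "intensity", "protein_accession")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peptide table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(intensity) | !nzchar(trimws(df$sequence)))
  if (length(bad)) {
    stop("unparseable peptide row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  neg <- which(intensity < 0)
  if (length(neg)) {
    stop("negative intensity at line ", neg[1] + 1L, " of ", path, call. = FALSE)
  }
  data.frame(sequence = df$sequence, modifications = df$modifications,
             intensity = intensity, accession = df$protein_accession,
             stringsAsFactors = FALSE)
}
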