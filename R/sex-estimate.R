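#' A unified sex estimate
#'
#' The common currency of the three estimation tracks: a karyotype call
#' (XX / XY / indeterminate) with a certainty tier. Definitive calls have
#' confidence intervals entirely inside one sex region (or, for proteomics,
#' meet the unambiguous peptide rules); conditional ("consistent with ...")
#' genomic calls have intervals crossing exactly one definitive-region
#' boundary; osteological conditional calls use the probable/possible tiers;
#' indeterminate calls carry certainty "none".
#'
#' @param method One of `"oste"`, `"ry"`, `"rx"`, `"prot"`.
#' @param sex One of `"XX"`, `"XY"`, `"indeterminate"`.
#' @param certainty One of `"definitive"`, `"conditional"`, `"probable"`,
#'   `"possible"`, `"none"`. Must be `"none"` iff sex is indeterminate;
#'   probable/possible are osteology-only, conditional is genomic-only.
#' @param low_data `TRUE` when a genomic estimate was made below both
#'   advisory read minima. Advisory metadata: never alters the call.
#' @param diagnostic Optional free-text reason (e.g. "no sex-chromosome
#'   reads").
#'
#' @return An object of class `sex_estimate`.
#' @examples
#' sex_estimate("ry", "XY", "definitive")
#' sex_estimate("prot", "indeterminate", "none")
#' @export
sex_estimate <- function(method, sex, certainty, low_data = FALSE,
                         diagnostic = NA_character_) {
  method <- match.arg(method, sex_methods())
  sex <- match.arg(sex, c("XX", "XY", "indeterminate"))
  certainty <- match.arg(certainty,
                         c("definitive", "conditional", "probable", "possible", "none"))
  if ((sex == "indeterminate") != (certainty == "none")) {
    stop("sex 'indeterminate' iff certainty 'none'", call. = FALSE)
  }
  if (certainty %in% c("probable", "possible") && method != "oste") {
    stop("probable/possible tiers are osteology-only", call. = FALSE)
  }
  if (certainty == "conditional" && !method %in% c("ry", "rx")) {
    stop("conditional tier is genomic-only", call. = FALSE)
  }
  structure(
    list(method = method, sex = sex, certainty = certainty,
         low_data = isTRUE(low_data), diagnostic = diagnostic),
    class = "sex_estimate"
  )
}

#' Methods recognized across the package
#'
#' @return Character vector `c("oste", "ry", "rx", "prot")`.
#' @export
sex_methods <- function() c("oste", "ry", "rx", "prot")

#' Map a certainty tier onto the two-tier definitive/conditional partition
#'
#' Osteological probable and possible both count as conditional for
#' cross-method accounting.
#'
#' @param certainty Character vector of certainty tiers.
#' @return `"definitive"`, `"conditional"` or `NA` (for `"none"`).
#' @export
certainty_tier <- function(certainty) {
  ifelse(certainty == "definitive", "definitive",
         ifelse(certainty %in% c("conditional", "probable", "possible"),
                "conditional", NA_character_))
}

#' @export
print.sex_estimate <- function(x, ...) {
  cat(sprintf("[%s] %s (%s)%s\n", x$method, x$sex, x$certainty,
              if (x$low_data) " [low-data]" else ""))
  if (!is.na(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
format.sex_estimate <- function(x, ...) {
  if (x$sex == "indeterminate") return("Indet")
  base <- if (x$sex == "XY") "M" else "F"
  if (x$certainty == "definitive") base else paste0(base, "*")
}
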