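#' The 20-trait osteological scoring scheme
#'
#' Returns the named traits grouped as pelvic (9, os coxae), cranial /
#' mandibular (6) and postcranial robusticity (5). Each trait is scored on a
#' five-point scale -2..+2 (negative = female-leaning expression, positive =
#' male-leaning), or `NA` when not observable.
#'
#' @return Named list of character vectors `pelvic`, `cranial`, `robusticity`.
#' @export
osteo_trait_names <- function() {
  list(
    pelvic = c("subpubic_concavity", "shape_of_pubis", "ventral_arc",
               "dorsal_pits", "acetabulum_size", "greater_sciatic_notch",
               "preauricular_sulcus", "auricular_surface",
               "acetabulum_dimensions"),
    cranial = c("nuchal_crest", "mastoid_process", "supraorbital_margin",
                "supraorbital_ridge", "mental_eminence", "ascending_ramus"),
    robusticity = c("glenoid_fossa_size", "vertical_humeral_head",
                    "humeral_epicondyle_width", "femoral_head_diameter",
                    "femoral_bicondyle_width")
  )
}

#' Ingest an expert categorical osteological estimate
#'
#' Converts an expert's categorical label into a structured estimate.
#' Accepted labels: `"F"`, `"M"` (definitive), `"probable F"`,
#' `"probable M"`, `"possible F"`, `"possible M"`, `"Indet"`, plus the
#' compact table dialect `"F*"` / `"M*"` (mapped to the probable tier).
#'
#' @param label Character label.
#' @return A [sex_estimate()] with method `"oste"`.
#' @examples
#' ingest_expert_estimate("probable F")
#' @export
ingest_expert_estimate <- function(label) {
  parse_sex_label(label, method = "oste")
}

#' Aggregate trait scores into a categorical estimate
#'
#' A package-defined surrogate for expert evaluation (the published scheme
#' delegates aggregation to expert judgment relative to the local
#' population): a weighted mean of available scores, pelvic traits double
#' weighted, compared against tier cutoffs. The sign gives the sex; the
#' magnitude the certainty tier. Juveniles — whose sexually dimorphic traits
#' have not yet developed — and all-missing score sets are indeterminate.
#'
#' @param scores Named numeric vector over the 20 traits of
#'   [osteo_trait_names()] (values in -2..2 or `NA`).
#' @param adult `FALSE` forces an indeterminate estimate.
#' @param pelvic_weight Relative weight of pelvic traits. Default 2.
#' @param cutoffs Named numeric vector `c(definitive =, probable =,
#'   possible =)`: minimum |weighted mean| for each tier.
#' @return A [sex_estimate()] with attribute `score` (the weighted mean).
#' @examples
#' s <- setNames(rep(NA_real_, 20), unlist(osteo_trait_names()))
#' s[c("ventral_arc", "dorsal_pits", "greater_sciatic_notch")] <- c(-2, -2, -1)
#' aggregate_traits(s)
#' @export
aggregate_traits <- function(scores, adult = TRUE, pelvic_weight = 2,
                             cutoffs = c(definitive = 1.5, probable = 0.75,
                                         possible = 0.25)) {
  traits <- osteo_trait_names()
  all_traits <- unlist(traits, use.names = FALSE)
  miss <- setdiff(all_traits, names(scores))
  if (length(miss)) stop("scores lack trait(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  extra <- setdiff(names(scores), all_traits)
  if (length(extra)) stop("unknown trait(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  vals <- scores[all_traits]
  ok <- !is.na(vals)
  if (any(abs(vals[ok]) > 2)) stop("scores must lie in -2..2", call. = FALSE)
  if (!isTRUE(adult) || !any(ok)) {
    return(structure(
      sex_estimate("oste", "indeterminate", "none",
                   diagnostic = if (!isTRUE(adult)) "juvenile" else "no scorable traits"),
      score = NA_real_))
  }
  w <- ifelse(all_traits %in% traits$pelvic, pelvic_weight, 1)
  m <- sum(w[ok] * vals[ok]) / sum(w[ok])
  tier <- if (abs(m) >= cutoffs[["definitive"]]) "definitive"
  else if (abs(m) >= cutoffs[["probable"]]) "probable"
  else if (abs(m) >= cutoffs[["possible"]]) "possible"
  else NA_character_
  est <- if (is.na(tier)) {
    sex_estimate("oste", "indeterminate", "none",
                 diagnostic = sprintf("weighted mean %.2f below possible cutoff", m))
  } else {
    sex_estimate("oste", if (m > 0) "XY" else "XX", tier)
  }
  structure(est, score = m)
}
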