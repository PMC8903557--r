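#' Classify covert vs open contraceptive use
#'
#' Covert use is the wife's use of a female modern spacing method that her
#' husband does not report: a couple is covert exactly when the husband
#' reports no non-barrier method at last sex *and* no condom use. If the
#' husband reports condom use, or any female modern method (the same as the
#' wife's or a different one), the use is open. The function is pure in its
#' three arguments and vectorized.
#'
#' @param wife_method Wife's current method; must be a reversible modern
#'   female method (`pill`, `iud`, `injectable`, `other_modern_female`) —
#'   the cohort filter guarantees this upstream.
#' @param husband_reports_nonbarrier_method Husband's last-sex non-barrier
#'   report: `none` or one of the four female methods.
#' @param husband_condom_last_sex Binary condom-at-last-sex flag.
#' @return A tibble with columns `covert` (integer 0/1) and `covert_reason`
#'   (`husband_reports_nothing`, `husband_reports_condom`,
#'   `husband_reports_same_method`, `husband_reports_other_female_method`).
#'   `covert == 1` iff the reason is `husband_reports_nothing`.
#' @export
#' @examples
#' classify_covert("pill", "none", 0)   # covert
#' classify_covert("pill", "none", 1)   # open: condom
#' classify_covert("iud", "pill", 0)    # open: different female method
classify_covert <- function(wife_method, husband_reports_nonbarrier_method,
                            husband_condom_last_sex) {
  if (any(!wife_method %in% METHODS_REVERSIBLE)) {
    abort("`wife_method` must be a reversible modern female method.")
  }
  if (any(!husband_reports_nonbarrier_method %in% METHODS_HUSBAND)) {
    abort("Unknown husband non-barrier report code.")
  }
  hr <- husband_reports_nonbarrier_method
  condom <- as.integer(husband_condom_last_sex)
  reason <- dplyr::case_when(
    condom == 1 ~ "husband_reports_condom",
    hr == "none" ~ "husband_reports_nothing",
    hr == wife_method ~ "husband_reports_same_method",
    TRUE ~ "husband_reports_other_female_method"
  )
  tibble::tibble(
    covert = as.integer(reason == "husband_reports_nothing"),
    covert_reason = reason
  )
}

#' Append the covert-use outcome to a couple table
#'
#' @param table Eligible couple table.
#' @return `table` with `covert` and `covert_reason` columns appended.
#' @export
add_covert_status <- function(table) {
  st <- classify_covert(table$wife_method,
                        table$husband_reports_nonbarrier_method,
                        table$husband_condom_last_sex)
  table$covert <- st$covert
  table$covert_reason <- st$covert_reason
  table
}

#' Weighted covert-method mix
#'
#' Weighted shares of the four reversible female methods among covert
#' users, together with the weighted covert prevalence (the weight share of
#' covert rows; with unit weights, the count ratio).
#'
#' @param wife_method Wife's method per couple.
#' @param covert Binary covert indicator per couple.
#' @param weights Analysis weights; default unit weights.
#' @return A list with `shares` (named numeric over the four methods,
#'   summing to 1; all-`NA` when there are no covert users, with
#'   `n_covert = 0`), `prevalence` (weighted covert share), and `n_covert`
#'   (unweighted covert count).
#' @export
method_mix <- function(wife_method, covert,
                       weights = rep(1, length(wife_method))) {
  stopifnot(length(wife_method) == length(covert),
            length(weights) == length(covert))
  prevalence <- sum(weights * covert) / sum(weights)
  idx <- covert == 1
  if (!any(idx)) {
    return(list(
      shares = setNames(rep(NA_real_, length(METHODS_REVERSIBLE)),
                        METHODS_REVERSIBLE),
      prevalence = prevalence, n_covert = 0L))
  }
  w <- tapply(weights[idx], factor(wife_method[idx],
                                   levels = METHODS_REVERSIBLE), sum,
              default = 0)
  shares <- as.numeric(w) / sum(w)
  names(shares) <- METHODS_REVERSIBLE
  list(shares = shares, prevalence = prevalence, n_covert = sum(idx))
}
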