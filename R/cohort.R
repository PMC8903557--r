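#' Read a couple file
#'
#' Reads the comma-delimited couple-file schema produced by
#' [write_couple_table()] (or prepared externally), types every column, and
#' validates categorical labels, reporting offending row numbers.
#'
#' @param path CSV path.
#' @param design_path Optional CSV of per-cluster eligible / interviewed
#'   couple counts, attached as the `cluster_design` attribute.
#' @return A typed tibble following the couple-file schema.
#' @export
read_couple_table <- function(path, design_path = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COUPLE_SCHEMA, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  check_labels <- function(col, allowed) {
    bad <- which(!is.na(tab[[col]]) & !(tab[[col]] %in% allowed))
    if (length(bad) > 0) {
      abort(sprintf(
        "Unknown %s label %s at row(s) %s.", col,
        paste(unique(tab[[col]][bad]), collapse = ", "),
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  check_labels("wife_method", METHODS_WIFE)
  check_labels("husband_reports_nonbarrier_method", METHODS_HUSBAND)
  check_labels("religion", RELIGION_LEVELS)
  check_labels("caste", CASTE_LEVELS)
  check_labels("residence", RESIDENCE_LEVELS)
  check_labels("wife_education", EDUCATION_LEVELS)
  check_labels("husband_education", EDUCATION_LEVELS)
  check_labels("region", REGION_LEVELS)
  check_labels("working", c("no", "yes"))
  for (col in c(ATTITUDE_ITEMS, ELIGIBILITY_FLAGS, "husband_condom_last_sex",
                "mobility_market", "mobility_health", "money_own",
                "wife_wants_more", "husband_wants_more")) {
    bad <- which(!is.na(tab[[col]]) & !(tab[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("Column %s must be 0/1; offending row(s): %s.", col,
                    paste(head(bad, 5), collapse = ", ")))
    }
    tab[[col]] <- as.integer(tab[[col]])
  }
  if (nrow(tab) > 0 && any(tab$hh_weight <= 0, na.rm = TRUE)) {
    abort("`hh_weight` must be strictly positive.")
  }
  if (!is.null(design_path)) {
    attr(tab, "cluster_design") <- readr::read_csv(
      design_path, show_col_types = FALSE, progress = FALSE)
  }
  tab
}

#' Apply the cohort eligibility filters
#'
#' Retains fecund, monogamous couples in which the wife currently uses a
#' reversible modern female (spacing) method — pill, IUD, injectable, or
#' another modern female method. Couples are dropped, in order, when the
#' husband is polygynous, his last sexual partner was not his wife,
#' contraception was adopted only after the last coitus, either partner is
#' sterilized, the wife uses a traditional method, the wife uses no method,
#' or the wife's method is otherwise outside the reversible female set
#' (e.g. condom).
#'
#' @param table A typed couple table.
#' @return The eligible subset, with a `drop_report` attribute: a tibble of
#'   per-rule drop counts in order of application.
#' @export
select_eligible_couples <- function(table) {
  rules <- c(ELIGIBILITY_FLAGS, "wife_method_not_reversible")
  keep <- rep(TRUE, nrow(table))
  dropped <- integer(length(rules))
  names(dropped) <- rules
  for (fl in ELIGIBILITY_FLAGS) {
    hit <- keep & table[[fl]] == 1
    dropped[fl] <- sum(hit)
    keep <- keep & !hit
  }
  hit <- keep & !(table$wife_method %in% METHODS_REVERSIBLE)
  dropped["wife_method_not_reversible"] <- sum(hit)
  keep <- keep & !hit
  out <- table[keep, , drop = FALSE]
  attr(out, "cluster_design") <- attr(table, "cluster_design")
  attr(out, "drop_report") <- tibble::tibble(
    rule = rules, n_dropped = unname(dropped))
  out
}

#' Construct normalized couple sampling weights
#'
#' Matched couple files carry household and individual weights but no
#' couple weight; applying either spouse's weight biases couple-level
#' estimates. The couple weight inflates the household weight by the
#' inverse cluster-level couple response rate:
#' raw weight = `hh_weight` x (eligible couples in cluster / couples with
#' both partners interviewed in cluster), then normalized so the mean over
#' analyzed couples is exactly 1.
#'
#' @param table Eligible couple table.
#' @param design Per-cluster counts (`cluster_id`, `n_eligible`,
#'   `n_interviewed`); defaults to the table's `cluster_design` attribute.
#'   When neither is available, full response is assumed and the weight
#'   reduces to the normalized household weight.
#' @return `table` with a `couple_weight` column appended (mean 1).
#' @export
compute_couple_weights <- function(table, design = NULL) {
  if (is.null(design)) design <- attr(table, "cluster_design")
  if (is.null(design)) {
    ratio <- rep(1, nrow(table))
  } else {
    zero <- design$n_interviewed == 0
    contradict <- zero & design$cluster_id %in% table$cluster_id &
      design$n_eligible > 0
    if (any(contradict)) {
      abort(sprintf(
        "Cluster(s) %s have interviewed count 0 yet contribute rows.",
        paste(design$cluster_id[contradict], collapse = ", ")))
    }
    if (any(zero & design$n_eligible > 0)) {
      warn(sprintf("Excluding %d cluster(s) with no interviewed couples.",
                   sum(zero & design$n_eligible > 0)))
    }
    idx <- match(table$cluster_id, design$cluster_id)
    if (anyNA(idx)) abort("Rows reference clusters absent from the design.")
    ratio <- design$n_eligible[idx] / design$n_interviewed[idx]
  }
  raw <- table$hh_weight * ratio
  table$couple_weight <- raw / mean(raw)
  table
}

#' Recode covariates into the analysis categories
#'
#' Adds the derived couple-level and socioeconomic analysis categories:
#' spousal age difference (`same_or_wife_older`, `husband_1-3`,
#' `husband_4-5`, `husband_6+`), educational difference (`no_difference`,
#' `wife_more`, `husband_more`), wealth group (quintiles 1-2 poor, 3
#' middle, 4-5 rich), living-children group (0 / 1 / 2 / 3+), and
#' concordance of the spouses' desire for more children. Every row receives
#' exactly one category per variable.
#'
#' @param table Eligible couple table.
#' @return The table with factor columns `age_diff_cat`, `edu_diff_cat`,
#'   `wealth_group`, `living_children_cat`, `concordance` appended.
#' @export
recode_covariates <- function(table) {
  if (nrow(table) > 0) {
    if (any(table$living_children < 0, na.rm = TRUE)) {
      abort("`living_children` must be non-negative.")
    }
    if (any(!table$wealth_quintile %in% 1:5)) {
      abort("`wealth_quintile` must lie in 1..5.")
    }
  }
  gap <- table$husband_age - table$wife_age
  table$age_diff_cat <- factor(
    dplyr::case_when(
      gap <= 0 ~ "same_or_wife_older",
      gap <= 3 ~ "husband_1-3",
      gap <= 5 ~ "husband_4-5",
      TRUE ~ "husband_6+"
    ),
    levels = c("same_or_wife_older", "husband_1-3", "husband_4-5",
               "husband_6+"))
  we <- match(table$wife_education, EDUCATION_LEVELS)
  he <- match(table$husband_education, EDUCATION_LEVELS)
  table$edu_diff_cat <- factor(
    dplyr::case_when(we == he ~ "no_difference",
                     we > he ~ "wife_more",
                     TRUE ~ "husband_more"),
    levels = c("no_difference", "wife_more", "husband_more"))
  table$wealth_group <- factor(
    dplyr::case_when(table$wealth_quintile <= 2 ~ "poor",
                     table$wealth_quintile == 3 ~ "middle",
                     TRUE ~ "rich"),
    levels = c("poor", "middle", "rich"))
  table$living_children_cat <- factor(
    ifelse(table$living_children >= 3, "3+",
           as.character(table$living_children)),
    levels = c("0", "1", "2", "3+"))
  table$concordance <- derive_concordance(table$wife_wants_more,
                                          table$husband_wants_more)
  table
}

#' Concordance of the spouses' desire for more children
#'
#' A couple is concordant (`"yes"`) when the wife's and the husband's
#' desire-for-more-children flags agree, discordant (`"no"`) otherwise.
#' Missing flags yield `NA`, marking the row for listwise deletion.
#'
#' @param wife_wants_more,husband_wants_more Binary (0/1) vectors.
#' @return Factor with levels `no`, `yes`.
#' @export
#' @examples
#' derive_concordance(c(1, 1, 0, 0), c(1, 0, 1, 0))
derive_concordance <- function(wife_wants_more, husband_wants_more) {
  factor(ifelse(wife_wants_more == husband_wants_more, "yes", "no"),
         levels = c("no", "yes"))
}
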