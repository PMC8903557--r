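#' Default simulation profile for couple microdata
#'
#' Builds the default [sim_config()] describing the study conditions the
#' generator emulates: a three-class latent structure of husband's gender
#' attitude with class shares 0.677 / 0.134 / 0.189 (high, moderate, low
#' egalitarian), class-conditional item-response profiles for the 12 binary
#' attitude items, class-dependent covert-use probabilities 0.234 / 0.353 /
#' 0.306, a covert-method mix dominated by pills (67.2%), NFHS-like
#' covariate distributions, and a cluster sampling design with couple
#' nonresponse.
#'
#' Item-response defaults are stated as the probability of the *positive*
#' (egalitarian, code 1) response. Class profiles are built from published
#' per-class ranges of negative-response chances, spread evenly across the
#' items of each battery; the low-egalitarian profile of the third battery
#' (husband's asserted rights when refused sex) is only characterised
#' qualitatively as the highest of the three classes, and defaults to
#' negative-response chances 0.30-0.45.
#'
#' @param n_couples Number of couples drawn before nonresponse. Default 7824.
#' @param seed Integer master seed for the generator.
#' @return A `sim_config` object (a named list).
#' @seealso [generate_couples()]
#' @export
#' @examples
#' cfg <- default_profiles(n_couples = 500, seed = 1)
#' cfg$delta
#' # implied marginal covert prevalence
#' sum(cfg$delta * cfg$covert_prob_by_class)
default_profiles <- function(n_couples = 7824, seed = 1L) {
  ## Per-class chance of the NEGATIVE response, battery by battery.
  neg_high <- c(
    seq(0.005, 0.051, length.out = 5),
    seq(0.015, 0.056, length.out = 3),
    c(0.06, 0.005, 0.005, 0.005)
  )
  neg_moderate <- c(
    seq(0.02, 0.10, length.out = 5),
    c(0.67, 0.94, 0.89),
    seq(0.02, 0.05, length.out = 4)
  )
  neg_low <- c(
    seq(0.27, 0.56, length.out = 5),
    c(0.13, 0.20, 0.24),
    c(0.30, 0.35, 0.40, 0.45)
  )
  tau <- rbind(high = 1 - neg_high, moderate = 1 - neg_moderate,
               low = 1 - neg_low)
  colnames(tau) <- ATTITUDE_ITEMS

  sim_config(
    n_couples = n_couples,
    delta = c(high = 0.677, moderate = 0.134, low = 0.189),
    tau = tau,
    covert_prob_by_class = c(high = 0.234, moderate = 0.353, low = 0.306),
    covert_logit_effects = numeric(0),
    method_mix = c(pill = 0.672, iud = 0.200, injectable = 0.080,
                   other_modern_female = 0.048),
    open_report_mix = c(same = 0.7, different = 0.1, condom = 0.2),
    covariate_specs = default_covariate_specs(),
    eligibility_violation_rate = 0.05,
    n_clusters = 200L,
    couple_response_rate_by_cluster = NULL,
    seed = seed
  )
}

## Category probabilities patterned on the marginal distributions of a large
## Indian couple survey (religion ~2/3 Hindu, ~60% rural, wealth skewed
## toward the upper quintiles among reversible-method users, etc.).
default_covariate_specs <- function() {
  list(
    religion = c(Hindu = 0.670, Muslim = 0.196, Other = 0.134),
    caste = c(`SC/ST` = 0.329, OBC = 0.353, Other = 0.318),
    residence = c(urban = 0.384, rural = 0.616),
    wife_education = c(`non-literate` = 0.184, primary = 0.129,
                       secondary = 0.520, higher = 0.167),
    husband_education = c(`non-literate` = 0.120, primary = 0.140,
                          secondary = 0.560, higher = 0.180),
    working = c(no = 0.814, yes = 0.186),
    wealth_quintile = c(`1` = 0.138, `2` = 0.138, `3` = 0.195,
                        `4` = 0.264, `5` = 0.265),
    living_children = c(`0` = 0.036, `1` = 0.291, `2` = 0.393,
                        `3` = 0.200, `4` = 0.080),
    region = c(North = 0.340, Northeast = 0.186, East = 0.151,
               West = 0.072, South = 0.029, Central = 0.222),
    age_gap = c(`same_or_wife_older` = 0.075, `1-3` = 0.362,
                `4-5` = 0.234, `6+` = 0.329),
    wife_age_mean = 28, wife_age_sd = 6,
    mobility_market = c(no = 0.409, yes = 0.591),
    mobility_health = c(no = 0.450, yes = 0.550),
    money_own = c(no = 0.526, yes = 0.474),
    wife_wants_more = c(no = 0.70, yes = 0.30),
    concordance_rate = 0.821
  )
}

#' Construct a simulation configuration
#'
#' Lower-level constructor validating the invariants of a simulation
#' configuration; most users start from [default_profiles()] and modify
#' fields.
#'
#' @param n_couples Positive couple count before nonresponse.
#' @param delta Length-C class shares, summing to 1.
#' @param tau C x 12 matrix of positive-response probabilities, rows in
#'   class order.
#' @param covert_prob_by_class Length-C covert-use probabilities at
#'   covariate reference levels.
#' @param covert_logit_effects Named numeric vector of additive log-odds
#'   effects; names are `"variable=level"` for categorical indicators or a
#'   bare numeric variable name.
#' @param method_mix Named distribution over the four reversible female
#'   methods, summing to 1.
#' @param open_report_mix Shares of the husband's report routes among open
#'   users: `same` female method, `different` female method, `condom`.
#' @param covariate_specs Named list of category-probability vectors (see
#'   `default_profiles`).
#' @param eligibility_violation_rate Per-rule fraction of rows made to
#'   violate each cohort eligibility rule.
#' @param n_clusters Number of sampling clusters.
#' @param couple_response_rate_by_cluster Per-cluster couple response
#'   probability in (0, 1]; `NULL` for the default evenly spaced
#'   0.85-1.00 gradient.
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_couples, delta, tau, covert_prob_by_class,
                       covert_logit_effects = numeric(0),
                       method_mix, open_report_mix = c(same = 0.7,
                                                       different = 0.1,
                                                       condom = 0.2),
                       covariate_specs = default_covariate_specs(),
                       eligibility_violation_rate = 0.05,
                       n_clusters = 200L,
                       couple_response_rate_by_cluster = NULL,
                       seed = 1L) {
  if (length(n_couples) != 1 || n_couples < 1) {
    abort("`n_couples` must be a positive count.")
  }
  delta <- delta / sum(delta)
  if (abs(sum(delta) - 1) > 1e-12) abort("`delta` must sum to 1.")
  if (!is.matrix(tau) || nrow(tau) != length(delta) ||
      ncol(tau) != length(ATTITUDE_ITEMS)) {
    abort("`tau` must be a C x 12 matrix with C = length(delta).")
  }
  if (any(tau < 0 | tau > 1)) abort("`tau` entries must lie in [0, 1].")
  if (any(covert_prob_by_class < 0 | covert_prob_by_class > 1)) {
    abort("`covert_prob_by_class` entries must lie in [0, 1].")
  }
  if (abs(sum(method_mix) - 1) > 1e-8) abort("`method_mix` must sum to 1.")
  if (!all(names(method_mix) %in% METHODS_REVERSIBLE)) {
    abort("`method_mix` names must be the reversible female methods.")
  }
  if (is.null(couple_response_rate_by_cluster)) {
    couple_response_rate_by_cluster <-
      seq(0.85, 1.00, length.out = n_clusters)
  }
  if (any(couple_response_rate_by_cluster <= 0 |
          couple_response_rate_by_cluster > 1)) {
    abort("`couple_response_rate_by_cluster` must lie in (0, 1].")
  }
  structure(list(
    n_couples = as.integer(n_couples), delta = delta, tau = tau,
    covert_prob_by_class = covert_prob_by_class,
    covert_logit_effects = covert_logit_effects,
    method_mix = method_mix, open_report_mix = open_report_mix / sum(open_report_mix),
    covariate_specs = covariate_specs,
    eligibility_violation_rate = eligibility_violation_rate,
    n_clusters = as.integer(n_clusters),
    couple_response_rate_by_cluster = couple_response_rate_by_cluster,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate couple-level survey microdata
#'
#' Draws matched wife-husband couples under the latent-class attitude model:
#' each couple is assigned a latent class from `delta`, attitude items are
#' Bernoulli draws from the class's `tau` row, and the wife's covert-use
#' indicator follows a logistic model whose per-class intercept reproduces
#' `covert_prob_by_class` at covariate reference levels. The husband's
#' last-sex report is constructed consistently with the covert status: a
#' covert user's husband reports no method and no condom; an open user's
#' husband reports the same female method, a different one, or condom use
#' according to `open_report_mix`. A small configurable fraction of rows is
#' made to violate each cohort eligibility rule, and couples respond
#' cluster-wise with the configured response rates (nonresponding couples
#' are absent from the output but counted in the attached cluster design).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per interviewed couple, columns following
#'   the documented couple-file schema plus `true_class`, and a
#'   `cluster_design` attribute (tibble of per-cluster eligible and
#'   interviewed couple counts) consumed by [compute_couple_weights()].
#' @export
#' @examples
#' couples <- generate_couples(default_profiles(n_couples = 300, seed = 7))
#' table(couples$true_class)
generate_couples <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_couples
  m <- ncol(config$tau)
  C <- length(config$delta)
  cs <- config$covariate_specs
  set.seed(stage_seed(config$seed, "simulate"))

  cluster_id <- sample.int(config$n_clusters, n, replace = TRUE)
  stratum_id <- ((cluster_id - 1L) %% 4L) + 1L
  cluster_w <- rlnorm(config$n_clusters, 0, 0.25)
  hh_weight <- cluster_w[cluster_id]
  wife_weight <- hh_weight * rlnorm(n, 0, 0.1)
  husband_weight <- hh_weight * rlnorm(n, 0, 0.1)

  true_class <- sample.int(C, n, replace = TRUE, prob = config$delta)
  items <- matrix(runif(n * m) < config$tau[true_class, , drop = FALSE],
                  nrow = n)
  storage.mode(items) <- "integer"
  colnames(items) <- ATTITUDE_ITEMS

  religion <- sample_cat(n, cs$religion)
  caste <- sample_cat(n, cs$caste)
  residence <- sample_cat(n, cs$residence)
  wife_education <- sample_cat(n, cs$wife_education)
  husband_education <- sample_cat(n, cs$husband_education)
  working <- sample_cat(n, cs$working)
  wealth_quintile <- as.integer(sample_cat(n, cs$wealth_quintile))
  living_children <- as.integer(sample_cat(n, cs$living_children))
  region <- sample_cat(n, cs$region)
  mobility_market <- as.integer(sample_cat(n, cs$mobility_market) == "yes")
  mobility_health <- as.integer(sample_cat(n, cs$mobility_health) == "yes")
  money_own <- as.integer(sample_cat(n, cs$money_own) == "yes")
  wife_wants_more <- as.integer(sample_cat(n, cs$wife_wants_more) == "yes")
  concordant <- runif(n) < cs$concordance_rate
  husband_wants_more <- ifelse(concordant, wife_wants_more,
                               1L - wife_wants_more)

  wife_age <- pmin(pmax(round(rnorm(n, cs$wife_age_mean, cs$wife_age_sd)),
                        15L), 49L)
  gap_cat <- sample_cat(n, cs$age_gap)
  gap <- integer(n)
  gap[gap_cat == "same_or_wife_older"] <-
    sample(-3:0, sum(gap_cat == "same_or_wife_older"), replace = TRUE)
  gap[gap_cat == "1-3"] <- sample(1:3, sum(gap_cat == "1-3"), replace = TRUE)
  gap[gap_cat == "4-5"] <- sample(4:5, sum(gap_cat == "4-5"), replace = TRUE)
  gap[gap_cat == "6+"] <- sample(6:10, sum(gap_cat == "6+"), replace = TRUE)
  husband_age <- pmin(pmax(wife_age + gap, 15L), 54L)

  covars <- tibble::tibble(religion, caste, residence, wife_education,
                           husband_education, working, wealth_quintile,
                           living_children, region, mobility_market,
                           mobility_health, money_own, wife_wants_more,
                           husband_wants_more, wife_age, husband_age)
  lp <- qlogis(config$covert_prob_by_class)[true_class]
  lp <- lp + covert_effect_term(config$covert_logit_effects, covars)
  covert <- runif(n) < plogis(lp)

  wife_method <- sample_cat(n, config$method_mix)
  husband_report <- rep("none", n)
  husband_condom <- integer(n)
  open_idx <- which(!covert)
  route <- sample_cat(length(open_idx), config$open_report_mix)
  same_i <- open_idx[route == "same"]
  diff_i <- open_idx[route == "different"]
  cond_i <- open_idx[route == "condom"]
  husband_report[same_i] <- wife_method[same_i]
  husband_report[diff_i] <- vapply(wife_method[diff_i], function(wm) {
    sample(setdiff(METHODS_REVERSIBLE, wm), 1L)
  }, character(1))
  husband_condom[cond_i] <- 1L

  viol <- matrix(runif(n * length(ELIGIBILITY_FLAGS)) <
                   config$eligibility_violation_rate, nrow = n)
  colnames(viol) <- ELIGIBILITY_FLAGS
  ## method-based violations overwrite the wife's reported method
  wife_method[viol[, "sterilized_flag"]] <- "female_sterilization"
  wife_method[viol[, "traditional_method_flag"]] <- "traditional"
  wife_method[viol[, "nonuser_flag"]] <- "none"

  tab <- tibble::tibble(
    couple_id = seq_len(n), cluster_id = cluster_id, stratum_id = stratum_id,
    hh_weight = hh_weight, wife_weight = wife_weight,
    husband_weight = husband_weight,
    wife_method = wife_method,
    husband_reports_nonbarrier_method = husband_report,
    husband_condom_last_sex = husband_condom
  )
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(items))
  tab <- dplyr::bind_cols(
    tab,
    covars[, c("wife_age", "husband_age", "wife_education",
               "husband_education", "religion", "caste", "residence",
               "working", "wealth_quintile", "living_children", "region",
               "mobility_market", "mobility_health", "money_own",
               "wife_wants_more", "husband_wants_more")],
    tibble::as_tibble(viol * 1L)
  )
  tab$true_class <- ATTITUDE_CLASS_LEVELS[true_class]
  tab <- tab[, c(COUPLE_SCHEMA, "true_class")]

  rate <- config$couple_response_rate_by_cluster
  keep <- runif(n) < rate[cluster_id]
  n_elig_by_cluster <- tabulate(cluster_id, nbins = config$n_clusters)
  n_int_by_cluster <- tabulate(cluster_id[keep], nbins = config$n_clusters)
  design <- tibble::tibble(
    cluster_id = seq_len(config$n_clusters),
    n_eligible = n_elig_by_cluster,
    n_interviewed = n_int_by_cluster
  )
  out <- tab[keep, , drop = FALSE]
  attr(out, "cluster_design") <- design
  out
}

## Additive log-odds contribution of configured covariate effects.
## Effect names: "var=level" adds the coefficient for rows with var == level;
## a bare name multiplies the (numeric) covariate.
covert_effect_term <- function(effects, covars) {
  lp <- numeric(nrow(covars))
  if (length(effects) == 0) return(lp)
  for (nm in names(effects)) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(covars)) {
        abort(paste0("Unknown covariate in effect name: ", parts[1]))
      }
      lp <- lp + effects[[nm]] * (covars[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(covars)) {
        abort(paste0("Unknown covariate in effect name: ", nm))
      }
      lp <- lp + effects[[nm]] * covars[[nm]]
    }
  }
  lp
}

#' Write a couple table to a delimited file
#'
#' Writes the documented comma-delimited couple-file schema (one header
#' row); the file round-trips losslessly through [read_couple_table()]. The
#' per-cluster design counts, if attached, are written alongside when
#' `design_path` is given.
#'
#' @param table A couple table (tibble) following the schema.
#' @param path Output CSV path.
#' @param design_path Optional CSV path for the cluster design counts.
#' @return `path`, invisibly.
#' @export
write_couple_table <- function(table, path, design_path = NULL) {
  cols <- intersect(c(COUPLE_SCHEMA, "true_class"), names(table))
  missing <- setdiff(COUPLE_SCHEMA, names(table))
  if (length(missing) > 0) {
    abort(paste0("Couple table is missing schema columns: ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(table[, cols], path)
  design <- attr(table, "cluster_design")
  if (!is.null(design_path)) {
    if (is.null(design)) abort("No cluster design attached to write.")
    readr::write_csv(design, design_path)
  }
  invisible(path)
}
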