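#' Set analysis factor levels
#'
#' Converts the categorical analysis variables to factors with the
#' reference level first (high-egalitarian attitude, Hindu, SC/ST, urban,
#' non-literate wife, non-working, North region), so that model
#' coefficients are log odds ratios against those references.
#'
#' @param table Analytic couple table.
#' @return The table with factor columns releveled.
#' @export
set_analysis_factors <- function(table) {
  if ("attitude_class" %in% names(table)) {
    table$attitude_class <- factor(table$attitude_class,
                                   levels = ATTITUDE_CLASS_LEVELS)
  }
  table$religion <- factor(table$religion, levels = RELIGION_LEVELS)
  table$caste <- factor(table$caste, levels = CASTE_LEVELS)
  table$residence <- factor(table$residence, levels = RESIDENCE_LEVELS)
  table$wife_education <- factor(table$wife_education,
                                 levels = EDUCATION_LEVELS)
  table$working <- factor(table$working, levels = c("no", "yes"))
  table$region <- factor(table$region, levels = REGION_LEVELS)
  table
}

#' Run configuration for the full pipeline
#'
#' @param sim Simulation configuration ([sim_config()]) used when no input
#'   file is given.
#' @param input Optional path to an existing couple CSV (with optional
#'   `design_path` for cluster counts).
#' @param design_path Optional cluster-design CSV accompanying `input`.
#' @param class_candidates Candidate class counts for model selection;
#'   a single value fixes C without selection.
#' @param n_restarts,max_iter,tol EM settings.
#' @param weighted_lca Use couple weights in the latent class likelihood.
#' @param weighted_models Use couple weights in the cross-tabulations and
#'   regressions.
#' @param use_true_class Regress on the simulator's true latent class
#'   instead of the modal LCA assignment (validation runs only).
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param out_dir Optional directory for report artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = default_profiles(), input = NULL,
                       design_path = NULL, class_candidates = 2:4,
                       n_restarts = 20L, max_iter = 300L, tol = 1e-7,
                       weighted_lca = FALSE, weighted_models = TRUE,
                       use_true_class = FALSE,
                       seed = 1L, out_dir = NULL) {
  structure(list(
    sim = sim, input = input, design_path = design_path,
    class_candidates = class_candidates, n_restarts = n_restarts,
    max_iter = max_iter, tol = tol, weighted_lca = weighted_lca,
    weighted_models = weighted_models, use_true_class = use_true_class,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full covert-use pipeline
#'
#' Orchestrates simulate (or read) -> eligibility filters -> couple
#' weights -> covariate recoding -> covert-outcome derivation -> latent
#' class measurement of the husband's attitude (selection over the
#' candidate class counts, labeling, modal assignment) -> bivariate
#' cross-tabulations -> model 1 and model 2 weighted logistic regressions
#' -> VIF diagnostics -> method-mix summary -> report tables. Identical
#' configuration and seed give identical artifacts.
#'
#' @param config A [run_config()].
#' @return A list with `cohort` (the analytic table including
#'   `couple_weight`, recodes, `covert`, `attitude_class`), `selection`
#'   (class-count selection table), `lca` (labeled fit), `assignment`,
#'   `crosstabs`, `models` (list of `logit_result`), `vif`, `mix`,
#'   `report`, `drop_report`, and `manifest` (settings and stage seeds).
#'   Report CSVs and a JSON manifest are written when `out_dir` is set.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(sim = default_profiles(500, seed = 1),
#'                                class_candidates = 3, n_restarts = 3))
#' res$mix$prevalence
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(config$input)) {
      config$sim$seed <- stage_seed(config$seed, "sim")
      raw <- generate_couples(config$sim)
    } else {
      raw <- read_couple_table(config$input, config$design_path)
    }

    stage <- "cohort"
    elig <- select_eligible_couples(raw)
    if (nrow(elig) == 0) abort("No eligible couples after filtering.")
    elig <- compute_couple_weights(elig)
    elig <- recode_covariates(elig)

    stage <- "covert"
    elig <- add_covert_status(elig)

    stage <- "lca"
    Y <- as.matrix(elig[, ATTITUDE_ITEMS])
    lca_w <- if (config$weighted_lca) elig$couple_weight else NULL
    sel <- select_num_classes(
      Y, candidates = config$class_candidates,
      max_iter = config$max_iter, tol = config$tol,
      n_restarts = config$n_restarts,
      seed = stage_seed(config$seed, "lca"), weights = lca_w)
    fit <- label_classes(sel$fits[[as.character(sel$chosen_C)]])
    assign <- posterior_assign(fit, Y)
    elig$attitude_class <- assign$modal
    if (config$use_true_class && "true_class" %in% names(elig)) {
      elig$attitude_class <- factor(elig$true_class,
                                    levels = ATTITUDE_CLASS_LEVELS)
    }
    elig <- set_analysis_factors(elig)

    stage <- "fit"
    w <- if (config$weighted_models) elig$couple_weight
         else rep(1, nrow(elig))
    factors <- c("attitude_class", "concordance", "religion", "caste",
                 "residence", "wife_education", "age_diff_cat",
                 "edu_diff_cat", "working", "wealth_group",
                 "living_children_cat", "region")
    crosstabs <- lapply(factors, function(f) {
      weighted_crosstab(elig[[f]], elig$covert, w, factor_name = f)
    })
    names(crosstabs) <- factors
    m1 <- fit_weighted_logit(elig, model_formula(1), weights = w,
                             model_id = 1)
    m2 <- fit_weighted_logit(elig, model_formula(2), weights = w,
                             model_id = 2)
    X2 <- model.matrix(model_formula(2), elig)
    vif <- vif_report(X2)
    mix <- method_mix(elig$wife_method, elig$covert, w)

    stage <- "report"
    report <- results_report(crosstabs, list(m1, m2), vif, mix,
                             out_dir = config$out_dir)

    manifest <- list(
      package_version = as.character(utils::packageVersion("covertuse")),
      seed = config$seed,
      stage_seeds = list(sim = stage_seed(config$seed, "sim"),
                         lca = stage_seed(config$seed, "lca")),
      n_input = nrow(raw), n_eligible = nrow(elig),
      chosen_C = sel$chosen_C,
      weighted_lca = config$weighted_lca,
      weighted_models = config$weighted_models,
      settings = list(class_candidates = config$class_candidates,
                      n_restarts = config$n_restarts,
                      max_iter = config$max_iter, tol = config$tol)
    )
    if (!is.null(config$out_dir)) {
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }

    list(cohort = elig, selection = sel$table, lca = fit,
         assignment = assign, crosstabs = crosstabs,
         models = list(model1 = m1, model2 = m2), vif = vif, mix = mix,
         report = report,
         drop_report = attr(elig, "drop_report"), manifest = manifest)
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  res
}
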