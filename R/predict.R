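#' Posterior predicted choice probabilities
#'
#' Evaluates the fitted model variant's predicted probability of a correct
#' choice for each row of `newdata`, draw by draw, and summarises across
#' draws by the posterior mean and a 95% highest density interval. Rows are
#' mapped like trial rows: `condition = "none"` with an object is a
#' mutual-exclusivity scene (uniform prior), rows without an object are
#' discourse-novelty scenes (the prediction is the common-ground trajectory
#' itself), and congruent/incongruent rows use the variant's full mapping.
#'
#' @param fit A [fit_model()] result.
#' @param newdata Data frame with columns `age`, `condition`, `object_id`
#'   (defaults to the full combined-design grid from [prediction_grid()]).
#' @param model Variant used to map draws to predictions; defaults to the
#'   fitted variant. A prediction-stage fit can be mapped through any
#'   non-biased variant, which is how one stage-1 posterior yields the four
#'   competing sets of a-priori predictions.
#' @param mass Probability mass of the reported HDI.
#' @return `newdata` as a tibble with `.pred`, `.lower`, `.upper` appended.
#' @export
posterior_predict <- function(fit, newdata = prediction_grid(fit$objects),
                              model = fit$model, mass = 0.95) {
  pp <- predictive_draws(fit, newdata, model)
  out <- tibble::as_tibble(newdata)
  out$.pred <- rowMeans(pp)
  lim <- t(apply(pp, 1, hdi_interval, mass = mass))
  out$.lower <- lim[, 1]
  out$.upper <- lim[, 2]
  out
}

# rows of newdata x posterior draws matrix of choice probabilities
predictive_draws <- function(fit, newdata, model = fit$model) {
  model <- match.arg(model, MODEL_NAMES)
  if (model %in% c("biased", "developmental_bias") &&
      !any(fit$active[c("phi_intercept", "phi_slope")])) {
    abort_config("this fit carries no bias coefficients; refit with the biased variant")
  }
  newdata <- tibble::as_tibble(newdata)
  if (!all(c("age", "condition", "object_id") %in% names(newdata))) {
    abort_config("`newdata` needs columns age, condition, object_id")
  }
  if (nrow(fit$draws) == 0) abort_config("posterior is empty")
  obj <- match(newdata$object_id, fit$objects$object_id)
  expid <- dplyr::case_when(
    newdata$condition %in% c("congruent", "incongruent") ~ 3L,
    !is.na(newdata$object_id) ~ 1L,
    TRUE ~ 2L
  )
  pp <- cpp_prob_matrix(
    draw_matrix(fit),
    integer(nrow(newdata)),
    as.double(newdata$age),
    expid,
    match(newdata$condition, c("congruent", "incongruent"), nomatch = 0L),
    ifelse(is.na(obj), -1L, obj - 1L),
    model_code(model), fit$age_center,
    as.integer(fit$alpha_link == "log")
  )
  pp
}

#' Combined-design prediction grid
#'
#' The cells over which out-of-sample predictions are evaluated: every
#' familiar object crossed with both alignment conditions and an age grid
#' (default: age-year bin midpoints 2.5, 3.5, 4.5).
#'
#' @param objects Familiar-object roster.
#' @param ages Ages (years) at which to evaluate.
#' @return A tibble with columns `age`, `condition`, `object_id`.
#' @export
#' @examples
#' nrow(prediction_grid())  # 12 objects x 2 conditions x 3 ages = 72 cells
prediction_grid <- function(objects = default_objects(),
                            ages = c(2.5, 3.5, 4.5)) {
  tidyr::expand_grid(age = ages,
                     condition = c("congruent", "incongruent"),
                     object_id = objects$object_id)
}
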