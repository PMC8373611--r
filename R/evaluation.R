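#' Bin responses by age year, condition and object
#'
#' Groups trials into cells by whole age year (half-open bins: age 3.0
#' falls in bin 3), condition and familiar object, and reports the observed
#' proportion of correct choices per cell. Every trial lands in exactly one
#' cell; cells simply never materialise when no trial falls in them.
#'
#' @param trials Trial tibble.
#' @return A tibble with columns `age_bin`, `condition`, `object_id`,
#'   `n_trials`, `observed_rate`.
#' @export
#' @examples
#' trials <- simulate_experiment(experiment_design("exp3", 10),
#'                               default_truth(), seed = 1)
#' bin_responses(trials)
bin_responses <- function(trials) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) abort_config("cannot bin an empty trial table")
  trials |>
    dplyr::mutate(age_bin = floor(.data$age)) |>
    dplyr::group_by(.data$age_bin, .data$condition, .data$object_id) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     observed_rate = mean(.data$correct), .groups = "drop")
}

#' Bin posterior predictions to the same cells as the data
#'
#' For each (age-year, condition, object) cell occupied by `trials`, the
#' per-draw predicted cell rate is the mean of the model's predicted choice
#' probabilities over the cell's trials (each evaluated at the trial's
#' actual age); the cell summary is the posterior mean and 95% HDI of that
#' per-draw rate.
#'
#' @param fit A [fit_model()] result.
#' @param trials Trial tibble defining the cells (typically the exp3 data).
#' @param model Variant used for prediction; defaults to the fitted one.
#' @param mass HDI mass.
#' @return A tibble with columns `age_bin`, `condition`, `object_id`,
#'   `predicted_mean`, `predicted_hdi_low`, `predicted_hdi_high`.
#' @export
bin_predictions <- function(fit, trials, model = fit$model, mass = 0.95) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) abort_config("cannot bin an empty trial table")
  pp <- predictive_draws(fit, trials[, c("age", "condition", "object_id")],
                         model)
  cells <- dplyr::mutate(trials, age_bin = floor(.data$age)) |>
    dplyr::group_by(.data$age_bin, .data$condition, .data$object_id)
  idx <- dplyr::group_rows(cells)
  keys <- dplyr::group_keys(cells)
  summ <- purrr::map_dfr(idx, function(rows) {
    cell_draws <- colMeans(pp[rows, , drop = FALSE])
    h <- hdi_interval(cell_draws, mass)
    tibble::tibble(predicted_mean = mean(cell_draws),
                   predicted_hdi_low = h[1], predicted_hdi_high = h[2])
  })
  dplyr::bind_cols(keys, summ)
}

#' Pearson correlation between predictions and observations
#'
#' Product-moment correlation and the proportion of variance explained
#' (`r^2`) between two equal-length vectors, e.g. binned predicted and
#' observed correct rates.
#'
#' @param predicted,observed Numeric vectors of equal length (at least 3),
#'   neither constant.
#' @return A tibble with columns `r` and `r_squared`.
#' @export
#' @examples
#' pearson_r(c(0.2, 0.5, 0.9), c(0.1, 0.6, 0.8))
pearson_r <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    abort_domain("`predicted` and `observed` must have equal length >= 3")
  }
  if (sd(predicted) == 0 || sd(observed) == 0) {
    abort_domain("correlation is undefined for a constant vector")
  }
  r <- stats::cor(predicted, observed)
  tibble::tibble(r = r, r_squared = r^2)
}

#' Highest density interval
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed from sorted samples. For clearly bimodal inputs the contiguous
#' interval is still reported, with a warning.
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass in `(0, 1]`.
#' @return A tibble with columns `lower` and `upper`.
#' @export
#' @examples
#' hdi(rnorm(1000))
hdi <- function(samples, mass = 0.95) {
  h <- hdi_interval(samples, mass, check = TRUE)
  tibble::tibble(lower = h[1], upper = h[2])
}

# bare numeric version used internally
hdi_interval <- function(samples, mass = 0.95, check = FALSE) {
  if (check && length(samples) < 100) {
    abort_domain("hdi() needs at least 100 samples")
  }
  if (mass <= 0 || mass > 1) abort_domain("`mass` must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  k <- min(n, ceiling(mass * n))
  if (k == n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  if (check && is_bimodal(x)) {
    warn("samples look multimodal; the contiguous HDI may be misleading",
         class = "pragword_hdi_warning")
  }
  c(x[i], x[i + k])
}

# crude bimodality screen: a large interior gap relative to spread
is_bimodal <- function(x) {
  n <- length(x)
  gaps <- diff(x)
  interior <- gaps[seq(max(1, floor(0.1 * n)), min(n - 1, ceiling(0.9 * n)))]
  rng <- x[ceiling(0.95 * n)] - x[floor(0.05 * n) + 1]
  rng > 0 && max(interior) > 0.25 * rng
}

#' Model-versus-data comparison report
#'
#' Joins each model's binned predictions to the observed cell rates,
#' computes the Pearson correlation and variance explained over the shared
#' cells (cells weighted equally), and attaches marginal-likelihood
#' evidence and Bayes factors relative to the first model when supplied.
#'
#' @param observed Output of [bin_responses()].
#' @param predictions Named list of [bin_predictions()] outputs, one per
#'   model.
#' @param evidence Optional named list of `pw_evidence` objects matching
#'   `predictions`.
#' @param weighted If `TRUE`, weight cells by their trial counts instead of
#'   equally.
#' @return A tibble with one row per model: `r`, `r_squared`, and when
#'   evidence is given `log_ml`, `log10_bf` (relative to the first model).
#' @export
compare_report <- function(observed, predictions, evidence = NULL,
                           weighted = FALSE) {
  if (!is.list(predictions) || is.null(names(predictions)) ||
      any(names(predictions) == "")) {
    abort_config("`predictions` must be a named list of binned predictions")
  }
  keys <- c("age_bin", "condition", "object_id")
  rows <- purrr::imap_dfr(predictions, function(pred, nm) {
    joined <- dplyr::inner_join(observed, pred, by = keys)
    if (nrow(joined) != nrow(observed) || nrow(joined) != nrow(pred)) {
      abort_config(paste0("cell sets of the data and model '", nm,
                          "' do not align"))
    }
    if (weighted) {
      w <- joined$n_trials
      r <- stats::cov.wt(cbind(joined$predicted_mean, joined$observed_rate),
                         wt = w, cor = TRUE)$cor[1, 2]
      tibble::tibble(model = nm, n_cells = nrow(joined), r = r,
                     r_squared = r^2)
    } else {
      dplyr::bind_cols(
        tibble::tibble(model = nm, n_cells = nrow(joined)),
        pearson_r(joined$predicted_mean, joined$observed_rate)
      )
    }
  })
  if (!is.null(evidence)) {
    if (!setequal(names(evidence), names(predictions))) {
      abort_config("`evidence` names must match `predictions` names")
    }
    rows$log_ml <- unname(purrr::map_dbl(evidence[rows$model], "log_ml"))
    # Bayes factor of each model relative to the first row's model
    rows$log10_bf <- (rows$log_ml - rows$log_ml[1]) / log(10)
  }
  rows
}
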