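#' Fit a model variant to trial data
#'
#' Fully Bayesian estimation of the age-trajectory coefficients by adaptive
#' Metropolis-within-Gibbs sampling over the package's single compiled
#' likelihood kernel. Each trial contributes a Bernoulli likelihood for its
#' `correct` response with success probability given by the model variant at
#' the row's age, object and condition: mutual-exclusivity trials (exp1) use
#' the uniform-prior submodel, discourse-novelty trials (exp2) inform the
#' common-ground trajectory directly, and combined trials (exp3) use the
#' variant's full mapping.
#'
#' Two stages mirror the prediction-versus-explanation workflow:
#' `stage = "prediction"` uses only the exp1/exp2 rows (any exp3 rows are
#' dropped and never touch the likelihood), so the resulting posterior makes
#' parameter-free out-of-sample predictions for the combined design;
#' `stage = "explanation"` constrains the parameters with all rows. The bias
#' coefficients of the biased variants are only estimable at the
#' explanation stage.
#'
#' @param data Trial tibble (see [read_trials()] for the schema).
#' @param model One of [model_names()].
#' @param stage `"explanation"` (all experiments) or `"prediction"`
#'   (exp1 + exp2 only).
#' @param priors A [prior_spec()] object.
#' @param chains,warmup,iter,thin MCMC settings: `iter` retained draws per
#'   chain after `warmup` adaptation iterations, thinned by `thin`.
#' @param seed Integer seed (mandatory; the fit is reproducible given it).
#' @param objects Familiar-object roster.
#' @param sample_prior If `TRUE`, ignore the likelihood and sample the prior
#'   (data may then be empty).
#' @param age_center,alpha_link Shared trajectory configuration; see
#'   [trajectory_coefficients()].
#' @return An object of class `pw_fit` with posterior draws, sampler
#'   diagnostics (split-Rhat, effective sample size, acceptance rates) and
#'   the fit configuration. Supports [tidy()], [glance()],
#'   [posterior_predict()] and [ggplot2::autoplot()].
#' @export
fit_model <- function(data, model = "integration",
                      stage = c("explanation", "prediction"),
                      priors = prior_spec(),
                      chains = 2, warmup = 1000, iter = 1000, thin = 1,
                      seed, objects = default_objects(),
                      sample_prior = FALSE,
                      age_center = 3,
                      alpha_link = c("identity_clip", "log")) {
  model <- match.arg(model, MODEL_NAMES)
  stage <- match.arg(stage)
  alpha_link <- match.arg(alpha_link)
  if (missing(seed)) abort_config("`seed` is required for fitting")
  if (!inherits(priors, "pw_priors")) {
    abort_config("`priors` must come from prior_spec()")
  }

  if (sample_prior && (is.null(data) || nrow(data) == 0)) {
    data <- empty_trials()
  }
  data <- validate_trials(data)
  if (stage == "prediction") {
    if (model %in% c("biased", "developmental_bias")) {
      abort_config(paste0(
        "the biased variants have no prediction stage: their bias parameter ",
        "is not identified by exp1/exp2 data"))
    }
    data <- dplyr::filter(data, .data$experiment != "exp3")
  }
  if (nrow(data) == 0 && !sample_prior) {
    abort_config("cannot fit to an empty trial table")
  }

  td <- prepare_trial_data(data, objects)
  pv <- prior_vectors(priors, objects)
  nm <- par_layout(objects)

  active <- rep(1L, 34)
  active[33:34] <- 0L
  if (model == "biased") active[33] <- 1L
  if (model == "developmental_bias") active[33:34] <- 1L

  init_base <- pv$loc
  init_base[31:32] <- log(0.5)  # offset sds start at 0.5

  runs <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(chains), function(ch) {
      init <- init_base
      jitter_idx <- which(active == 1L & (seq_len(34) <= 6 | seq_len(34) >= 33))
      init[jitter_idx] <- init[jitter_idx] + rnorm(length(jitter_idx), 0, 0.1)
      cpp_fit_mh(td$y, td$age, as.integer(td$expid), as.integer(td$cond),
                 as.integer(td$obj), model_code(model), age_center,
                 as.integer(alpha_link == "log"),
                 unname(pv$loc), unname(pv$scale), pv$re_scale0, pv$re_scale1,
                 unname(init), active,
                 as.integer(warmup), as.integer(iter), as.integer(thin),
                 isTRUE(sample_prior))
    })
  })

  arr <- array(NA_real_, dim = c(iter, chains, 34),
               dimnames = list(NULL, NULL, nm))
  for (ch in seq_len(chains)) arr[, ch, ] <- runs[[ch]]$draws

  active_names <- nm[active == 1L]
  diag_tbl <- mcmc_diagnostics(arr[, , active_names, drop = FALSE],
                               active_names)
  converged <- max(diag_tbl$rhat, na.rm = TRUE) < 1.05 &&
    min(diag_tbl$ess, na.rm = TRUE) >= 100
  if (!converged) {
    warn(paste0("convergence diagnostics flagged: max Rhat = ",
                signif(max(diag_tbl$rhat, na.rm = TRUE), 3), ", min ESS = ",
                signif(min(diag_tbl$ess, na.rm = TRUE), 3)),
         class = "pragword_convergence_warning")
  }

  draws <- purrr::map_dfr(seq_len(chains), function(ch) {
    d <- tibble::as_tibble(as.data.frame(runs[[ch]]$draws))
    names(d) <- nm
    d$.chain <- ch
    d$.draw <- seq_len(nrow(d))
    d$.lp <- as.numeric(runs[[ch]]$lp)
    d
  })

  structure(
    list(
      draws = draws,
      model = model,
      stage = stage,
      priors = priors,
      objects = objects,
      settings = list(chains = chains, warmup = warmup, iter = iter,
                      thin = thin, seed = seed),
      diagnostics = list(table = diag_tbl, converged = converged,
                         accept = purrr::map(runs, "accept")),
      data_info = list(
        n_trials = nrow(data),
        n_by_experiment = table(data$experiment),
        n_exp3_used = sum(data$experiment == "exp3")
      ),
      active = setNames(active == 1L, nm),
      age_center = age_center,
      alpha_link = alpha_link,
      sample_prior = isTRUE(sample_prior)
    ),
    class = "pw_fit"
  )
}

#' @export
print.pw_fit <- function(x, ...) {
  cat("<pw_fit> model '", x$model, "' (", x$stage, " stage)\n", sep = "")
  cat("  ", x$data_info$n_trials, " trials; ", x$settings$chains, " chains x ",
      x$settings$iter, " draws (warmup ", x$settings$warmup, ")\n", sep = "")
  cat(sprintf("  max Rhat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$table$rhat, na.rm = TRUE),
              min(x$diagnostics$table$ess, na.rm = TRUE),
              if (x$diagnostics$converged) "" else "  [flagged]"))
  invisible(x)
}

# posterior draw matrix (all kept draws x 34), in the kernel's non-centred
# layout (object offsets standardized)
draw_matrix <- function(fit) {
  as.matrix(fit$draws[, par_layout(fit$objects)])
}

# draws with object offsets rescaled to the natural (logit) scale
natural_draws <- function(fit) {
  d <- fit$draws
  s0 <- exp(d$log_sd_obj_intercept)
  s1 <- exp(d$log_sd_obj_slope)
  for (nm in names(d)) {
    if (startsWith(nm, "theta_obj_intercept")) d[[nm]] <- d[[nm]] * s0
    if (startsWith(nm, "theta_obj_slope")) d[[nm]] <- d[[nm]] * s1
  }
  d
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `pw_fit` object.
#' @param conf_level Mass of the equal-tailed credible interval.
#' @param all_terms Include parameters that were held fixed (inactive) in
#'   this fit.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, sd, credible
#'   interval bounds and sampler diagnostics.
#' @export
tidy.pw_fit <- function(x, conf_level = 0.95, all_terms = FALSE, ...) {
  nms <- names(x$active)[x$active | all_terms]
  a <- (1 - conf_level) / 2
  nd <- natural_draws(x)
  out <- purrr::map_dfr(nms, function(nm) {
    v <- nd[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
  dplyr::left_join(out, x$diagnostics$table, by = "term")
}

#' One-row summary of a fitted model
#'
#' @param x A `pw_fit` object.
#' @param ... Unused.
#' @return A tibble with the model name, stage, data size, number of
#'   retained draws and worst-case convergence diagnostics.
#' @export
glance.pw_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, stage = x$stage,
    nobs = x$data_info$n_trials,
    n_draws = nrow(x$draws),
    chains = x$settings$chains,
    max_rhat = max(x$diagnostics$table$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$table$ess, na.rm = TRUE),
    converged = x$diagnostics$converged
  )
}

# an empty but schema-complete trial table (prior-sampling mode)
empty_trials <- function() {
  tibble::tibble(child_id = character(), age = numeric(),
                 experiment = character(), condition = character(),
                 object_id = character(), correct = integer())
}
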