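#' Monte-Carlo marginal likelihood of arbitrary models
#'
#' Simple Monte-Carlo estimate of a marginal likelihood: draws parameters
#' from `sampler`, evaluates `loglik` on each draw and averages the
#' likelihood in log space (log-sum-exp). The standard error is the delta-
#' method error of the log of the Monte-Carlo mean.
#'
#' @param loglik Function taking one parameter draw and returning the data
#'   log-likelihood.
#' @param sampler Function taking a count `n` and returning a list of `n`
#'   parameter draws.
#' @param n_samples Number of Monte-Carlo draws (at least 1000).
#' @param seed Integer seed.
#' @return A `pw_evidence` object with `log_ml`, `se` and `n_samples`.
#' @export
#' @examples
#' # Beta-Bernoulli: uniform prior on p, one success in two trials -> 1/6
#' ev <- evidence_mc(function(p) log(p) + log(1 - p),
#'                   function(n) as.list(runif(n)),
#'                   n_samples = 5000, seed = 1)
#' exp(ev$log_ml)
evidence_mc <- function(loglik, sampler, n_samples = 10000, seed) {
  if (n_samples < 1000) abort_config("`n_samples` must be at least 1000")
  if (missing(seed)) abort_config("`seed` is required")
  withr::with_seed(as.integer(seed), {
    draws <- sampler(n_samples)
    ll <- vapply(draws, loglik, numeric(1))
    new_evidence(ll, model = NA_character_)
  })
}

# evidence object from a vector of per-draw data log-likelihoods
new_evidence <- function(ll, model) {
  n <- length(ll)
  if (all(!is.finite(ll))) {
    warn("all sampled likelihoods are zero; marginal likelihood is -Inf",
         class = "pragword_evidence_warning")
    return(structure(list(log_ml = -Inf, se = Inf, n_samples = n,
                          model = model), class = "pw_evidence"))
  }
  m <- max(ll)
  w <- exp(ll - m)
  log_ml <- m + log(mean(w))
  se <- sd(w) / (mean(w) * sqrt(n))
  structure(list(log_ml = log_ml, se = se, n_samples = n, model = model),
            class = "pw_evidence")
}

#' @export
print.pw_evidence <- function(x, ...) {
  cat(sprintf("<pw_evidence>%s log ML = %.3f (SE %.3g, %d draws)\n",
              if (is.na(x$model)) "" else paste0(" model '", x$model, "'"),
              x$log_ml, x$se, x$n_samples))
  invisible(x)
}

#' Marginal likelihood of trial data under a model variant
#'
#' The probability of the data averaged over a distribution on the
#' trajectory coefficients, estimated by naive Monte Carlo in log space.
#' Two sampling distributions correspond to the two workflow stages: for
#' prediction models pass a stage-1 (`exp1`/`exp2`) posterior fit as
#' `sampler` and exp3 rows as `data`, giving the evidence of the new data
#' under the model's a-priori predictions; for explanation models pass a
#' [prior_spec()] and all rows.
#'
#' @param data Trial tibble whose likelihood is evaluated.
#' @param model One of [model_names()].
#' @param sampler Either a `pw_fit` (draws reused as the parameter
#'   distribution) or a `pw_priors` object (draws sampled fresh).
#' @param n_samples Monte-Carlo draws (prior sampler) or maximum number of
#'   posterior draws used.
#' @param seed Integer seed.
#' @param objects,age_center,alpha_link Configuration, as in [fit_model()];
#'   taken from the fit when `sampler` is a `pw_fit`.
#' @return A `pw_evidence` object.
#' @export
marginal_likelihood <- function(data, model, sampler, n_samples = 10000,
                                seed, objects = default_objects(),
                                age_center = 3,
                                alpha_link = c("identity_clip", "log")) {
  model <- match.arg(model, MODEL_NAMES)
  if (missing(seed)) abort_config("`seed` is required")
  if (n_samples < 1000) abort_config("`n_samples` must be at least 1000")
  biased <- model %in% c("biased", "developmental_bias")

  if (inherits(sampler, "pw_fit")) {
    if (biased && !any(sampler$active[c("phi_intercept", "phi_slope")])) {
      abort_config(paste0(
        "the supplied posterior carries no bias coefficients; biased-variant ",
        "evidence needs a prior sampler or a biased-variant fit"))
    }
    objects <- sampler$objects
    age_center <- sampler$age_center
    alpha_link <- sampler$alpha_link
    draws <- draw_matrix(sampler)
    if (nrow(draws) > n_samples) {
      keep <- withr::with_seed(as.integer(seed),
                               sample.int(nrow(draws), n_samples))
      draws <- draws[keep, , drop = FALSE]
    }
  } else if (inherits(sampler, "pw_priors")) {
    alpha_link <- match.arg(alpha_link)
    active_phi <- c(biased, model == "developmental_bias")
    draws <- withr::with_seed(as.integer(seed),
                              sample_prior_draws(sampler, n_samples, objects,
                                                 active_phi))
  } else {
    abort_config("`sampler` must be a pw_fit or a pw_priors object")
  }

  td <- prepare_trial_data(data, objects)
  if (td$n == 0) abort_config("cannot compute evidence for an empty trial table")
  ll <- cpp_loglik_matrix(draws, td$y, td$age, as.integer(td$expid),
                          as.integer(td$cond), as.integer(td$obj),
                          model_code(model), age_center,
                          as.integer(alpha_link == "log"))
  new_evidence(as.numeric(ll), model = model)
}

#' Bayes factor between two evidence estimates
#'
#' @param evidence_a,evidence_b `pw_evidence` objects (numerator /
#'   denominator).
#' @return A tibble with the models, the Bayes factor, its log10, and the
#'   difference in log marginal likelihood.
#' @export
#' @examples
#' a <- pragword:::new_evidence(log(0.2), NA)
#' b <- pragword:::new_evidence(log(0.02), NA)
#' bayes_factor(a, b)$bf  # 10
bayes_factor <- function(evidence_a, evidence_b) {
  if (!inherits(evidence_a, "pw_evidence") ||
      !inherits(evidence_b, "pw_evidence")) {
    abort_config("bayes_factor() takes two pw_evidence objects")
  }
  d <- evidence_a$log_ml - evidence_b$log_ml
  if (!is.finite(d)) {
    warn("infinite log marginal likelihood; Bayes factor is degenerate",
         class = "pragword_evidence_warning")
    d <- ifelse(is.nan(d), NA_real_, d)
  }
  tibble::tibble(
    model_a = evidence_a$model, model_b = evidence_b$model,
    log_ml_a = evidence_a$log_ml, log_ml_b = evidence_b$log_ml,
    bf = exp(d), log10_bf = d / log(10)
  )
}
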