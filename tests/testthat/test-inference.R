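test_that("the compiled likelihood matches the enumeration oracle", {
  set.seed(19)
  trials <- simulate_study(3, default_truth(), seed = 55)
  td <- pragword:::prepare_trial_data(trials)
  for (m in model_names()) {
    co <- trajectory_coefficients(
      alpha = c(runif(1, 0, 2), runif(1, -0.5, 1)),
      rho = rnorm(2, 0, 1), theta = rnorm(2, 0, 1),
      theta_obj = tibble::tibble(object_id = default_objects()$object_id,
                                 intercept = rnorm(12), slope = rnorm(12, 0, 0.3)),
      phi = rnorm(2, 0, 1)
    )
    got <- pragword:::trial_loglik(pragword:::coeffs_to_par(co), td, m)
    want <- oracle_loglik(trials, co, m)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("fitting guards its preconditions", {
  expect_error(fit_model(pragword:::empty_trials(), seed = 1),
               class = "pragword_config_error")
  tr <- simulate_study(2, default_truth(), seed = 9)
  expect_error(fit_model(tr), class = "pragword_config_error")  # no seed
  expect_error(fit_model(tr, "biased", stage = "prediction", seed = 1),
               class = "pragword_config_error")
  expect_error(fit_model(tr, seed = 1, priors = list()),
               class = "pragword_config_error")
})

test_that("prediction-stage fits never touch combined-design rows", {
  tr <- simulate_study(6, default_truth(), seed = 14)
  with3 <- suppressWarnings(
    fit_model(tr, stage = "prediction", chains = 1, warmup = 150, iter = 100,
              seed = 5))
  without3 <- suppressWarnings(
    fit_model(dplyr::filter(tr, experiment != "exp3"), stage = "prediction",
              chains = 1, warmup = 150, iter = 100, seed = 5))
  expect_equal(with3$data_info$n_exp3_used, 0)
  expect_identical(with3$draws, without3$draws)
})

test_that("with no data the sampler reproduces the prior", {
  pr <- prior_spec()
  f <- suppressWarnings(
    fit_model(NULL, "integration", priors = pr, chains = 2, warmup = 1000,
              iter = 2000, seed = 77, sample_prior = TRUE))
  d <- f$draws
  # posterior = prior within Monte-Carlo error
  expect_equal(mean(d$alpha_intercept), pr$alpha$loc[1], tolerance = 0.15)
  expect_equal(sd(d$alpha_intercept), pr$alpha$scale[1], tolerance = 0.15)
  expect_equal(mean(d$theta_slope), 0, tolerance = 0.3)
  expect_equal(sd(d$theta_slope), 2.5, tolerance = 0.3)
  expect_equal(mean(d$`theta_obj_intercept[obj01]`), 0, tolerance = 0.15)
})

test_that("fits are reproducible given the seed and expose diagnostics", {
  tr <- simulate_study(4, default_truth(), seed = 23)
  f1 <- suppressWarnings(fit_model(tr, chains = 2, warmup = 200, iter = 150,
                                   seed = 30))
  f2 <- suppressWarnings(fit_model(tr, chains = 2, warmup = 200, iter = 150,
                                   seed = 30))
  expect_identical(f1$draws, f2$draws)
  g <- glance(f1)
  expect_equal(g$n_draws, 300)
  expect_true(is.finite(g$max_rhat) && is.finite(g$min_ess))
  td <- tidy(f1)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "rhat", "ess") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("Monte-Carlo evidence matches closed-form oracles", {
  # no parameters to average: fixed p = 0.5 on three trials
  ev0 <- evidence_mc(function(p) 3 * log(0.5),
                     function(n) as.list(rep(0.5, n)),
                     n_samples = 1000, seed = 2)
  expect_equal(ev0$log_ml, 3 * log(0.5), tolerance = 1e-12)
  expect_equal(ev0$se, 0)

  # Beta-Bernoulli: uniform prior, 1 success in 2 trials -> integral = 1/6
  ev <- evidence_mc(function(p) log(p) + log(1 - p),
                    function(n) as.list(runif(n)),
                    n_samples = 10000, seed = 3)
  expect_lt(abs(exp(ev$log_ml) - 1 / 6), 3 * ev$se * exp(ev$log_ml))

  # Monte-Carlo error shrinks like 1/sqrt(n)
  ses <- vapply(1:8, function(s) {
    evidence_mc(function(p) log(p) + log(1 - p),
                function(n) as.list(runif(n)),
                n_samples = 1000, seed = s)$se
  }, numeric(1))
  ses10 <- vapply(1:8, function(s) {
    evidence_mc(function(p) log(p) + log(1 - p),
                function(n) as.list(runif(n)),
                n_samples = 10000, seed = 100 + s)$se
  }, numeric(1))
  expect_equal(mean(ses) / mean(ses10), sqrt(10), tolerance = 0.25)
})

test_that("fit and marginal likelihood share one likelihood code path", {
  trials <- simulate_study(3, default_truth(), seed = 44)
  tr3 <- dplyr::filter(trials, experiment == "exp3")
  f <- suppressWarnings(fit_model(trials, stage = "prediction", chains = 1,
                                  warmup = 200, iter = 1000, seed = 8))
  ev <- marginal_likelihood(tr3, "integration", f, seed = 1)
  # recompute the same average through the slow enumeration oracle
  dm <- pragword:::draw_matrix(f)
  ll <- vapply(seq_len(nrow(dm)), function(s) {
    co <- pragword:::par_to_coeffs(dm[s, ], with_phi = FALSE)
    oracle_loglik(tr3, co, "integration")
  }, numeric(1))
  m <- max(ll)
  expect_equal(ev$log_ml, m + log(mean(exp(ll - m))), tolerance = 1e-8)
  expect_true(is.finite(ev$se))
  expect_equal(ev$n_samples, 1000)
})

test_that("evidence and Bayes factors handle edge cases per contract", {
  tr3 <- dplyr::filter(simulate_study(2, default_truth(), seed = 4),
                       experiment == "exp3")
  expect_error(marginal_likelihood(tr3, "integration", prior_spec(),
                                   n_samples = 10, seed = 1),
               class = "pragword_config_error")
  f <- suppressWarnings(fit_model(tr3, chains = 1, warmup = 100, iter = 1000,
                                  seed = 2))
  expect_error(marginal_likelihood(tr3, "biased", f, seed = 1),
               class = "pragword_config_error")

  a <- pragword:::new_evidence(rep(log(0.5), 5), "a")
  b <- pragword:::new_evidence(rep(log(0.5), 5), "b")
  expect_equal(bayes_factor(a, b)$bf, 1)
  c2 <- pragword:::new_evidence(rep(log(0.5) - log(10), 5), "c")
  expect_equal(bayes_factor(a, c2)$bf, 10, tolerance = 1e-10)
  expect_equal(bayes_factor(a, c2)$log10_bf, 1, tolerance = 1e-10)

  inf <- suppressWarnings(pragword:::new_evidence(rep(-Inf, 5), "z"))
  expect_warning(bayes_factor(a, inf), class = "pragword_evidence_warning")
})

test_that("the bias parameter is recovered from biased-model data", {
  truth <- default_truth()
  # constant bias: generating phi = logistic(0.62) ~ 0.65
  truth$phi <- c(intercept = 0.62, slope = 0)
  trials <- simulate_study(40, truth, "biased", seed = 60)
  f <- suppressWarnings(
    fit_model(trials, "biased", stage = "explanation", chains = 2,
              warmup = 800, iter = 700, seed = 61))
  phi_draws <- plogis(f$draws$phi_intercept)
  expect_equal(mean(phi_draws), plogis(0.62), tolerance = 0.08)
  h <- hdi(phi_draws)
  expect_lt(h$lower, plogis(0.62))
  expect_gt(h$upper, plogis(0.62))
})
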