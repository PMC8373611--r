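# Independent brute-force oracles. These enumerate the 2x2 utterance-by-
# referent scene with explicit matrices and never touch the package's
# closed-form kernels, so they can arbitrate them.

# literal listener table: rows = utterances, cols = c(novel, familiar)
oracle_l0 <- function(theta) {
  m <- rbind(
    novel_word = c(0.5, 0.5),
    familiar_word = c(theta * 0 + (1 - theta) * 0.5,
                      theta * 1 + (1 - theta) * 0.5)
  )
  sweep(m, 1, rowSums(m), "/")
}

# speaker table: P(utterance | referent), cols = c(novel, familiar)
oracle_s1 <- function(alpha, theta) {
  l0 <- oracle_l0(theta)
  u <- l0^alpha
  sweep(u, 2, colSums(u), "/")
}

# pragmatic listener p(novel object | novel word)
oracle_l1_p_novel <- function(alpha, theta, prior_novel) {
  s1 <- oracle_s1(alpha, theta)
  w <- s1["novel_word", ] * c(prior_novel, 1 - prior_novel)
  unname(w[1] / sum(w))
}

# model-variant choice probability via the enumeration oracle
oracle_choice <- function(model, alpha, theta, prior_novel,
                          phi = NULL, theta_pooled = NULL) {
  switch(model,
    integration = oracle_l1_p_novel(alpha, theta, prior_novel),
    no_word_knowledge = oracle_l1_p_novel(alpha, theta_pooled, prior_novel),
    no_common_ground = oracle_l1_p_novel(alpha, theta, 0.5),
    no_speaker_informativeness = prior_novel,
    phi * oracle_l1_p_novel(alpha, theta, 0.5) + (1 - phi) * prior_novel
  )
}

# slow reference log-likelihood of a trial table given pw_coeffs, reading
# the coefficient fields directly and using the enumeration oracle per row
oracle_loglik <- function(trials, coeffs, model) {
  coeffs[c("alpha", "rho", "theta", "phi")] <-
    lapply(coeffs[c("alpha", "rho", "theta", "phi")], unname)
  ac <- trials$age - coeffs$age_center
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    rho <- plogis(coeffs$rho[1] + coeffs$rho[2] * ac[i])
    if (trials$experiment[i] == "exp2") {
      p <- rho
    } else {
      lpa <- coeffs$alpha[1] + coeffs$alpha[2] * ac[i]
      alpha <- if (coeffs$alpha_link == "log") exp(lpa) else max(0, lpa)
      j <- match(trials$object_id[i], coeffs$theta_obj$object_id)
      theta <- plogis(coeffs$theta[1] + coeffs$theta_obj$intercept[j] +
                        (coeffs$theta[2] + coeffs$theta_obj$slope[j]) * ac[i])
      if (trials$experiment[i] == "exp1") {
        p <- oracle_l1_p_novel(alpha, theta, 0.5)
      } else {
        prior <- if (trials$condition[i] == "congruent") rho else 1 - rho
        p <- switch(model,
          integration = oracle_l1_p_novel(alpha, theta, prior),
          no_word_knowledge = oracle_l1_p_novel(
            alpha, plogis(coeffs$theta[1] + coeffs$theta[2] * ac[i]), prior),
          no_common_ground = oracle_l1_p_novel(alpha, theta, 0.5),
          no_speaker_informativeness = prior,
          biased = {
            phi <- plogis(coeffs$phi[1])
            phi * oracle_l1_p_novel(alpha, theta, 0.5) + (1 - phi) * prior
          },
          developmental_bias = {
            phi <- plogis(coeffs$phi[1] + coeffs$phi[2] * ac[i])
            phi * oracle_l1_p_novel(alpha, theta, 0.5) + (1 - phi) * prior
          })
      }
    }
    ll <- ll + if (trials$correct[i] == 1) log(p) else log(1 - p)
  }
  ll
}

# small fitted fixture shared across test files, computed once per run
fixture_env <- new.env(parent = emptyenv())

fixture_prediction_fit <- function() {
  if (is.null(fixture_env$pred_fit)) {
    trials <- simulate_study(30, default_truth(), "integration", seed = 101)
    fixture_env$pred_trials <- trials
    fixture_env$pred_fit <- suppressWarnings(
      fit_model(trials, "integration", stage = "prediction",
                chains = 2, warmup = 600, iter = 500, seed = 202)
    )
  }
  list(fit = fixture_env$pred_fit, trials = fixture_env$pred_trials)
}
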