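# Flat parameter layout shared with the compiled kernel (src/likelihood.cpp).
# Order matters and is fixed: 6 main trajectory coefficients, 12 + 12 object
# offsets, 2 log random-effect scales, 2 bias coefficients.

par_layout <- function(objects = default_objects()) {
  ids <- objects$object_id
  c("alpha_intercept", "alpha_slope",
    "rho_intercept", "rho_slope",
    "theta_intercept", "theta_slope",
    paste0("theta_obj_intercept[", ids, "]"),
    paste0("theta_obj_slope[", ids, "]"),
    "log_sd_obj_intercept", "log_sd_obj_slope",
    "phi_intercept", "phi_slope")
}

MAIN_PARS <- c("alpha_intercept", "alpha_slope", "rho_intercept", "rho_slope",
               "theta_intercept", "theta_slope", "phi_intercept", "phi_slope")

# pw_coeffs -> flat vector in the kernel's non-centred parameterization:
# offsets are stored standardized, the log scales carry their spread, and
# the kernel multiplies them back (exactly reproducing the given offsets)
coeffs_to_par <- function(coeffs, objects = default_objects()) {
  stopifnot(inherits(coeffs, "pw_coeffs"))
  idx <- match(objects$object_id, coeffs$theta_obj$object_id)
  if (anyNA(idx)) abort_config("coefficients lack offsets for some objects")
  sd0 <- max(sd(coeffs$theta_obj$intercept[idx]), 1e-3)
  sd1 <- max(sd(coeffs$theta_obj$slope[idx]), 1e-3)
  par <- c(coeffs$alpha, coeffs$rho, coeffs$theta,
           coeffs$theta_obj$intercept[idx] / sd0,
           coeffs$theta_obj$slope[idx] / sd1,
           log(sd0), log(sd1),
           if (is.null(coeffs$phi)) c(0, 0) else coeffs$phi)
  setNames(par, par_layout(objects))
}

# flat kernel vector -> pw_coeffs (offsets rescaled to the natural scale)
par_to_coeffs <- function(par, objects = default_objects(), age_center = 3,
                          alpha_link = "identity_clip", with_phi = FALSE) {
  s0 <- exp(par[31])
  s1 <- exp(par[32])
  trajectory_coefficients(
    alpha = par[1:2], rho = par[3:4], theta = par[5:6],
    theta_obj = tibble::tibble(object_id = objects$object_id,
                               intercept = unname(par[7:18]) * s0,
                               slope = unname(par[19:30]) * s1),
    phi = if (with_phi) par[33:34],
    age_center = age_center, alpha_link = alpha_link
  )
}

# trial tibble -> integer/double vectors for the kernel
prepare_trial_data <- function(data, objects = default_objects()) {
  data <- validate_trials(data)
  obj <- match(data$object_id, objects$object_id)
  if (any(is.na(obj) & !is.na(data$object_id))) {
    abort_config("trial table contains objects not in the roster")
  }
  list(
    y = as.integer(data$correct),
    age = as.double(data$age),
    expid = match(data$experiment, c("exp1", "exp2", "exp3")),
    cond = match(data$condition, c("congruent", "incongruent"),
                 nomatch = 0L),
    obj = ifelse(is.na(obj), -1L, obj - 1L),
    n = nrow(data)
  )
}

# total log-likelihood of a trial table at one parameter vector; this is the
# single likelihood code path used by fitting, evidence and prediction
trial_loglik <- function(par, td, model, age_center = 3,
                         alpha_link = "identity_clip") {
  cpp_loglik(as.numeric(par), td$y, td$age, as.integer(td$expid),
             as.integer(td$cond), as.integer(td$obj), model_code(model),
             age_center, as.integer(alpha_link == "log"))
}
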