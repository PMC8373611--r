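#' Default familiar-object roster
#'
#' Twelve familiar objects ordered by rated age of acquisition
#' (`aoa_rank` 1 = earliest acquired, easiest). Synthetic analyses use
#' placeholder identifiers `obj01` ... `obj12`.
#'
#' @return A tibble with columns `object_id`, `display_name`, `aoa_rank`.
#' @export
#' @examples
#' default_objects()
default_objects <- function() {
  tibble::tibble(
    object_id = sprintf("obj%02d", 1:12),
    display_name = sprintf("object %02d", 1:12),
    aoa_rank = 1:12
  )
}

#' Age trajectories of the model parameters
#'
#' Bundles the regression coefficients that map a child's age to the model
#' parameters: a linear submodel for speaker informativeness `alpha`, and
#' logistic submodels for the common-ground parameter `rho`, semantic
#' knowledge `theta` (with per-object random intercept/slope offsets around
#' the main trajectory) and, for the biased variants, the bias `phi`. All
#' slopes are per year of age; ages are centred at `age_center` before the
#' linear predictor is formed.
#'
#' @param alpha,rho,theta,phi Length-2 numeric vectors `c(intercept, slope)`
#'   (`rho`, `theta`, `phi` on the logit scale). `phi` may be `NULL` when no
#'   biased variant is evaluated.
#' @param theta_obj Data frame with columns `object_id`, `intercept`,
#'   `slope`: per-object logit-scale offsets around the `theta` main effect,
#'   one row per familiar object.
#' @param age_center Years subtracted from age before applying slopes.
#' @param alpha_link `"identity_clip"` (linear predictor clipped at zero) or
#'   `"log"` (exponentiated linear predictor).
#' @return An object of class `pw_coeffs`.
#' @export
#' @examples
#' co <- trajectory_coefficients(
#'   alpha = c(1, 0.5), rho = c(0.6, 0.45), theta = c(0.8, 0.8),
#'   theta_obj = tibble::tibble(object_id = default_objects()$object_id,
#'                              intercept = 0, slope = 0)
#' )
#' alpha_at(co, age = 3)
trajectory_coefficients <- function(alpha = c(0, 0), rho = c(0, 0),
                                    theta = c(0, 0),
                                    theta_obj = NULL,
                                    phi = NULL,
                                    age_center = 3,
                                    alpha_link = c("identity_clip", "log")) {
  alpha_link <- match.arg(alpha_link)
  pair <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
      abort_config(paste0("`", name, "` must be c(intercept, slope)"))
    }
    setNames(as.numeric(x), c("intercept", "slope"))
  }
  if (is.null(theta_obj)) {
    theta_obj <- tibble::tibble(object_id = default_objects()$object_id,
                                intercept = 0, slope = 0)
  }
  theta_obj <- tibble::as_tibble(theta_obj)
  if (!all(c("object_id", "intercept", "slope") %in% names(theta_obj))) {
    abort_config("`theta_obj` needs columns object_id, intercept, slope")
  }
  if (anyDuplicated(theta_obj$object_id)) {
    abort_config("`theta_obj` must have exactly one row per object")
  }
  structure(
    list(
      alpha = pair(alpha, "alpha"),
      rho = pair(rho, "rho"),
      theta = pair(theta, "theta"),
      theta_obj = theta_obj,
      phi = if (!is.null(phi)) pair(phi, "phi"),
      age_center = age_center,
      alpha_link = alpha_link
    ),
    class = "pw_coeffs"
  )
}

#' @export
print.pw_coeffs <- function(x, ...) {
  cat("<pw_coeffs> age trajectories (age centred at ",
      x$age_center, " yr)\n", sep = "")
  cat(sprintf("  alpha: %.3f + %.3f * age_c  [%s link]\n",
              x$alpha[1], x$alpha[2], x$alpha_link))
  cat(sprintf("  rho:   logit^-1(%.3f + %.3f * age_c)\n", x$rho[1], x$rho[2]))
  cat(sprintf("  theta: logit^-1(%.3f + %.3f * age_c), %d object offset pairs\n",
              x$theta[1], x$theta[2], nrow(x$theta_obj)))
  if (!is.null(x$phi)) {
    cat(sprintf("  phi:   logit^-1(%.3f + %.3f * age_c)\n", x$phi[1], x$phi[2]))
  }
  invisible(x)
}

#' @rdname trajectory_coefficients
#' @param x A `pw_coeffs` object.
#' @param ... Unused.
#' @export
tidy.pw_coeffs <- function(x, ...) {
  main <- purrr::map_dfr(
    c("alpha", "rho", "theta", if (!is.null(x$phi)) "phi"),
    function(p) tibble::tibble(parameter = p,
                               term = c("intercept", "slope"),
                               object_id = NA_character_,
                               value = unname(x[[p]]))
  )
  obj <- tidyr::pivot_longer(x$theta_obj, c("intercept", "slope"),
                             names_to = "term", values_to = "value")
  obj <- dplyr::mutate(obj, parameter = "theta_obj", .before = 1)
  dplyr::bind_rows(main, obj[, c("parameter", "term", "object_id", "value")])
}

#' Logistic age trajectory
#'
#' Inverse-logit of `intercept + offset_intercept + (slope + offset_slope) *
#' (age - age_center)`: the link shared by the common-ground, semantic
#' knowledge and bias submodels.
#'
#' @param age Age in years.
#' @param intercept,slope Main-effect coefficients (logit scale, slope per
#'   year).
#' @param offset_intercept,offset_slope Optional object-level offsets.
#' @param age_center Centring constant in years.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' logistic_trajectory_at(5, intercept = -1, slope = 0.5, age_center = 3)
logistic_trajectory_at <- function(age, intercept, slope,
                                   offset_intercept = 0, offset_slope = 0,
                                   age_center = 3) {
  plogis(intercept + offset_intercept +
           (slope + offset_slope) * (age - age_center))
}

#' Speaker informativeness at a given age
#'
#' @param coeffs A [trajectory_coefficients()] object.
#' @param age Age in years.
#' @return Non-negative numeric vector: for the `identity_clip` link the
#'   linear predictor clipped below at zero, for the `log` link its
#'   exponential.
#' @export
alpha_at <- function(coeffs, age) {
  lp <- coeffs$alpha[["intercept"]] +
    coeffs$alpha[["slope"]] * (age - coeffs$age_center)
  if (coeffs$alpha_link == "log") exp(lp) else pmax(0, lp)
}

#' @rdname alpha_at
#' @export
rho_at <- function(coeffs, age) {
  logistic_trajectory_at(age, coeffs$rho[["intercept"]],
                         coeffs$rho[["slope"]], age_center = coeffs$age_center)
}

#' @rdname alpha_at
#' @param object_id Object identifiers (or `NULL` for the pooled main-effect
#'   trajectory ignoring object variation).
#' @export
theta_at <- function(coeffs, age, object_id = NULL) {
  if (is.null(object_id)) {
    return(logistic_trajectory_at(age, coeffs$theta[["intercept"]],
                                  coeffs$theta[["slope"]],
                                  age_center = coeffs$age_center))
  }
  idx <- match(object_id, coeffs$theta_obj$object_id)
  if (anyNA(idx)) {
    abort_config(paste0("unknown object_id: ",
                        paste(unique(object_id[is.na(idx)]), collapse = ", ")))
  }
  logistic_trajectory_at(age, coeffs$theta[["intercept"]],
                         coeffs$theta[["slope"]],
                         offset_intercept = coeffs$theta_obj$intercept[idx],
                         offset_slope = coeffs$theta_obj$slope[idx],
                         age_center = coeffs$age_center)
}

#' @rdname alpha_at
#' @export
phi_at <- function(coeffs, age) {
  if (is.null(coeffs$phi)) {
    abort_config("these coefficients carry no `phi` trajectory")
  }
  logistic_trajectory_at(age, coeffs$phi[["intercept"]],
                         coeffs$phi[["slope"]], age_center = coeffs$age_center)
}

#' Condition-specific referent prior
#'
#' Maps the common-ground parameter `rho` to the prior probability that the
#' contextually novel object is the referent: in the congruent condition the
#' novel object is also new in context (prior `rho`), in the incongruent
#' condition the familiar object is the contextually new one (prior
#' `1 - rho`); with no common-ground manipulation (`none`) the prior is
#' uniform.
#'
#' @param condition Character vector in `{"congruent", "incongruent", "none"}`.
#' @param rho Numeric vector in `[0, 1]`.
#' @return Numeric vector of prior probabilities for the novel object.
#' @export
#' @examples
#' prior_novel_for("incongruent", rho = 0.8)  # 0.2
prior_novel_for <- function(condition, rho) {
  check_unit(rho, "rho")
  if (!all(condition %in% c("congruent", "incongruent", "none"))) {
    abort_config("`condition` must be congruent, incongruent or none")
  }
  n <- vctrs_size2(condition, rho)
  condition <- rep_len(condition, n)
  rho <- rep_len(rho, n)
  dplyr::case_when(
    condition == "congruent" ~ rho,
    condition == "incongruent" ~ 1 - rho,
    TRUE ~ 0.5
  )
}

#' Assemble parameter slices for trial rows
#'
#' Maps each row's age, object and condition to the parameter values at
#' which a model variant is evaluated: `alpha` from the linear submodel,
#' `theta` from the logistic submodel with object offsets (the pooled
#' trajectory additionally as `theta_pooled` for the no-word-knowledge
#' lesion), the referent prior from the condition (forced to 0.5 for the
#' no-common-ground lesion), and `phi` for the biased variants.
#'
#' @param data Data frame with columns `age`, `object_id`, `condition`
#'   (`object_id` may be `NA` only where `theta` is not needed).
#' @param coeffs A [trajectory_coefficients()] object.
#' @param model One of [model_names()].
#' @return The input as a tibble with parameter columns appended.
#' @export
param_slice_at <- function(data, coeffs, model = "integration") {
  model <- match.arg(model, MODEL_NAMES)
  data <- tibble::as_tibble(data)
  need <- c("age", "object_id", "condition")
  if (!all(need %in% names(data))) {
    abort_config("`data` needs columns age, object_id, condition")
  }
  out <- data
  out$alpha <- if (model == "no_speaker_informativeness") {
    0
  } else {
    alpha_at(coeffs, data$age)
  }
  # rows without a familiar object (e.g. discourse-novelty trials) fall back
  # to the pooled semantic-knowledge trajectory
  has_obj <- !is.na(data$object_id)
  out$theta <- theta_at(coeffs, data$age)
  if (any(has_obj)) {
    out$theta[has_obj] <- theta_at(coeffs, data$age[has_obj],
                                   data$object_id[has_obj])
  }
  if (model == "no_word_knowledge") {
    out$theta_pooled <- theta_at(coeffs, data$age)
  }
  rho <- rho_at(coeffs, data$age)
  out$prior_novel <- if (model == "no_common_ground") {
    0.5
  } else {
    prior_novel_for(data$condition, rho)
  }
  if (model %in% c("biased", "developmental_bias")) {
    out$phi <- if (model == "biased") {
      plogis(coeffs$phi[["intercept"]])
    } else {
      phi_at(coeffs, data$age)
    }
  }
  out
}
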