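#' Literal listener
#'
#' Interprets an utterance in proportion to its literal meaning only. The
#' lexicon carries graded semantic knowledge: with probability `theta` the
#' familiar word exclusively denotes the familiar object, with probability
#' `1 - theta` it is unknown to the listener and applies to both referents
#' equally; the novel word always applies to both referents equally.
#'
#' @param utterance Character vector, `"novel_word"` or `"familiar_word"`.
#' @param theta Numeric vector in `[0, 1]`: probability that the familiar
#'   word is known (object-specific semantic knowledge).
#' @return A tibble with columns `utterance`, `theta`, `p_novel`,
#'   `p_familiar`, one row per input; the two probabilities sum to one.
#' @export
#' @examples
#' literal_listener("familiar_word", theta = 0.5)
literal_listener <- function(utterance, theta) {
  check_unit(theta, "theta")
  utterance <- check_utterance(utterance)
  n <- vctrs_size2(utterance, theta)
  utterance <- rep_len(utterance, n)
  theta <- rep_len(theta, n)
  # meaning mass: familiar word -> ((1 - theta)/2, (1 + theta)/2); novel -> (1/2, 1/2)
  p_novel <- ifelse(utterance == "novel_word", 0.5, (1 - theta) / 2)
  p_familiar <- ifelse(utterance == "novel_word", 0.5, (1 + theta) / 2)
  tibble::tibble(utterance = utterance, theta = theta,
                 p_novel = p_novel, p_familiar = p_familiar)
}

#' Informative speaker
#'
#' A speaker who, intending referent `referent`, soft-maximises the
#' informativity of the two candidate utterances: the probability of an
#' utterance is proportional to the literal listener's probability of the
#' intended referent raised to the informativeness exponent `alpha`.
#' `alpha = 0` yields a uniform speaker; large `alpha` approaches the
#' arg-max speaker.
#'
#' @param referent Character vector, `"novel_object"` or `"familiar_object"`.
#' @param alpha Non-negative numeric vector: speaker informativeness.
#' @param theta Numeric vector in `[0, 1]`, as in [literal_listener()].
#' @return A tibble with columns `referent`, `alpha`, `theta`,
#'   `p_novel_word`, `p_familiar_word`.
#' @export
#' @examples
#' speaker("familiar_object", alpha = 1, theta = 1)
speaker <- function(referent, alpha, theta) {
  check_alpha(alpha)
  check_unit(theta, "theta")
  referent <- check_referent(referent)
  n <- vctrs_size2(referent, alpha, theta)
  referent <- rep_len(referent, n)
  alpha <- rep_len(alpha, n)
  theta <- rep_len(theta, n)
  l0_novel_word <- literal_listener(rep("novel_word", n), theta)
  l0_familiar_word <- literal_listener(rep("familiar_word", n), theta)
  inf_novel_word <- ifelse(referent == "novel_object",
                           l0_novel_word$p_novel, l0_novel_word$p_familiar)
  inf_familiar_word <- ifelse(referent == "novel_object",
                              l0_familiar_word$p_novel, l0_familiar_word$p_familiar)
  u_novel <- inf_novel_word^alpha
  u_familiar <- inf_familiar_word^alpha
  z <- u_novel + u_familiar
  bad <- which(z == 0 | !is.finite(z))
  if (length(bad) > 0) {
    # underflow guard: redo in log space (alpha = 0 gives log-weight 0 even
    # for a zero-informativity utterance, matching x^0 = 1)
    logw <- function(inf, a) ifelse(a == 0, 0, a * log(inf))
    la <- logw(inf_novel_word[bad], alpha[bad])
    lb <- logw(inf_familiar_word[bad], alpha[bad])
    if (any(la == -Inf & lb == -Inf)) {
      abort_domain("degenerate scene: both utterances have zero informativity")
    }
    m <- pmax(la, lb)
    u_novel[bad] <- exp(la - m)
    u_familiar[bad] <- exp(lb - m)
    z[bad] <- u_novel[bad] + u_familiar[bad]
  }
  tibble::tibble(referent = referent, alpha = alpha, theta = theta,
                 p_novel_word = u_novel / z, p_familiar_word = u_familiar / z)
}

# closed-form speaker probability of uttering the novel word, used by the
# pragmatic listener; r_novel: P(novel_word | novel_object) and familiar analogue
speaker_novel_word <- function(alpha, theta) {
  list(given_novel = 1 / (1 + (1 - theta)^alpha),
       given_familiar = 1 / (1 + (1 + theta)^alpha))
}

#' Pragmatic listener: rational integration of all cues
#'
#' Bayesian inference over the referent after hearing the novel word: the
#' speaker likelihood (informativeness `alpha`, semantic knowledge `theta`)
#' is combined with the common-ground referent prior `prior_novel`.
#'
#' @param alpha Non-negative numeric vector: speaker informativeness.
#' @param theta Numeric vector in `[0, 1]`: semantic knowledge.
#' @param prior_novel Numeric vector in `[0, 1]`: prior probability that the
#'   contextually novel object is the referent.
#' @return A tibble with columns `alpha`, `theta`, `prior_novel`, `p_novel`,
#'   `p_familiar`.
#' @export
#' @examples
#' pragmatic_listener(alpha = 1, theta = 1, prior_novel = 0.5)  # p_novel 0.75
pragmatic_listener <- function(alpha, theta, prior_novel) {
  check_alpha(alpha)
  check_unit(theta, "theta")
  check_unit(prior_novel, "prior_novel")
  n <- vctrs_size2(alpha, theta, prior_novel)
  alpha <- rep_len(alpha, n)
  theta <- rep_len(theta, n)
  prior_novel <- rep_len(prior_novel, n)
  p <- listener_p_novel(alpha, theta, prior_novel)
  tibble::tibble(alpha = alpha, theta = theta, prior_novel = prior_novel,
                 p_novel = p, p_familiar = 1 - p)
}

# scalar/vector kernel shared by every variant; exact at prior 0 and 1
listener_p_novel <- function(alpha, theta, prior_novel) {
  s <- speaker_novel_word(alpha, theta)
  num <- prior_novel * s$given_novel
  den <- num + (1 - prior_novel) * s$given_familiar
  p <- num / den
  # exact 0/1 priors propagate exactly (s$given_novel >= 1/2 always, so the
  # posterior is only ever 0/0 when the prior itself is degenerate at 0 and
  # the familiar-referent likelihood has underflowed)
  p[prior_novel == 0] <- 0
  p[prior_novel == 1] <- 1
  if (anyNA(p)) {
    abort_domain("degenerate scene: posterior over referents is unnormalizable")
  }
  p
}

#' Mutual exclusivity inference
#'
#' The pragmatic listener with a uniform referent prior: only speaker
#' informativeness and object-specific semantic knowledge enter. This is the
#' inference that a knowledgeable speaker would have used the familiar word
#' had they meant the familiar object.
#'
#' @inheritParams pragmatic_listener
#' @return A tibble with columns `alpha`, `theta`, `p_novel`, `p_familiar`.
#' @export
#' @examples
#' mutual_exclusivity(alpha = 1, theta = 1)  # p_novel 0.75
mutual_exclusivity <- function(alpha, theta) {
  out <- pragmatic_listener(alpha, theta, prior_novel = 0.5)
  out$prior_novel <- NULL
  out
}

#' Bias-weighted mixture of inferences
#'
#' Convex combination of a mutual-exclusivity inference and the
#' common-ground prior, weighted by the bias parameter `phi` (`phi = 1`:
#' pure mutual exclusivity; `phi = 0`: pure prior). The result is always
#' bounded between its two components.
#'
#' @param phi Numeric vector in `[0, 1]`: bias toward the mutual-exclusivity
#'   inference.
#' @param me_p_novel Numeric vector in `[0, 1]`: `p_novel` of the
#'   mutual-exclusivity component (e.g. from [mutual_exclusivity()]).
#' @param prior_novel Numeric vector in `[0, 1]`: common-ground prior.
#' @return A tibble with columns `phi`, `me_p_novel`, `prior_novel`,
#'   `p_novel`, `p_familiar`.
#' @export
#' @examples
#' biased_mix(phi = 0.65, me_p_novel = 0.75, prior_novel = 0.5)
biased_mix <- function(phi, me_p_novel, prior_novel) {
  check_unit(phi, "phi")
  check_unit(me_p_novel, "me_p_novel")
  check_unit(prior_novel, "prior_novel")
  n <- vctrs_size2(phi, me_p_novel, prior_novel)
  phi <- rep_len(phi, n)
  me_p_novel <- rep_len(me_p_novel, n)
  prior_novel <- rep_len(prior_novel, n)
  p <- phi * me_p_novel + (1 - phi) * prior_novel
  tibble::tibble(phi = phi, me_p_novel = me_p_novel, prior_novel = prior_novel,
                 p_novel = p, p_familiar = 1 - p)
}

#' Predicted choice probability under a model variant
#'
#' Dispatches over the six model variants and returns, for each parameter
#' slice, the probability of choosing the contextually novel object on
#' hearing the novel word.
#'
#' @param params A data frame with one row per evaluation and columns
#'   `alpha`, `theta`, `prior_novel`, plus `phi` for the biased variants and
#'   `theta_pooled` for the no-word-knowledge variant.
#' @param model One of [model_names()].
#' @return The input as a tibble with a `p_choice` column appended.
#' @export
#' @examples
#' params <- tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.5)
#' predict_choice(params, model = "integration")
predict_choice <- function(params, model = "integration") {
  model <- match.arg(model, MODEL_NAMES)
  params <- tibble::as_tibble(params)
  need <- c("alpha", "theta", "prior_novel")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols) > 0) {
    abort_config(paste0("`params` lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (model %in% c("biased", "developmental_bias") && is.null(params[["phi"]])) {
    abort_config(paste0("model '", model, "' requires a `phi` column"))
  }
  if (!model %in% c("biased", "developmental_bias") && !is.null(params[["phi"]])) {
    abort_config(paste0("model '", model, "' does not take a `phi` column"))
  }
  if (model == "no_word_knowledge" && is.null(params[["theta_pooled"]])) {
    abort_config("model 'no_word_knowledge' requires a `theta_pooled` column")
  }
  check_alpha(params$alpha)
  check_unit(params$theta, "theta")
  check_unit(params$prior_novel, "prior_novel")
  p <- switch(
    model,
    integration = listener_p_novel(params$alpha, params$theta, params$prior_novel),
    no_word_knowledge = {
      check_unit(params$theta_pooled, "theta_pooled")
      listener_p_novel(params$alpha, params$theta_pooled, params$prior_novel)
    },
    no_common_ground = listener_p_novel(params$alpha, params$theta, 0.5),
    no_speaker_informativeness = params$prior_novel,
    biased = ,
    developmental_bias = {
      check_unit(params$phi, "phi")
      me <- listener_p_novel(params$alpha, params$theta, 0.5)
      params$phi * me + (1 - params$phi) * params$prior_novel
    }
  )
  dplyr::mutate(params, p_choice = p)
}

# ---- argument checks ---------------------------------------------------

check_unit <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort_domain(paste0("`", name, "` must lie in [0, 1]"))
  }
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0)) {
    abort_domain("`alpha` must be non-negative")
  }
  invisible(alpha)
}

check_utterance <- function(utterance) {
  if (!all(utterance %in% c("novel_word", "familiar_word"))) {
    abort_domain("`utterance` must be 'novel_word' or 'familiar_word'")
  }
  utterance
}

check_referent <- function(referent) {
  if (!all(referent %in% c("novel_object", "familiar_object"))) {
    abort_domain("`referent` must be 'novel_object' or 'familiar_object'")
  }
  referent
}

# common recycling size (scalar or equal lengths)
vctrs_size2 <- function(...) {
  lens <- vapply(list(...), length, 1L)
  n <- max(lens)
  if (!all(lens %in% c(1L, n))) {
    abort_domain("arguments must have length 1 or a common length")
  }
  n
}
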