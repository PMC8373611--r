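#' Experiment design templates
#'
#' Describes the structure of the three experiment designs the models are
#' evaluated on: mutual-exclusivity trials (`exp1`, 12 trials per child, one
#' per familiar object), discourse-novelty trials (`exp2`, 10 trials per
#' child, no familiar objects) and the combined design (`exp3`, 12 trials
#' per child: each familiar object once, six trials in each of the congruent
#' and incongruent alignments). Children are drawn in whole-year age bins
#' (2-, 3- and 4-year-olds) with ages uniform within each bin.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_children_per_year Number of children per age-year bin.
#' @param objects Object roster tibble as from [default_objects()].
#' @return An object of class `pw_design`.
#' @export
#' @examples
#' experiment_design("exp3", n_children_per_year = 60)
experiment_design <- function(experiment = c("exp1", "exp2", "exp3"),
                              n_children_per_year = 60,
                              objects = default_objects()) {
  experiment <- match.arg(experiment)
  if (n_children_per_year < 1) {
    abort_config("`n_children_per_year` must be at least 1")
  }
  objects <- tibble::as_tibble(objects)
  if (experiment != "exp2" && nrow(objects) != 12) {
    abort_config("the object roster must contain exactly 12 familiar objects")
  }
  structure(
    list(
      experiment = experiment,
      n_children_per_year = as.integer(n_children_per_year),
      trials_per_child = switch(experiment, exp1 = 12L, exp2 = 10L, exp3 = 12L),
      objects = objects,
      years = 2:4
    ),
    class = "pw_design"
  )
}

#' Ground-truth coefficients for simulation
#'
#' A documented fixture of generating coefficients with the qualitative
#' developmental shape the models assume: sensitivity to common ground,
#' speaker informativeness and semantic knowledge all increase with age, and
#' the twelve familiar objects span the full range from words known by most
#' two-year-olds to words few four-year-olds know (offsets ordered by
#' age-of-acquisition rank, mean zero). The bias trajectory crosses
#' indifference (`phi = 0.5`) just before age three, favouring common ground
#' in younger and mutual exclusivity in older children.
#'
#' @return A [trajectory_coefficients()] object (with a `phi` trajectory, so
#'   the same truth can drive the biased variants).
#' @export
#' @examples
#' rho_at(default_truth(), 2) < rho_at(default_truth(), 4)
default_truth <- function() {
  objects <- default_objects()
  trajectory_coefficients(
    alpha = c(1.0, 0.5),
    rho = c(0.6, 0.45),
    theta = c(0.8, 0.8),
    theta_obj = tibble::tibble(
      object_id = objects$object_id,
      intercept = seq(2.5, -2.5, length.out = 12),
      slope = seq(-0.25, 0.25, length.out = 12)
    ),
    phi = c(0.62, 0.8),
    age_center = 3
  )
}

#' Simulate a trial-level dataset
#'
#' Generates Bernoulli responses whose success probabilities follow a chosen
#' generating model at each simulated child's age, object and condition:
#' mutual-exclusivity trials use a uniform referent prior, discourse-novelty
#' trials are direct draws from the common-ground trajectory `rho(age)` (the
#' design measures common-ground sensitivity alone), and combined trials use
#' the full model variant. Deterministic given `seed`.
#'
#' @param design A [experiment_design()] object.
#' @param truth Generating [trajectory_coefficients()].
#' @param generating_model One of [model_names()].
#' @param seed Integer seed.
#' @return A trial tibble with columns `child_id`, `age`, `experiment`,
#'   `condition`, `object_id`, `correct`.
#' @export
#' @examples
#' trials <- simulate_experiment(experiment_design("exp1", 5),
#'                               default_truth(), seed = 1)
#' dplyr::count(trials, child_id)
simulate_experiment <- function(design, truth,
                                generating_model = "integration", seed) {
  if (!inherits(design, "pw_design")) {
    abort_config("`design` must come from experiment_design()")
  }
  generating_model <- match.arg(generating_model, MODEL_NAMES)
  if (missing(seed)) abort_config("`seed` is required for simulation")
  if (generating_model %in% c("biased", "developmental_bias") &&
      is.null(truth$phi)) {
    abort_config("generating a biased variant needs `phi` in `truth`")
  }
  withr::with_seed(as.integer(seed), {
    children <- tidyr::expand_grid(year = design$years,
                                   idx = seq_len(design$n_children_per_year))
    children$age <- children$year + runif(nrow(children))
    children$child_id <- sprintf("%s_c%03d", design$experiment,
                                 seq_len(nrow(children)))
    trials <- purrr::pmap_dfr(
      children[, c("child_id", "age")],
      function(child_id, age) child_trials(design, child_id, age)
    )
    trials$p <- generating_probability(trials, truth, generating_model)
    trials$correct <- rbinom(nrow(trials), 1L, trials$p)
    trials$p <- NULL
    tibble::as_tibble(trials[, c("child_id", "age", "experiment", "condition",
                                 "object_id", "correct")])
  })
}

# one child's trial sheet for a design (object order and alignment
# assignment randomised; each familiar object used at most once)
child_trials <- function(design, child_id, age) {
  exp <- design$experiment
  if (exp == "exp2") {
    return(tibble::tibble(child_id = child_id, age = age, experiment = "exp2",
                          condition = "none", object_id = NA_character_,
                          trial = 1:10))
  }
  objs <- sample(design$objects$object_id)
  condition <- if (exp == "exp1") {
    rep("none", 12)
  } else {
    sample(rep(c("congruent", "incongruent"), each = 6))
  }
  tibble::tibble(child_id = child_id, age = age, experiment = exp,
                 condition = condition, object_id = objs,
                 trial = seq_along(objs))
}

# success probability of each trial row under the generating model
generating_probability <- function(trials, truth, generating_model) {
  p <- numeric(nrow(trials))
  is2 <- trials$experiment == "exp2"
  p[is2] <- rho_at(truth, trials$age[is2])
  rest <- !is2
  if (any(rest)) {
    slice <- param_slice_at(trials[rest, ], truth, model = generating_model)
    p[rest] <- predict_choice(slice, model = generating_model)$p_choice
  }
  p
}

#' Simulate all three experiments from one truth
#'
#' Convenience wrapper drawing independent samples of children for each
#' design and binding the resulting trial tables.
#'
#' @inheritParams simulate_experiment
#' @param n_children_per_year Children per age-year bin in every experiment.
#' @param objects Object roster shared by exp1 and exp3.
#' @return A trial tibble covering `exp1`, `exp2` and `exp3`.
#' @export
simulate_study <- function(n_children_per_year = 60, truth = default_truth(),
                           generating_model = "integration", seed,
                           objects = default_objects()) {
  if (missing(seed)) abort_config("`seed` is required for simulation")
  dplyr::bind_rows(
    simulate_experiment(experiment_design("exp1", n_children_per_year, objects),
                        truth, generating_model, seed = seed),
    simulate_experiment(experiment_design("exp2", n_children_per_year, objects),
                        truth, generating_model, seed = seed + 1L),
    simulate_experiment(experiment_design("exp3", n_children_per_year, objects),
                        truth, generating_model, seed = seed + 2L)
  )
}
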