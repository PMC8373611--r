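#' Plot parameter trajectories
#'
#' Developmental trajectories of the common-ground, speaker-informativeness
#' and semantic-knowledge parameters implied by a coefficient set (thin
#' lines: per-object semantic knowledge).
#'
#' @param object A `pw_coeffs` object.
#' @param ages Age grid in years.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pw_coeffs <- function(object, ages = seq(2, 5, by = 0.05), ...) {
  main <- dplyr::bind_rows(
    tibble::tibble(parameter = "rho (common ground)", age = ages,
                   value = rho_at(object, ages)),
    tibble::tibble(parameter = "alpha (informativeness)", age = ages,
                   value = alpha_at(object, ages)),
    tibble::tibble(parameter = "theta (semantic knowledge)", age = ages,
                   value = theta_at(object, ages))
  )
  objs <- tidyr::expand_grid(object_id = object$theta_obj$object_id,
                             age = ages) |>
    dplyr::mutate(parameter = "theta (semantic knowledge)",
                  value = theta_at(object, .data$age, .data$object_id))
  ggplot2::ggplot(main, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(data = objs,
                       ggplot2::aes(group = .data$object_id),
                       linewidth = 0.3, alpha = 0.35) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "parameter value") +
    ggplot2::theme_minimal()
}

#' Plot posterior trajectories of a fitted model
#'
#' Posterior mean and 95% HDI of the three main parameter trajectories
#' across age.
#'
#' @param object A `pw_fit` object.
#' @param ages Age grid in years.
#' @param mass HDI mass.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pw_fit <- function(object, ages = seq(2, 5, by = 0.1),
                            mass = 0.95, ...) {
  dm <- draw_matrix(object)
  ac <- ages - object$age_center
  traj <- function(label, f) {
    vals <- vapply(seq_along(ages), function(i) {
      v <- f(ac[i])
      h <- hdi_interval(v, mass)
      c(mean(v), h)
    }, numeric(3))
    tibble::tibble(parameter = label, age = ages, mean = vals[1, ],
                   lower = vals[2, ], upper = vals[3, ])
  }
  alpha_f <- function(a) {
    lp <- dm[, "alpha_intercept"] + dm[, "alpha_slope"] * a
    if (object$alpha_link == "log") exp(lp) else pmax(0, lp)
  }
  df <- dplyr::bind_rows(
    traj("rho (common ground)",
         function(a) plogis(dm[, "rho_intercept"] + dm[, "rho_slope"] * a)),
    traj("alpha (informativeness)", alpha_f),
    traj("theta (semantic knowledge)",
         function(a) plogis(dm[, "theta_intercept"] + dm[, "theta_slope"] * a))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "posterior trajectory") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed scatter per model
#'
#' The binned-cell comparison underlying the correlation report: one panel
#' per model, predicted cell rates against observed rates with HDI error
#' bars and the identity line.
#'
#' @param observed Output of [bin_responses()].
#' @param predictions Named list of [bin_predictions()] outputs.
#' @return A ggplot.
#' @export
plot_model_fit <- function(observed, predictions) {
  df <- purrr::imap_dfr(predictions, function(pred, nm) {
    dplyr::inner_join(observed, pred,
                      by = c("age_bin", "condition", "object_id")) |>
      dplyr::mutate(model = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted_mean,
                                   y = .data$observed_rate)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$predicted_hdi_low,
                                         xmax = .data$predicted_hdi_high),
                            alpha = 0.4, height = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$age_bin)),
                        size = 1.6) +
    ggplot2::facet_wrap(~model) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted correct rate", y = "observed correct rate",
                  colour = "age bin") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
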