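#' Weakly informative prior specification
#'
#' Independent normal priors on the trajectory coefficients: the speaker
#' informativeness intercept is centred at 1 (an informative but not
#' deterministic speaker; negativity is absorbed by the link), logit-scale
#' intercepts and slopes are centred at 0 with scale 2.5, and the
#' object-offset standard deviations get half-normal hyperpriors.
#'
#' @param alpha List with `loc` and `scale`, each `c(intercept, slope)`.
#' @param rho,theta,phi As `alpha`, on the logit scale.
#' @param re_scale Half-normal scales `c(intercept, slope)` for the standard
#'   deviations of the per-object offsets.
#' @return An object of class `pw_priors`.
#' @export
#' @examples
#' prior_spec()
prior_spec <- function(alpha = list(loc = c(1, 0), scale = c(1, 1)),
                       rho = list(loc = c(0, 0), scale = c(2.5, 2.5)),
                       theta = list(loc = c(0, 0), scale = c(2.5, 2.5)),
                       phi = list(loc = c(0, 0), scale = c(2.5, 2.5)),
                       re_scale = c(1, 1)) {
  blocks <- list(alpha = alpha, rho = rho, theta = theta, phi = phi)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.list(b) || length(b$loc) != 2 || length(b$scale) != 2) {
      abort_config(paste0("prior block `", nm,
                          "` needs loc and scale of length 2"))
    }
    if (any(b$scale <= 0)) abort_config("prior scales must be positive")
  }
  if (length(re_scale) != 2 || any(re_scale <= 0)) {
    abort_config("`re_scale` must be two positive values")
  }
  structure(c(blocks, list(re_scale = setNames(re_scale,
                                               c("intercept", "slope")))),
            class = "pw_priors")
}

#' @export
print.pw_priors <- function(x, ...) {
  cat("<pw_priors>\n")
  for (nm in c("alpha", "rho", "theta", "phi")) {
    cat(sprintf("  %-5s intercept ~ N(%g, %g), slope ~ N(%g, %g)\n", nm,
                x[[nm]]$loc[1], x[[nm]]$scale[1],
                x[[nm]]$loc[2], x[[nm]]$scale[2]))
  }
  cat(sprintf("  object offsets ~ N(0, sd), sd ~ half-N(%g)/half-N(%g)\n",
              x$re_scale[1], x$re_scale[2]))
  invisible(x)
}

# expand a pw_priors object to flat loc/scale vectors over the par layout
prior_vectors <- function(priors, objects = default_objects()) {
  loc <- scale <- setNames(numeric(34), par_layout(objects))
  scale[] <- 1  # offsets/scales positions unused by the normal prior terms
  for (nm in c("alpha", "rho", "theta", "phi")) {
    loc[paste0(nm, c("_intercept", "_slope"))] <- priors[[nm]]$loc
    scale[paste0(nm, c("_intercept", "_slope"))] <- priors[[nm]]$scale
  }
  list(loc = loc, scale = scale,
       re_scale0 = unname(priors$re_scale[1]),
       re_scale1 = unname(priors$re_scale[2]))
}

# draw n parameter vectors from the prior (rows = draws, full layout)
sample_prior_draws <- function(priors, n, objects = default_objects(),
                               active_phi = c(FALSE, FALSE)) {
  pv <- prior_vectors(priors, objects)
  draws <- matrix(0, nrow = n, ncol = 34,
                  dimnames = list(NULL, par_layout(objects)))
  for (nm in MAIN_PARS) {
    draws[, nm] <- rnorm(n, pv$loc[nm], pv$scale[nm])
  }
  if (!active_phi[1]) draws[, "phi_intercept"] <- 0
  if (!active_phi[2]) draws[, "phi_slope"] <- 0
  s0 <- abs(rnorm(n, 0, pv$re_scale0))
  s1 <- abs(rnorm(n, 0, pv$re_scale1))
  draws[, "log_sd_obj_intercept"] <- log(s0)
  draws[, "log_sd_obj_slope"] <- log(s1)
  # offsets are standardized in the kernel layout (non-centred)
  for (j in 1:12) {
    draws[, 6 + j] <- rnorm(n)
    draws[, 18 + j] <- rnorm(n)
  }
  draws
}
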