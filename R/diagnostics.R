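# Split-chain potential scale reduction factor (split-Rhat) for one
# parameter: draws as a (iterations x chains) matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains. x: iterations x chains.
ess_geyer <- function(x) {
  per_chain <- apply(x, 2, function(v) {
    n <- length(v)
    v <- v - mean(v)
    if (all(v == 0)) return(n)
    ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    # sum consecutive pairs while they stay positive
    s <- 0
    k <- 1
    while (k + 1 <= length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (pair <= 0) break
      s <- s + pair
      k <- k + 2
    }
    tau <- max(1, 2 * s / ac[1] - 1)
    n / tau
  })
  sum(per_chain)
}

# Diagnostics table for a draws array (iterations x chains x parameters).
mcmc_diagnostics <- function(arr, par_names) {
  purrr::map_dfr(seq_along(par_names), function(k) {
    x <- arr[, , k, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    tibble::tibble(term = par_names[k],
                   rhat = split_rhat(x),
                   ess = ess_geyer(x))
  })
}
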