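# Simulation-based power analysis for the natural-indirect-effect Wald test
# over grids of sample size and effect parameters.

#' Power of the NIE Wald test by simulation
#'
#' For each replicate, simulates a cohort of unrelated individuals from the
#' generative model, fits the mediator and outcome models by ordinary least
#' squares, computes the NIE with its delta-method p-value, and counts
#' rejections at level `alpha`. Replicate `r` uses seed `seed + r`, so any
#' single replicate can be re-run in isolation. Replicates whose designs are
#' degenerate (e.g. a monomorphic genotype draw) are discarded and the power
#' denominator is the number of successful replicates.
#'
#' @param params a [generative_params()].
#' @param n cohort size per replicate.
#' @param n_reps number of replicates (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed base integer seed.
#' @param a,a_star exposure contrast for the NIE.
#' @return One-row data.frame of class `power_estimate`: `n`, `beta1`,
#'   `theta2`, `theta3`, `sigma_m`, `sigma_y`, `n_reps`, `n_ok`, `alpha`,
#'   `power`, `mc_se` (binomial Monte-Carlo standard error), `seed`.
#' @export
power_nie <- function(params, n, n_reps = 500, alpha = 0.05, seed = 1,
                      a = 1, a_star = 0) {
  stopifnot(inherits(params, "generative_params"), n_reps >= 1,
            alpha > 0, alpha < 1)
  reject <- logical(0)
  n_fail <- 0
  for (r in seq_len(n_reps)) {
    p <- tryCatch({
      ds <- simulate_dataset(params, n, seed = seed + r, family_size = 1)
      med <- fit_mediator_model(ds, "snp1", "cg1", mode = "ols")
      out <- fit_outcome_model(ds, "snp1", "cg1", mode = "ols")
      estimate_nie(med, out, a, a_star)$p
    }, error = function(e) NA_real_)
    if (is.na(p)) n_fail <- n_fail + 1 else reject <- c(reject, p < alpha)
  }
  if (n_fail > 0)
    message(n_fail, " replicate(s) discarded (degenerate fit)")
  n_ok <- length(reject)
  if (!n_ok) stop("all replicates failed to fit")
  pow <- mean(reject)
  structure(data.frame(
    n = n, beta1 = params$beta1, theta2 = params$theta2,
    theta3 = params$theta3, sigma_m = params$sigma_m,
    sigma_y = params$sigma_y, n_reps = n_reps, n_ok = n_ok, alpha = alpha,
    power = pow, mc_se = sqrt(pow * (1 - pow) / n_ok), seed = seed),
    class = c("power_estimate", "data.frame"))
}

#' Power grid over sample size and effect parameters
#'
#' Varies one parameter axis at a time around `base_params` (all other
#' parameters held at their base values) and evaluates [power_nie()] at
#' every grid point, mirroring the one-factor-at-a-time design of a power
#' figure with panels for sample size, `beta1`, `theta2` and `theta3`.
#'
#' @param base_params a [generative_params()] supplying the held-constant
#'   values.
#' @param n_values,beta1_values,theta2_values,theta3_values numeric vectors
#'   of grid values (any may be `NULL`; at least one must be non-empty).
#' @param n_default cohort size used on the effect axes.
#' @param n_reps,alpha,seed,a,a_star passed to [power_nie()]; each grid
#'   point advances the base seed by `n_reps` so no replicate seeds overlap.
#' @return data.frame with one row per grid point: `axis`, `value`, and the
#'   [power_nie()] columns.
#' @export
power_grid <- function(base_params, n_values = NULL, beta1_values = NULL,
                       theta2_values = NULL, theta3_values = NULL,
                       n_default = 1000, n_reps = 500, alpha = 0.05,
                       seed = 1, a = 1, a_star = 0) {
  axes <- list(n = n_values, beta1 = beta1_values,
               theta2 = theta2_values, theta3 = theta3_values)
  if (!sum(lengths(axes))) stop("empty power grid")
  out <- NULL
  k <- 0
  for (axis in names(axes)) {
    for (v in axes[[axis]]) {
      p <- base_params
      n <- n_default
      if (axis == "n") n <- v else p[[axis]] <- v
      class(p) <- "generative_params"
      pe <- power_nie(p, n, n_reps = n_reps, alpha = alpha,
                      seed = seed + k * n_reps, a = a, a_star = a_star)
      out <- rbind(out, cbind(data.frame(axis = axis, value = v), pe))
      k <- k + 1
    }
  }
  out
}
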