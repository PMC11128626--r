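#' Indirect (mediated) effect by the product of coefficients
#'
#' Combines the exposure-to-mediator effect `beta1` and the mediator-to-
#' outcome effect `beta2` into the indirect effect `beta1 * beta2`. The
#' `"delta"` interval uses the first-order standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` with a symmetric normal CI; the
#' default `"montecarlo"` interval draws the two coefficients from independent
#' normals and takes empirical 2.5/97.5 percentiles of their product, which
#' captures the asymmetry of a product of normals.
#'
#' @param beta1,se1 Exposure-to-mediator effect and SE.
#' @param beta2,se2 Mediator-to-outcome effect and SE.
#' @param method `"montecarlo"` (default) or `"delta"`.
#' @param n_draws Monte-Carlo draws (default 100000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return One-row tibble: `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`,
#'   `method`.
#' @export
indirect_effect <- function(beta1, se1, beta2, se2,
                            method = c("montecarlo", "delta"),
                            n_draws = 1e5, seed = 1) {
  method <- match.arg(method)
  if (se1 < 0 || se2 < 0) stop("standard errors must be non-negative", call. = FALSE)
  point <- beta1 * beta2
  se_delta <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  if (method == "delta") {
    z <- if (se_delta == 0) NA_real_ else point / se_delta
    return(tibble::tibble(
      estimate = point, se = se_delta,
      ci_low = point - 1.96 * se_delta, ci_high = point + 1.96 * se_delta,
      pvalue = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
      method = "delta"
    ))
  }
  set.seed(seed)
  draws <- rnorm(n_draws, beta1, se1) * rnorm(n_draws, beta2, se2)
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  p <- min(1, 2 * min(mean(draws <= 0), mean(draws >= 0)))
  tibble::tibble(
    estimate = point, se = stats::sd(draws),
    ci_low = ci[1], ci_high = ci[2], pvalue = p, method = "montecarlo"
  )
}

#' Mediated proportion of the total effect
#'
#' The share of the total causal effect flowing through the mediator,
#' `indirect / total * 100` percent. The `"delta"` CI propagates the ratio
#' variance to first order assuming independence; the default `"montecarlo"`
#' CI redraws indirect (as a product of its two coefficients when supplied)
#' and total effects and takes empirical percentiles of the ratio.
#'
#' @param indirect One-row tibble from [indirect_effect()] or a list with
#'   `estimate` and `se`; for Monte-Carlo propagation the components `beta1`,
#'   `se1`, `beta2`, `se2` may be given instead via `components`.
#' @param total_beta,total_se Total-effect estimate and SE.
#' @param method `"montecarlo"` (default) or `"delta"`.
#' @param components Optional list(beta1, se1, beta2, se2); when present the
#'   Monte-Carlo draws regenerate the indirect effect as a product rather than
#'   a normal.
#' @param n_draws Monte-Carlo draws (default 100000).
#' @param seed Seed.
#' @return One-row tibble: `proportion` (percent), `ci_low`, `ci_high`,
#'   `method`.
#' @export
mediated_proportion <- function(indirect, total_beta, total_se,
                                method = c("montecarlo", "delta"),
                                components = NULL, n_draws = 1e5, seed = 1) {
  method <- match.arg(method)
  if (total_beta == 0) stop("mediated proportion undefined: total effect is zero",
                            call. = FALSE)
  ind_est <- indirect$estimate
  ind_se <- indirect$se
  prop <- ind_est / total_beta * 100
  if (method == "delta") {
    var_r <- ind_se^2 / total_beta^2 +
      ind_est^2 * total_se^2 / total_beta^4
    se_r <- 100 * sqrt(var_r)
    return(tibble::tibble(proportion = prop,
                          ci_low = prop - 1.96 * se_r,
                          ci_high = prop + 1.96 * se_r,
                          method = "delta"))
  }
  set.seed(seed)
  ind_draws <- if (!is.null(components)) {
    rnorm(n_draws, components$beta1, components$se1) *
      rnorm(n_draws, components$beta2, components$se2)
  } else {
    rnorm(n_draws, ind_est, ind_se)
  }
  tot_draws <- rnorm(n_draws, total_beta, total_se)
  ratio <- 100 * ind_draws / tot_draws
  ci <- unname(quantile(ratio, c(0.025, 0.975)))
  tibble::tibble(proportion = prop, ci_low = ci[1], ci_high = ci[2],
                 method = "montecarlo")
}

#' Two-step mediation Mendelian randomization
#'
#' Combines three IVW fits into the mediation decomposition: the total effect
#' (exposure instruments on the outcome), direct effect A (`beta1`, exposure
#' instruments on the mediator), and direct effect B (`beta2`, mediator
#' instruments on the outcome, a univariable fit as in the two-step design).
#' The indirect effect is the product `beta1 * beta2` and the mediated
#' proportion its ratio to the total effect. A full sensitivity suite is
#' attached for each of the three fits.
#'
#' @param exposure_outcome Harmonized instruments for exposure -> outcome.
#' @param exposure_mediator Harmonized instruments for exposure -> mediator.
#' @param mediator_outcome Harmonized instruments for mediator -> outcome.
#' @param interval_method `"montecarlo"` or `"delta"` for the indirect and
#'   proportion intervals.
#' @param n_draws Monte-Carlo draws.
#' @param seed Seed for intervals and sensitivity simulations.
#' @param sensitivity Attach the sensitivity suite per fit (default TRUE).
#' @param n_sim MR-PRESSO simulations inside the sensitivity suite.
#' @param ivw_model IVW flavour for all three fits.
#' @return Object of class `mediation_result` with elements `total`,
#'   `direct_a`, `direct_b` (each an `mr_estimate`), `indirect`, `proportion`
#'   (tibbles), `interval_method`, `sensitivity`.
#' @export
run_two_step <- function(exposure_outcome, exposure_mediator, mediator_outcome,
                         interval_method = c("montecarlo", "delta"),
                         n_draws = 1e5, seed = 1, sensitivity = TRUE,
                         n_sim = 5000, ivw_model = "random") {
  interval_method <- match.arg(interval_method)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  total <- stage("total (exposure->outcome)",
                 mr_ivw(exposure_outcome, model = ivw_model))
  direct_a <- stage("direct A (exposure->mediator)",
                    mr_ivw(exposure_mediator, model = ivw_model))
  direct_b <- stage("direct B (mediator->outcome)",
                    mr_ivw(mediator_outcome, model = ivw_model))

  indirect <- indirect_effect(direct_a$beta, direct_a$se,
                              direct_b$beta, direct_b$se,
                              method = interval_method,
                              n_draws = n_draws, seed = seed)
  proportion <- mediated_proportion(
    indirect, total$beta, total$se, method = interval_method,
    components = list(beta1 = direct_a$beta, se1 = direct_a$se,
                      beta2 = direct_b$beta, se2 = direct_b$se),
    n_draws = n_draws, seed = seed + 1
  )

  sens <- NULL
  if (sensitivity) {
    sens <- list(
      total = mr_sensitivity(exposure_outcome, seed = seed + 2, n_sim = n_sim),
      direct_a = mr_sensitivity(exposure_mediator, seed = seed + 3, n_sim = n_sim),
      direct_b = mr_sensitivity(mediator_outcome, seed = seed + 4, n_sim = n_sim)
    )
  }

  structure(
    list(total = total, direct_a = direct_a, direct_b = direct_b,
         indirect = indirect, proportion = proportion,
         interval_method = interval_method, sensitivity = sens),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation MR\n")
  fmt <- function(lbl, e) cat(sprintf(
    "  %-14s %.4f (%.4f, %.4f)  OR %.3f\n", lbl, e$beta, e$ci_low, e$ci_high,
    exp(e$beta)))
  fmt("total", x$total)
  fmt("direct A", x$direct_a)
  fmt("direct B", x$direct_b)
  cat(sprintf("  %-14s %.4f (%.4f, %.4f)  p = %.3g [%s]\n", "indirect",
              x$indirect$estimate, x$indirect$ci_low, x$indirect$ci_high,
              x$indirect$pvalue, x$interval_method))
  cat(sprintf("  %-14s %.1f%% (%.1f, %.1f)\n", "proportion",
              x$proportion$proportion, x$proportion$ci_low, x$proportion$ci_high))
  invisible(x)
}

#' Tidy a mediation result into a one-row mediation table
#'
#' Shapes the decomposition as one row: total effect, direct effect A
#' (exposure to mediator), direct effect B (mediator to outcome), mediation
#' (indirect) effect with its p-value, and mediated proportion in percent.
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    total_effect = x$total$beta,
    total_ci_low = x$total$ci_low, total_ci_high = x$total$ci_high,
    direct_a = x$direct_a$beta,
    direct_a_ci_low = x$direct_a$ci_low, direct_a_ci_high = x$direct_a$ci_high,
    direct_b = x$direct_b$beta,
    direct_b_ci_low = x$direct_b$ci_low, direct_b_ci_high = x$direct_b$ci_high,
    mediation_effect = x$indirect$estimate,
    mediation_ci_low = x$indirect$ci_low, mediation_ci_high = x$indirect$ci_high,
    mediation_pvalue = x$indirect$pvalue,
    mediated_proportion_pct = x$proportion$proportion,
    proportion_ci_low = x$proportion$ci_low,
    proportion_ci_high = x$proportion$ci_high
  )
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    indirect = x$indirect$estimate,
    indirect_pvalue = x$indirect$pvalue,
    mediated_proportion_pct = x$proportion$proportion,
    interval_method = x$interval_method,
    n_variants_total = x$total$n_variants,
    n_variants_direct_a = x$direct_a$n_variants,
    n_variants_direct_b = x$direct_b$n_variants
  )
}

#' Write a mediation table as TSV
#'
#' @param x A `mediation_result`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
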