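new_mr_estimate <- function(method, beta, se, n_variants) {
  z <- if (is.na(se) || se == 0) NA_real_ else beta / se
  structure(
    list(
      method = method,
      beta = beta,
      se = se,
      ci_low = beta - 1.96 * se,
      ci_high = beta + 1.96 * se,
      pvalue = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
      n_variants = n_variants
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_variants))
  orr <- or_from_beta(x$beta, x$se)
  cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", orr$or, orr$ci_low, orr$ci_high))
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the estimate on the log-odds scale and the
#'   exp-transformed odds-ratio columns.
#' @export
tidy.mr_estimate <- function(x, ...) {
  orr <- or_from_beta(x$beta, x$se)
  tibble::tibble(
    method = x$method, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    n_variants = x$n_variants,
    or = orr$or, or_ci_low = orr$ci_low, or_ci_high = orr$ci_high
  )
}

#' @export
glance.mr_estimate <- function(x, ...) tidy(x, ...)

#' Odds ratio with 95% confidence interval from a log-odds effect
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error (used as `exp(beta +/- 1.96 se)`); ignored when
#'   `ci` is supplied.
#' @param ci Optional length-2 printed CI on the log-odds scale whose
#'   endpoints are exp-transformed directly.
#' @return Tibble with `or`, `ci_low`, `ci_high`.
#' @export
or_from_beta <- function(beta, se = NULL, ci = NULL) {
  if (!is.null(ci)) {
    return(tibble::tibble(or = exp(beta), ci_low = exp(ci[1]), ci_high = exp(ci[2])))
  }
  if (is.null(se)) se <- NA_real_
  if (any(!is.na(se) & se < 0)) stop("se must be non-negative", call. = FALSE)
  tibble::tibble(or = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se))
}

#' Per-variant Wald ratio estimates
#'
#' The single-instrument causal estimate `beta_outcome / beta_exposure` with
#' first-order standard error `se_outcome / |beta_exposure|`. Invariant to
#' jointly negating both betas (an allele flip).
#'
#' @param dat Harmonized instrument tibble.
#' @return Tibble with `variant_id` (if present), `ratio`, `ratio_se` plus the
#'   input effect columns; used as the forest/scatter plot data.
#' @export
wald_ratios <- function(dat) {
  dat <- as_instruments(dat)
  if (any(dat$beta_exposure == 0)) {
    stop("Wald ratio undefined for zero exposure effect", call. = FALSE)
  }
  out <- tibble::tibble(
    ratio = dat$beta_outcome / dat$beta_exposure,
    ratio_se = dat$se_outcome / abs(dat$beta_exposure)
  )
  if ("variant_id" %in% names(dat)) out <- dplyr::bind_cols(
    tibble::tibble(variant_id = dat$variant_id), out)
  dplyr::bind_cols(out, dat[, c("beta_exposure", "se_exposure",
                                "beta_outcome", "se_outcome")])
}

#' Inverse-variance-weighted causal estimate
#'
#' The inverse-variance-weighted (IVW) meta-analysis of per-variant Wald
#' ratios, equivalent to weighted least squares of `beta_outcome` on
#' `beta_exposure` through the origin with weights `1/se_outcome^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`. The fixed-effect standard error is
#' `1/sqrt(sum(w bx^2))`; the default multiplicative random-effects model
#' inflates it by `max(1, sqrt(Q/(J-1)))`, reducing to fixed when `Q <= df`.
#' A single instrument degrades to the Wald ratio with a message.
#'
#' @param dat Harmonized instrument tibble.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(dat, model = c("random", "fixed")) {
  model <- match.arg(model)
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 1) stop("no instruments", call. = FALSE)
  if (all(dat$beta_exposure == 0)) {
    stop("all exposure effects are zero", call. = FALSE)
  }
  w <- dat$se_outcome^-2
  s2 <- sum(w * dat$beta_exposure^2)
  beta <- sum(w * dat$beta_exposure * dat$beta_outcome) / s2
  se <- sqrt(1 / s2)
  if (j == 1) {
    message("single instrument: IVW degrades to the Wald ratio")
    return(new_mr_estimate("IVW", beta, se, 1L))
  }
  if (model == "random" && j >= 2) {
    q <- cochran_q(dat, beta_ref = beta)
    se <- se * max(1, sqrt(q$Q / q$df))
  }
  new_mr_estimate("IVW", beta, se, j)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_outcome` on `beta_exposure` with a free
#' intercept and weights `1/se_outcome^2`, after orienting every instrument so
#' the exposure effect is positive. The slope is the pleiotropy-adjusted
#' causal estimate; a nonzero intercept signals directional pleiotropy and is
#' tested two-sided against zero. Standard errors use a multiplicative
#' random-effects scale, never deflated below the fixed-effect value.
#'
#' @param dat Harmonized instrument tibble (at least 3 instruments).
#' @return An object of class `mr_egger`: `slope` (an `mr_estimate`),
#'   `intercept`, `intercept_se`, `intercept_pvalue`.
#' @export
mr_egger <- function(dat) {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 3) stop("MR-Egger needs at least 3 instruments, got ", j, call. = FALSE)
  flip <- sign(dat$beta_exposure)
  flip[flip == 0] <- 1
  bx <- dat$beta_exposure * flip
  by <- dat$beta_outcome * flip
  w <- dat$se_outcome^-2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- max(1, sigma) / sigma
  co <- sm$coefficients
  slope <- new_mr_estimate("Egger-slope", co["bx", "Estimate"],
                           co["bx", "Std. Error"] * scale, j)
  int_se <- co["(Intercept)", "Std. Error"] * scale
  structure(
    list(
      slope = slope,
      intercept = co["(Intercept)", "Estimate"],
      intercept_se = int_se,
      intercept_pvalue = 2 * pnorm(-abs(co["(Intercept)", "Estimate"] / int_se))
    ),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

#' @rdname mr_egger
#' @param x An `mr_egger` object.
#' @param ... Unused.
#' @export
tidy.mr_egger <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$slope),
    tibble::tibble(method = "Egger-intercept", beta = x$intercept,
                   se = x$intercept_se,
                   ci_low = x$intercept - 1.96 * x$intercept_se,
                   ci_high = x$intercept + 1.96 * x$intercept_se,
                   pvalue = x$intercept_pvalue,
                   n_variants = x$slope$n_variants,
                   or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_)
  )
}

#' @rdname mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  tibble::tibble(beta = x$slope$beta, se = x$slope$se, pvalue = x$slope$pvalue,
                 intercept = x$intercept, intercept_pvalue = x$intercept_pvalue,
                 n_variants = x$slope$n_variants)
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(b[1])
  if (0.5 >= cum[length(cum)]) return(b[length(b)])
  stats::approx(cum, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant Wald ratios and returns the value at which the
#' cumulative inverse-variance weight function (weights
#' `(beta_exposure/se_outcome)^2`, normalized, evaluated at the midpoint of
#' each step) crosses 0.5, by linear interpolation. Consistent when at least
#' half the weight comes from valid instruments. The standard error is a
#' seeded parametric bootstrap: exposure and outcome betas are resampled from
#' their sampling normals and the estimate recomputed.
#'
#' @param dat Harmonized instrument tibble (at least 3 instruments).
#' @param n_boot Bootstrap draws for the SE (default 5000); `0` skips the
#'   bootstrap and returns `NA` SE.
#' @param seed Integer seed (mandatory when `n_boot > 0`).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(dat, n_boot = 5000, seed = NULL) {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 3) stop("weighted median needs at least 3 instruments, got ", j,
                  call. = FALSE)
  ratio <- dat$beta_outcome / dat$beta_exposure
  weight <- (dat$beta_exposure / dat$se_outcome)^2
  est <- weighted_median_point(ratio, weight)
  se <- boot_se(dat, n_boot, seed, function(bx, by) {
    weighted_median_point(by / bx, (bx / dat$se_outcome)^2)
  })
  new_mr_estimate("weighted-median", est, se, j)
}

# Parametric bootstrap SE over resampled (beta_exposure, beta_outcome).
boot_se <- function(dat, n_boot, seed, estimator) {
  if (n_boot == 0) return(NA_real_)
  if (is.null(seed)) stop("a seed is required for the bootstrap SE", call. = FALSE)
  set.seed(seed)
  j <- nrow(dat)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(j, dat$beta_exposure, dat$se_exposure)
    by <- rnorm(j, dat$beta_outcome, dat$se_outcome)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(est)
}

# Exact weighted mode over tied values; used when the kernel bandwidth
# degenerates to zero (e.g. the MAD of the ratios is 0).
exact_weighted_mode <- function(x, w) {
  ux <- unique(x)
  totals <- vapply(ux, function(u) sum(w[x == u]), numeric(1))
  ux[which.max(totals)]
}

# Exact weighted gaussian kernel density argmax: coarse grid then local
# optimisation around the best grid point.
kde_argmax <- function(x, w, h, n_grid = 2048) {
  w <- w / sum(w)
  if (h <= 0 || length(unique(x)) == 1) return(exact_weighted_mode(x, w))
  f <- function(g) vapply(g, function(gi) sum(w * stats::dnorm(gi, x, h)), numeric(1))
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = n_grid)
  dx <- grid[2] - grid[1]
  best <- grid[which.max(f(grid))]
  stats::optimize(function(g) f(g), c(best - dx, best + dx), maximum = TRUE)$maximum
}

#' Mode-based causal estimate (simple and weighted mode)
#'
#' The mode of the kernel-smoothed empirical density of per-variant Wald
#' ratios (normal kernel). Consistent when the largest group of instruments
#' sharing one ratio value is valid (the plurality condition). The bandwidth
#' is `bandwidth_factor` times the modified Silverman scale
#' `0.9 min(sd, mad) J^(-1/5)` of the ratios; when that degenerates to zero
#' (tied ratios) the exact weighted mode of the tied values is returned,
#' which makes the estimator ignore a minority outlier. The weighted variant weights
#' each ratio by its inverse variance `(beta_exposure/se_outcome)^2`; the
#' simple mode weights equally. SE by seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights (weighted mode) rather than
#'   equal weights (simple mode).
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth.
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(dat, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 5000, seed = NULL) {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 3) stop("mode estimator needs at least 3 instruments, got ", j,
                  call. = FALSE)
  mode_of <- function(bx, by) {
    ratio <- by / bx
    w <- if (weighted) (bx / dat$se_outcome)^2 else rep(1, length(ratio))
    h <- bandwidth_factor * 0.9 * min(stats::sd(ratio), stats::mad(ratio)) *
      length(ratio)^(-1 / 5)
    kde_argmax(ratio, w, h)
  }
  est <- mode_of(dat$beta_exposure, dat$beta_outcome)
  se <- boot_se(dat, n_boot, seed, mode_of)
  new_mr_estimate(if (weighted) "weighted-mode" else "simple-mode", est, se, j)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (ratio_j - beta_ref)^2)` over per-variant Wald ratios with
#' first-order weights `w_j = (beta_exposure_j / se_outcome_j)^2`, referred to
#' a chi-square with `J - 1` degrees of freedom. `beta_ref` defaults to the
#' fixed-effect IVW estimate (whose weighting these weights reproduce).
#'
#' @param dat Harmonized instrument tibble (at least 2 instruments).
#' @param beta_ref Reference causal estimate; default the IVW point estimate.
#' @return List of class `mr_heterogeneity`: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(dat, beta_ref = NULL) {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 2) stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  w <- (dat$beta_exposure / dat$se_outcome)^2
  ratio <- dat$beta_outcome / dat$beta_exposure
  if (is.null(beta_ref)) beta_ref <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_ref)^2)
  structure(
    list(Q = q, df = j - 1L, pvalue = pchisq(q, df = j - 1, lower.tail = FALSE)),
    class = "mr_heterogeneity"
  )
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", x$Q, x$df, x$pvalue))
  invisible(x)
}

#' @rdname cochran_q
#' @param x An `mr_heterogeneity` object.
#' @param ... Unused.
#' @export
tidy.mr_heterogeneity <- function(x, ...) {
  tibble::tibble(Q = x$Q, df = x$df, pvalue = x$pvalue)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate omitting each instrument in turn; a materially
#' moving entry indicates a single variant driving the pooled estimate.
#'
#' @param dat Harmonized instrument tibble (at least 3 instruments).
#' @param model Passed to [mr_ivw()].
#' @return Tibble with one row per omitted variant: `omitted`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`.
#' @export
mr_leave_one_out <- function(dat, model = "random") {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 3) stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  ids <- if ("variant_id" %in% names(dat)) dat$variant_id else as.character(seq_len(j))
  purrr::map_dfr(seq_len(j), function(k) {
    fit <- mr_ivw(dat[-k, , drop = FALSE], model = model)
    tibble::tibble(omitted = ids[k], beta = fit$beta, se = fit$se,
                   ci_low = fit$ci_low, ci_high = fit$ci_high,
                   pvalue = fit$pvalue)
  })
}

# Leave-one-out IVW slopes for rows of (BX, BY) matrices under fixed outcome
# weights w; returns a matrix of residuals by_ij - loo_ij * bx_ij.
presso_residuals <- function(BX, BY, w) {
  WX2 <- sweep(BX^2, 2, w, `*`)
  WXY <- sweep(BX * BY, 2, w, `*`)
  s1 <- rowSums(WXY)
  s2 <- rowSums(WX2)
  loo <- (s1 - WXY) / (s2 - WX2)
  BY - loo * BX
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal pleiotropy from the weighted residual sum of squares
#' (RSS) of outcome effects around their leave-one-out IVW predictions. The
#' global p-value is the empirical tail probability of the observed RSS
#' against `n_sim` parametric simulations that redraw both exposure and
#' outcome betas from their sampling distributions under the no-pleiotropy
#' model. Each variant's outlier p-value is the empirical tail of its own
#' squared weighted residual, Bonferroni-adjusted across variants. When
#' outliers are flagged, a distortion test compares the IVW estimate with and
#' without them against the distortion distribution obtained by removing
#' random subsets of the same size.
#'
#' @param dat Harmonized instrument tibble (at least 4 instruments).
#' @param n_sim Number of parametric simulations (at least 1000).
#' @param seed Integer seed (mandatory).
#' @param significance Outlier significance level before Bonferroni
#'   adjustment (default 0.05).
#' @return Object of class `mr_presso`: `rss_observed`, `global_pvalue`,
#'   `outlier_indices`, `outlier_pvalues` (Bonferroni-adjusted),
#'   `distortion_pvalue` and `distortion_pct` (when outliers are found),
#'   `beta_raw`, `beta_outlier_corrected`, `n_simulations`, `seed`.
#' @export
mr_presso <- function(dat, n_sim = 5000, seed = NULL, significance = 0.05) {
  dat <- as_instruments(dat)
  j <- nrow(dat)
  if (j < 4) stop("MR-PRESSO needs at least 4 instruments, got ", j, call. = FALSE)
  if (n_sim < 1000) stop("n_sim must be at least 1000", call. = FALSE)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)

  w <- dat$se_outcome^-2
  bx <- dat$beta_exposure
  by <- dat$beta_outcome
  res_obs <- drop(presso_residuals(matrix(bx, 1), matrix(by, 1), w))
  rss_obs <- sum(w * res_obs^2)

  # parametric simulation under the no-pleiotropy model: outcome betas centred
  # on the leave-one-out IVW prediction, exposure betas on their estimates
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  loo <- (s1 - w * bx * by) / (s2 - w * bx^2)
  mu_y <- loo * bx
  BX <- matrix(rnorm(n_sim * j, rep(bx, each = n_sim), rep(dat$se_exposure, each = n_sim)),
               n_sim, j)
  BY <- matrix(rnorm(n_sim * j, rep(mu_y, each = n_sim), rep(dat$se_outcome, each = n_sim)),
               n_sim, j)
  res_sim <- presso_residuals(BX, BY, w)
  rss_sim <- rowSums(sweep(res_sim^2, 2, w, `*`))
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  out_p <- vapply(seq_len(j), function(k) {
    (1 + sum(res_sim[, k]^2 >= res_obs[k]^2)) / (n_sim + 1)
  }, numeric(1))
  out_p_adj <- pmin(1, out_p * j)
  outliers <- which(out_p_adj < significance)

  beta_raw <- sum(w * bx * by) / sum(w * bx^2)
  distortion_p <- NULL
  distortion_pct <- NULL
  beta_corrected <- NULL
  if (length(outliers) > 0 && length(outliers) < j - 1) {
    keep <- setdiff(seq_len(j), outliers)
    beta_corrected <- sum(w[keep] * bx[keep] * by[keep]) / sum(w[keep] * bx[keep]^2)
    d_obs <- (beta_raw - beta_corrected) / abs(beta_corrected)
    n_rand <- min(n_sim, 1000L)
    d_rand <- vapply(seq_len(n_rand), function(i) {
      drop_k <- sample(j, length(outliers))
      kk <- setdiff(seq_len(j), drop_k)
      b <- sum(w[kk] * bx[kk] * by[kk]) / sum(w[kk] * bx[kk]^2)
      (beta_raw - b) / abs(b)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_rand + 1)
    distortion_pct <- 100 * d_obs
  }

  structure(
    list(
      rss_observed = rss_obs,
      global_pvalue = global_p,
      outlier_indices = outliers,
      outlier_pvalues = out_p_adj,
      distortion_pvalue = distortion_p,
      distortion_pct = distortion_pct,
      beta_raw = beta_raw,
      beta_outlier_corrected = beta_corrected,
      n_simulations = n_sim,
      seed = seed
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.3g (%d simulations)\n",
              x$rss_observed, x$global_pvalue, x$n_simulations))
  if (length(x$outlier_indices) > 0) {
    cat("  outliers at indices:", paste(x$outlier_indices, collapse = ", "), "\n")
    if (!is.null(x$distortion_pvalue)) {
      cat(sprintf("  distortion %.1f%%, p = %.3g\n",
                  x$distortion_pct, x$distortion_pvalue))
    }
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' @rdname mr_presso
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    rss_observed = x$rss_observed, global_pvalue = x$global_pvalue,
    n_outliers = length(x$outlier_indices),
    distortion_pvalue = x$distortion_pvalue %||% NA_real_,
    n_simulations = x$n_simulations
  )
}

#' Run the five-estimator causal panel
#'
#' Fits IVW, MR-Egger, weighted median, simple mode and weighted mode on one
#' harmonized instrument set and returns a tidy table, the presentation used
#' for each outcome in a two-sample MR study.
#'
#' @param dat Harmonized instrument tibble (at least 3 instruments).
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param seed Integer seed for the bootstraps.
#' @param model IVW model flavour.
#' @return A tibble of class `mr_panel` with one row per method; attribute
#'   `fits` holds the underlying objects.
#' @export
mr_panel <- function(dat, n_boot = 5000, seed = 1, model = "random") {
  dat <- as_instruments(dat)
  fits <- list(
    ivw = mr_ivw(dat, model = model),
    egger = mr_egger(dat),
    weighted_median = mr_weighted_median(dat, n_boot = n_boot, seed = seed),
    simple_mode = mr_mode(dat, weighted = FALSE, n_boot = n_boot, seed = seed + 1),
    weighted_mode = mr_mode(dat, weighted = TRUE, n_boot = n_boot, seed = seed + 2)
  )
  out <- dplyr::bind_rows(
    tidy(fits$ivw),
    tidy(fits$egger$slope),
    tidy(fits$weighted_median),
    tidy(fits$simple_mode),
    tidy(fits$weighted_mode)
  )
  attr(out, "fits") <- fits
  class(out) <- c("mr_panel", class(out))
  out
}

#' Full sensitivity suite for one instrument set
#'
#' Cochran's Q, the MR-Egger intercept test, leave-one-out IVW, and (with at
#' least 4 instruments) MR-PRESSO.
#'
#' @param dat Harmonized instrument tibble.
#' @param seed Seed for MR-PRESSO.
#' @param n_sim MR-PRESSO simulations.
#' @return List with `heterogeneity`, `egger_intercept`, `leave_one_out`,
#'   `presso` (`NULL` when fewer than 4 instruments).
#' @export
mr_sensitivity <- function(dat, seed = 1, n_sim = 5000) {
  dat <- as_instruments(dat)
  egger <- if (nrow(dat) >= 3) mr_egger(dat) else NULL
  list(
    heterogeneity = if (nrow(dat) >= 2) cochran_q(dat) else NULL,
    egger_intercept = if (!is.null(egger)) {
      tibble::tibble(intercept = egger$intercept, se = egger$intercept_se,
                     pvalue = egger$intercept_pvalue)
    } else NULL,
    leave_one_out = if (nrow(dat) >= 3) mr_leave_one_out(dat) else NULL,
    presso = if (nrow(dat) >= 4) mr_presso(dat, n_sim = n_sim, seed = seed) else NULL
  )
}
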