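#' Log approximate Bayes factor for one variant
#'
#' Wakefield-style approximate Bayes factor comparing an association model
#' with effect prior N(0, prior_sd^2) against the null, computed from the
#' summary estimate and its standard error. With `z = beta/se`, `V = se^2`
#' and shrinkage `r = prior_sd^2 / (prior_sd^2 + V)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`. Increasing in `|z|` at fixed
#' `se`; negative at `z = 0`.
#'
#' @param beta,se Summary effect and standard error (`se > 0`), vectorized.
#' @param prior_sd Prior standard deviation of the true effect; 0.15 is the
#'   usual default for quantitative traits, 0.2 for binary (log-odds) traits.
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0) || any(prior_sd <= 0)) {
    stop("se and prior_sd must be positive", call. = FALSE)
  }
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian colocalization of two traits at a locus
#'
#' Tests whether two traits share a single causal variant at a locus using
#' per-variant approximate Bayes factors and the five standard hypotheses:
#' H0 neither trait associated, H1/H2 only trait 1/2 associated, H3 both
#' associated through distinct causal variants, H4 both through one shared
#' variant. Hypothesis sums are accumulated in log space; posteriors are
#' normalized to 1. The locus is called "colocalized" when the H4 posterior
#' exceeds `gate` (default 0.70).
#'
#' @param trait1,trait2 Tibbles of variant associations restricted to the
#'   locus; the variant intersection is analysed (at least 2 shared variants).
#' @param p1,p2 Prior probability a variant is causal for trait 1 / trait 2.
#' @param p12 Prior probability a variant is causal for both.
#' @param gate H4 posterior threshold for the binary call.
#' @param prior_sd1,prior_sd2 Effect-scale priors passed to [log_abf()].
#' @return An object of class `coloc_result`: list with `pp` (named numeric,
#'   H0..H4), `colocalized`, `priors`, `gate`, `n_variants`, and the
#'   per-variant log-ABF tibble.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      gate = 0.70, prior_sd1 = 0.15, prior_sd2 = 0.15) {
  trait1 <- tibble::as_tibble(trait1)
  trait2 <- tibble::as_tibble(trait2)
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) < 2) {
    stop("colocalization needs at least 2 shared variants, got ",
         length(shared), call. = FALSE)
  }
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]

  l1 <- log_abf(t1$beta, t1$se, prior_sd1)
  l2 <- log_abf(t2$beta, t2$se, prior_sd2)

  # log of: sum_j ABF1_j ; sum_j ABF2_j ; sum_j ABF1_j*ABF2_j ;
  # sum_{j != k} ABF1_j*ABF2_k = sum1*sum2 - sum12
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  # log(exp(ls1 + ls2) - exp(ls12)), guarded against cancellation
  cross <- ls1 + ls2
  ls3 <- if (ls12 >= cross) -Inf else cross + log1p(-exp(ls12 - cross))

  lh <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + ls3,
    H4 = log(p12) + ls12
  )
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)

  structure(
    list(
      pp = pp,
      colocalized = unname(pp["H4"] > gate),
      priors = c(p1 = p1, p2 = p2, p12 = p12),
      gate = gate,
      n_variants = length(shared),
      abf = tibble::tibble(variant_id = shared, log_abf1 = l1, log_abf2 = l2)
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "shared variants\n")
  print(round(x$pp, 4))
  cat(sprintf("PP(H4) %s %.2f -> %s\n",
              if (x$colocalized) ">" else "<=", x$gate,
              if (x$colocalized) "colocalized" else "not colocalized"))
  invisible(x)
}

#' @rdname coloc_abf
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @rdname coloc_abf
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(
    pp_h4 = unname(x$pp["H4"]), colocalized = x$colocalized,
    gate = x$gate, n_variants = x$n_variants
  )
}

#' Serialize a colocalization result to JSON
#'
#' @param x A `coloc_result`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_coloc_json <- function(x, path) {
  jsonlite::write_json(
    list(pp = as.list(x$pp), colocalized = x$colocalized,
         priors = as.list(x$priors), gate = x$gate, n_variants = x$n_variants),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
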