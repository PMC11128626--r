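# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# A harmonized instrument tibble from raw vectors.
instruments <- function(bx, by, sx = rep(0.01, length(bx)),
                        sy = rep(0.05, length(by)),
                        ids = sprintf("rs%03d", seq_along(bx))) {
  tibble::tibble(
    variant_id = ids,
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy
  )
}

# Random strong-instrument fixture with true slope theta and no pleiotropy.
random_instruments <- function(j, theta, seed) {
  set.seed(seed)
  gamma <- sample(c(-1, 1), j, TRUE) * runif(j, 0.05, 0.15)
  sx <- runif(j, 0.002, 0.006)
  sy <- runif(j, 0.01, 0.04)
  instruments(
    bx = rnorm(j, gamma, sx),
    by = rnorm(j, theta * gamma, sy),
    sx = sx, sy = sy
  )
}

# A raw variant-association tibble.
assoc_table <- function(n, seed = 1, beta = NULL, se = NULL, pvalue = NULL) {
  set.seed(seed)
  pairs <- matrix(c("A","C","A","G","C","A","C","T","G","A","G","T","T","C","T","G"),
                  ncol = 2, byrow = TRUE)
  idx <- sample(nrow(pairs), n, TRUE)
  se <- se %||% runif(n, 0.005, 0.05)
  beta <- beta %||% rnorm(n, 0, 0.05)
  tibble::tibble(
    variant_id = sprintf("rs%05d", seq_len(n)),
    chromosome = sample(1:22, n, TRUE),
    position = sample.int(1e6, n),
    effect_allele = pairs[idx, 1],
    other_allele = pairs[idx, 2],
    eaf = runif(n, 0.05, 0.95),
    beta = beta, se = se,
    pvalue = pvalue %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300),
    n = 100000L
  )
}

# Weighted least squares through the origin: the independent IVW oracle.
wls_origin_oracle <- function(dat) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = dat,
            weights = 1 / dat$se_outcome^2)
  unname(coef(fit)[1])
}

# Weighted regression with intercept after orienting bx > 0: the Egger oracle.
egger_oracle <- function(dat) {
  flip <- sign(dat$beta_exposure); flip[flip == 0] <- 1
  bx <- dat$beta_exposure * flip
  by <- dat$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / dat$se_outcome^2)
  unname(coef(fit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
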