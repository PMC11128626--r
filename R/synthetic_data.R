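NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulation configuration for two-sample summary statistics
#'
#' Bundles and validates the generator's parameters. Defaults mirror a
#' drug-target mediation study: a biomarker exposure GWAS of 344,182, a
#' mediator GWAS of 484,598, a binary outcome GWAS of 361,194 with case
#' fraction 1597/361194, and true effects theta_em = -0.05 (exposure to
#' mediator), theta_mo = 0.03 (mediator to outcome), theta_direct = -0.0155,
#' so the total effect theta_direct + theta_mo * theta_em is about -0.017.
#'
#' @param n_variants Number of exposure-instrument variants.
#' @param n_mediator_variants Number of mediator-specific instrument variants
#'   (effects on the mediator not running through the exposure, as the
#'   mediator's own GWAS hits would be); defaults to `n_variants`.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 2).
#' @param theta_em,theta_mo,theta_direct True causal effects of the
#'   exposure->mediator->outcome graph.
#' @param pleiotropy `list(type = "none")`, `list(type = "balanced", sd = )`,
#'   or `list(type = "directional", mean = , sd = )`: per-variant direct
#'   effects on the outcome.
#' @param ld_blocks `NULL` (independent variants) or `list(size = , r = )`:
#'   consecutive blocks of that size with exchangeable correlation `r` applied
#'   to the sampling noise of all three traits.
#' @param maf_range Effect-allele frequency range.
#' @param case_fraction Outcome case proportion; scales the outcome SEs by
#'   `1/sqrt(v (1 - v))` (log-odds approximation).
#' @param gamma_range Magnitude range of true per-variant exposure effects
#'   (signs random); the default 0.03-0.08 keeps every instrument strong
#'   (F well above 10) at the default exposure sample size.
#' @param prop_causal Fraction of variants with nonzero exposure effect.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 50,
                       n_mediator_variants = n_variants,
                       n_exposure = 344182,
                       n_mediator = 484598,
                       n_outcome = 361194,
                       theta_em = -0.05,
                       theta_mo = 0.03,
                       theta_direct = -0.0155,
                       pleiotropy = list(type = "none"),
                       ld_blocks = NULL,
                       maf_range = c(0.05, 0.5),
                       case_fraction = 1597 / 361194,
                       gamma_range = c(0.03, 0.08),
                       prop_causal = 1,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_variants >= 1, n_exposure >= 2, n_mediator >= 2, n_outcome >= 2,
            case_fraction > 0, case_fraction < 1,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            prop_causal > 0, prop_causal <= 1)
  if (!pleiotropy$type %in% c("none", "balanced", "directional")) {
    stop("pleiotropy$type must be none, balanced or directional", call. = FALSE)
  }
  if (!is.null(ld_blocks)) {
    stopifnot(ld_blocks$size >= 1, abs(ld_blocks$r) < 1)
  }
  structure(
    list(n_variants = n_variants, n_mediator_variants = n_mediator_variants,
         n_exposure = n_exposure,
         n_mediator = n_mediator, n_outcome = n_outcome,
         theta_em = theta_em, theta_mo = theta_mo, theta_direct = theta_direct,
         pleiotropy = pleiotropy, ld_blocks = ld_blocks,
         maf_range = maf_range, case_fraction = case_fraction,
         gamma_range = gamma_range, prop_causal = prop_causal,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

two_sided_p <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
}

random_alleles <- function(j) {
  idx <- sample(nrow(NONPALINDROMIC_PAIRS), j, replace = TRUE)
  list(effect = NONPALINDROMIC_PAIRS[idx, 1], other = NONPALINDROMIC_PAIRS[idx, 2])
}

# Draw J standard normals with exchangeable within-block correlation.
blocked_noise <- function(j, ld_blocks) {
  if (is.null(ld_blocks)) return(rnorm(j))
  size <- ld_blocks$size
  r <- ld_blocks$r
  out <- numeric(j)
  start <- 1
  while (start <= j) {
    end <- min(start + size - 1, j)
    k <- end - start + 1
    shared <- rnorm(1)
    own <- rnorm(k)
    out[start:end] <- sqrt(r) * shared + sqrt(1 - r) * own
    start <- end + 1
  }
  out
}

block_ld_matrix <- function(ids, ld_blocks) {
  j <- length(ids)
  m <- diag(j)
  if (!is.null(ld_blocks)) {
    start <- 1
    while (start <= j) {
      end <- min(start + ld_blocks$size - 1, j)
      m[start:end, start:end] <- ld_blocks$r
      diag(m)[] <- 1
      start <- end + 1
    }
    diag(m) <- 1
  }
  dimnames(m) <- list(ids, ids)
  m
}

sumstat_table <- function(ids, chrom, pos, alleles, maf, beta, se, n) {
  tibble::tibble(
    variant_id = ids, chromosome = chrom, position = pos,
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = maf, beta = beta, se = se, pvalue = two_sided_p(beta, se), n = n
  )
}

#' Simulate two-sample summary statistics under a known causal graph
#'
#' Draws per-variant summary statistics for an exposure, a mediator and a
#' binary outcome under the graph exposure -> mediator -> outcome with an
#' optional direct path and optional pleiotropy. Two classes of variants are
#' generated, mirroring a two-step design: exposure instruments with true
#' exposure effects `gamma_j` (drawn from a sparse two-sided uniform), and
#' mediator-specific instruments with true mediator effects `delta_j` and no
#' exposure effect, standing in for the mediator's own GWAS hits. Simulation
#' is at the summary level: observed exposure betas are
#' `N(gamma_j, sigma_xj^2)` with `sigma_xj = 1/sqrt(2 maf (1-maf) n)`;
#' mediator betas are centred on `theta_em * gamma_j + delta_j`; outcome
#' betas on `(theta_direct + theta_mo * theta_em) * gamma_j +
#' theta_mo * delta_j + alpha_j` where `alpha_j` is the pleiotropy draw;
#' outcome SEs carry the binary-trait scaling
#' `1/sqrt(case_fraction (1 - case_fraction))`. LD blocks, when configured,
#' correlate the sampling noise blockwise. Every draw is seeded and recorded
#' in the truth object.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_study`: tibbles `exposure`, `mediator`,
#'   `outcome`; `ld` (correlation matrix); `truth` (config plus every latent
#'   draw: `class`, `maf`, `gamma`, `delta`, `alpha`, per-trait true means
#'   and SEs).
#' @export
simulate_two_sample <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  set.seed(config$seed)
  jx <- config$n_variants
  jm <- config$n_mediator_variants
  j <- jx + jm
  cls <- rep(c("exposure", "mediator"), c(jx, jm))
  ids <- sprintf("rs%06d", sample.int(999999, j))
  chrom <- sample(1:22, j, replace = TRUE)
  pos <- sample.int(5e7, j)
  alleles <- random_alleles(j)
  maf <- runif(j, config$maf_range[1], config$maf_range[2])

  draw_effect <- function(k) {
    causal <- runif(k) < config$prop_causal
    ifelse(causal,
           sample(c(-1, 1), k, replace = TRUE) *
             runif(k, config$gamma_range[1], config$gamma_range[2]),
           0)
  }
  gamma <- c(draw_effect(jx), rep(0, jm))
  delta <- c(rep(0, jx), draw_effect(jm))
  alpha <- switch(config$pleiotropy$type,
    none = rep(0, j),
    balanced = rnorm(j, 0, config$pleiotropy$sd),
    directional = rnorm(j, config$pleiotropy$mean, config$pleiotropy$sd)
  )

  het <- 2 * maf * (1 - maf)
  v <- config$case_fraction
  se_x <- 1 / sqrt(het * config$n_exposure)
  se_m <- 1 / sqrt(het * config$n_mediator)
  se_y <- 1 / sqrt(het * config$n_outcome * v * (1 - v))

  mu_x <- gamma
  mu_m <- config$theta_em * gamma + delta
  mu_y <- (config$theta_direct + config$theta_mo * config$theta_em) * gamma +
    config$theta_mo * delta + alpha

  beta_x <- mu_x + se_x * blocked_noise(j, config$ld_blocks)
  beta_m <- mu_m + se_m * blocked_noise(j, config$ld_blocks)
  beta_y <- mu_y + se_y * blocked_noise(j, config$ld_blocks)

  structure(
    list(
      exposure = sumstat_table(ids, chrom, pos, alleles, maf, beta_x, se_x,
                               config$n_exposure),
      mediator = sumstat_table(ids, chrom, pos, alleles, maf, beta_m, se_m,
                               config$n_mediator),
      outcome = sumstat_table(ids, chrom, pos, alleles, maf, beta_y, se_y,
                              config$n_outcome),
      ld = block_ld_matrix(ids, config$ld_blocks),
      truth = list(config = config, class = cls, maf = maf,
                   gamma = gamma, delta = delta, alpha = alpha,
                   mu_exposure = mu_x, mu_mediator = mu_m, mu_outcome = mu_y,
                   se_exposure = se_x, se_mediator = se_m, se_outcome = se_y,
                   theta_total = config$theta_direct +
                     config$theta_mo * config$theta_em)
    ),
    class = "synthetic_study"
  )
}

#' Harmonized instrument sets for the three legs of a synthetic study
#'
#' Convenience wrapper pairing the simulated tables into the exposure->
#' mediator, exposure->outcome, and mediator->outcome harmonized sets used by
#' the estimators. Exposure legs use the exposure-instrument variants; the
#' mediator leg uses the mediator-specific variants, as a two-step design
#' requires.
#'
#' @param study A `synthetic_study`.
#' @return List of three harmonized tibbles: `exposure_mediator`,
#'   `exposure_outcome`, `mediator_outcome`.
#' @export
harmonize_study <- function(study) {
  ex_ids <- study$exposure$variant_id[study$truth$class == "exposure"]
  md_ids <- study$exposure$variant_id[study$truth$class == "mediator"]
  sub <- function(tab, ids) tab[tab$variant_id %in% ids, , drop = FALSE]
  list(
    exposure_mediator = harmonize_effects(sub(study$exposure, ex_ids),
                                          sub(study$mediator, ex_ids)),
    exposure_outcome = harmonize_effects(sub(study$exposure, ex_ids),
                                         sub(study$outcome, ex_ids)),
    mediator_outcome = harmonize_effects(sub(study$mediator, md_ids),
                                         sub(study$outcome, md_ids))
  )
}

#' Simulate a cis locus for colocalization
#'
#' Generates summary statistics for two traits over one locus with a single
#' causal variant per trait: z-scores are standard normal noise plus
#' `signal_z` at the causal index, which is shared between traits
#' (`shared = TRUE`) or placed at distinct variants (`shared = FALSE`).
#'
#' @param n_variants Locus size (at least 10).
#' @param shared Do the two traits share the causal variant?
#' @param signal_z Causal-variant z-score magnitude.
#' @param seed Integer seed.
#' @param n_sample Per-trait GWAS sample size used for the SEs.
#' @param maf_range Allele-frequency range.
#' @return List with tibbles `trait1`, `trait2` and `truth` (causal indices).
#' @export
simulate_coloc_locus <- function(n_variants = 100, shared = TRUE, signal_z = 8,
                                 seed = 1, n_sample = 30000,
                                 maf_range = c(0.1, 0.5)) {
  stopifnot(n_variants >= 10)
  set.seed(seed)
  ids <- sprintf("rsloc%05d", seq_len(n_variants))
  alleles <- random_alleles(n_variants)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_sample)

  i1 <- sample.int(n_variants, 1)
  i2 <- if (shared) i1 else sample(setdiff(seq_len(n_variants), i1), 1)
  z1 <- rnorm(n_variants); z1[i1] <- z1[i1] + signal_z
  z2 <- rnorm(n_variants); z2[i2] <- z2[i2] + signal_z

  mk <- function(z) sumstat_table(ids, chrom = 16, pos = seq_len(n_variants) * 500,
                                  alleles, maf, beta = z * se, se = se,
                                  n = n_sample)
  list(trait1 = mk(z1), trait2 = mk(z2),
       truth = list(index1 = i1, index2 = i2, shared = shared,
                    signal_z = signal_z, seed = seed))
}

#' Fixture mirroring the study's instrument counts
#'
#' Builds a deterministic synthetic study engineered so the selection
#' pipeline reproduces the instrument counts of a drug-target mediation
#' study: the mediator GWAS contains exactly 13 genome-wide-significant
#' variants of which 4 are removed by stringent clumping (r-squared 0.001)
#' and 2 by confounder screening (lipid and coronary-artery-disease
#' annotations), leaving 7 instruments; the exposure cis locus yields exactly
#' 6 instruments after the locus-scale filter (p < 1e-4), permissive clumping
#' (r-squared 0.8), and the F >= 10 screen; and a locus expression table
#' shares its causal signals with the exposure so the colocalization gate
#' passes. All F statistics exceed 10 by construction.
#'
#' @param seed Integer seed (perturbs only the cosmetic noise; the counts are
#'   fixed by construction).
#' @param theta_em,theta_mo,theta_direct True effects used for the causal
#'   legs (defaults as in [sim_config()]).
#' @return List of class `synthetic_fixture`: tibbles `exposure`, `mediator`,
#'   `outcome`, `expression`; `ld` matrix; `annotations` tibble; `truth`.
#' @export
make_study_fixture <- function(seed = 1, theta_em = -0.05,
                                      theta_mo = 0.03, theta_direct = -0.0155) {
  set.seed(seed)
  n_exposure <- 344182
  n_mediator <- 484598
  n_outcome <- 361194
  v <- 1597 / n_outcome

  ## --- mediator (VTE-like) GWAS: 40 variants, 13 significant ---
  n_vte <- 40
  vte_ids <- sprintf("rsvte%03d", seq_len(n_vte))
  z_sig <- seq(12, 6, length.out = 13)           # all beyond the 5e-8 z of 5.45
  z_null <- pmin(abs(rnorm(n_vte - 13)), 3.5)    # comfortably non-significant
  z_vte <- c(z_sig, z_null)
  maf_vte <- runif(n_vte, 0.1, 0.4)
  se_m <- 1 / sqrt(2 * maf_vte * (1 - maf_vte) * n_mediator)
  beta_m_vte <- z_vte * se_m * sample(c(-1, 1), n_vte, replace = TRUE)

  # clumping casualties: variants 10..13 correlated (r = 0.9) with 1..4
  ld_ids <- vte_ids
  ld <- diag(n_vte)
  for (k in 1:4) {
    ld[k, 9 + k] <- 0.9
    ld[9 + k, k] <- 0.9
  }

  # confounder casualties: 2 of the 9 surviving index variants
  annotations <- tibble::tibble(
    variant_id = c(vte_ids[5], vte_ids[6], vte_ids[7], vte_ids[20]),
    trait = c("Low-density lipoprotein", "Coronary artery disease",
              "height", "body mass index")
  )

  ## --- exposure (biomarker) cis locus: 20 variants, 8 significant, 6 kept ---
  n_cis <- 20
  cis_ids <- sprintf("rscis%03d", seq_len(n_cis))
  z_cis <- c(seq(9, 6.5, length.out = 6),  # the 6 intended instruments
             6.2, 6.0,                     # 2 correlated shadows, clumped away
             pmin(abs(rnorm(n_cis - 8)), 3))
  maf_cis <- runif(n_cis, 0.1, 0.4)
  se_x_cis <- 1 / sqrt(2 * maf_cis * (1 - maf_cis) * n_exposure)
  beta_x_cis <- z_cis * se_x_cis * sample(c(-1, 1), n_cis, replace = TRUE)

  all_ids <- c(cis_ids, vte_ids)
  n_all <- length(all_ids)
  ld_all <- diag(n_all)
  ld_all[n_cis + seq_len(n_vte), n_cis + seq_len(n_vte)] <- ld
  # shadows 7 and 8 in near-perfect LD with instruments 1 and 2
  ld_all[7, 1] <- ld_all[1, 7] <- 0.95
  ld_all[8, 2] <- ld_all[2, 8] <- 0.95
  dimnames(ld_all) <- list(all_ids, all_ids)

  alleles <- random_alleles(n_all)
  maf <- c(maf_cis, maf_vte)
  chrom <- c(rep(16, n_cis), rep(1, n_vte))
  pos <- c(seq_len(n_cis) * 400, seq_len(n_vte) * 1e5)
  het <- 2 * maf * (1 - maf)

  se_x <- 1 / sqrt(het * n_exposure)
  se_mall <- 1 / sqrt(het * n_mediator)
  se_y <- 1 / sqrt(het * n_outcome * v * (1 - v))

  # true exposure effects: cis betas for the locus, none elsewhere
  gamma <- c(beta_x_cis, rep(0, n_vte))
  # true mediator effects: theta_em*gamma for cis variants, own signals for VTE
  mu_m <- theta_em * gamma
  mu_m[n_cis + seq_len(n_vte)] <- beta_m_vte
  mu_y <- (theta_direct + theta_mo * theta_em) * gamma
  mu_y[n_cis + seq_len(n_vte)] <- theta_mo * beta_m_vte

  beta_x <- gamma + se_x * rnorm(n_all) * 0.1
  beta_x[seq_len(n_cis)] <- beta_x_cis       # keep locus significance exact
  beta_m <- mu_m + se_mall * rnorm(n_all) * 0.1
  beta_m[n_cis + seq_len(n_vte)] <- beta_m_vte
  beta_y <- mu_y + se_y * rnorm(n_all) * 0.1

  exposure <- sumstat_table(all_ids, chrom, pos, alleles, maf, beta_x, se_x,
                            n_exposure)
  mediator <- sumstat_table(all_ids, chrom, pos, alleles, maf, beta_m, se_mall,
                            n_mediator)
  outcome <- sumstat_table(all_ids, chrom, pos, alleles, maf, beta_y, se_y,
                           n_outcome)

  # locus expression trait sharing its causal signals with the exposure
  z_expr <- z_cis + rnorm(n_cis) * 0.2
  n_expr <- 31684
  se_expr <- 1 / sqrt(2 * maf_cis * (1 - maf_cis) * n_expr)
  expr_sign <- sign(beta_x_cis)
  expression <- sumstat_table(cis_ids, 16, seq_len(n_cis) * 400,
                              lapply(alleles, function(a) a[seq_len(n_cis)]),
                              maf_cis, z_expr * se_expr * expr_sign, se_expr,
                              n_expr)

  structure(
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         expression = expression, ld = ld_all, annotations = annotations,
         truth = list(seed = seed, theta_em = theta_em, theta_mo = theta_mo,
                      theta_direct = theta_direct,
                      n_significant_mediator = 13L,
                      n_mediator_instruments = 7L,
                      n_cis_instruments = 6L,
                      cis_instrument_ids = cis_ids[1:6],
                      mediator_instrument_ids = vte_ids[c(1:4, 7:9)])),
    class = "synthetic_fixture"
  )
}

#' Write a synthetic study's tables to a directory
#'
#' Emits the same TSV dialect the readers consume, the truth object as JSON,
#' and the configuration as YAML.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- default_column_map()
  for (nm in c("exposure", "mediator", "outcome")) {
    tab <- study[[nm]]
    names(tab) <- map[names(tab)]
    readr::write_tsv(tab, file.path(dir, paste0(nm, ".tsv")))
  }
  truth <- study$truth
  cfg <- truth$config
  truth$config <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
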