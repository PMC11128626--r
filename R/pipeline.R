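#' Analysis configuration for a full mediation MR study
#'
#' Validates and fills the thresholds and options driving [run_study()].
#' Inputs are either file paths (TSV summary statistics, LD matrix,
#' annotations) or in-memory tables/fixtures supplied through `data`.
#'
#' @param data Optional list with tibbles `exposure`, `mediator`, `outcome`,
#'   and optionally `expression`, `ld`, `annotations`, plus optional
#'   `secondary_outcomes` (named list of outcome tables). Takes precedence
#'   over paths.
#' @param paths Optional named list of file paths (`exposure`, `mediator`,
#'   `outcome`, `expression`, `ld`, `annotations`).
#' @param exposure_pvalue Locus-scale significance threshold for exposure
#'   instruments (default 1e-4).
#' @param exposure_r2 Permissive clumping threshold at the cis locus
#'   (default 0.8).
#' @param mediator_pvalue Genome-wide threshold for mediator instruments
#'   (default 5e-8).
#' @param mediator_r2 Stringent clumping threshold (default 0.001).
#' @param f_min Weak-instrument F cutoff (default 10).
#' @param coloc_gate H4 posterior required to trust the exposure instruments
#'   (default 0.70); applied only when an expression table is available.
#' @param blocked_traits Confounder annotations that disqualify a mediator
#'   instrument.
#' @param palindrome_policy Passed to [harmonize_effects()].
#' @param interval_method,n_draws Mediation interval options.
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param n_sim MR-PRESSO simulations.
#' @param seed Master seed for every stochastic component.
#' @param out_dir Optional directory to write report files into.
#' @return List of class `analysis_config`.
#' @export
study_config <- function(data = NULL, paths = NULL,
                         exposure_pvalue = 1e-4, exposure_r2 = 0.8,
                         mediator_pvalue = 5e-8, mediator_r2 = 0.001,
                         f_min = 10, coloc_gate = 0.70,
                         blocked_traits = c("Low-density lipoprotein",
                                            "Coronary artery disease"),
                         palindrome_policy = "drop",
                         interval_method = "montecarlo", n_draws = 1e5,
                         n_boot = 5000, n_sim = 5000, seed = 1,
                         out_dir = NULL) {
  stopifnot(exposure_pvalue > 0, exposure_pvalue < 1,
            mediator_pvalue > 0, mediator_pvalue < 1,
            exposure_r2 > 0, exposure_r2 <= 1,
            mediator_r2 > 0, mediator_r2 <= 1,
            coloc_gate > 0, coloc_gate < 1,
            is.null(f_min) || f_min >= 0)
  if (is.null(data) && is.null(paths)) {
    stop("supply either in-memory data or file paths", call. = FALSE)
  }
  structure(
    list(data = data, paths = paths,
         exposure_pvalue = exposure_pvalue, exposure_r2 = exposure_r2,
         mediator_pvalue = mediator_pvalue, mediator_r2 = mediator_r2,
         f_min = f_min, coloc_gate = coloc_gate,
         blocked_traits = blocked_traits,
         palindrome_policy = palindrome_policy,
         interval_method = interval_method, n_draws = n_draws,
         n_boot = n_boot, n_sim = n_sim, seed = as.integer(seed),
         out_dir = out_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [study_config()]
#'   (file paths under a `paths:` mapping).
#' @param seed Optional seed override.
#' @return An `analysis_config`.
#' @export
read_study_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(study_config, y)
}

load_study_inputs <- function(config) {
  if (!is.null(config$data)) return(config$data)
  p <- config$paths
  dat <- list(
    exposure = read_summary_stats(p$exposure),
    mediator = read_summary_stats(p$mediator),
    outcome = read_summary_stats(p$outcome)
  )
  if (!is.null(p$expression)) dat$expression <- read_summary_stats(p$expression)
  if (!is.null(p$ld)) dat$ld <- read_ld_matrix(p$ld)
  if (!is.null(p$annotations)) {
    dat$annotations <- readr::read_tsv(p$annotations, show_col_types = FALSE)
  }
  dat
}

#' Run the full mediation MR study
#'
#' Orchestrates the design end to end, in order: exposure (drug-target)
#' instrument selection at the cis locus with an optional colocalization
#' gate; mediator instrument selection (genome-wide significance, stringent
#' clumping, weak-instrument and confounder screens); the five-estimator
#' panel with sensitivity suite for each causal leg (exposure->outcome,
#' exposure->mediator, mediator->outcome); two-step mediation; and the same
#' estimator panel for any secondary outcomes. A failed stage is recorded
#' with its cause and dependent stages are skipped. When the colocalization
#' gate fails, the exposure instruments are not used: the total-effect,
#' exposure->mediator and mediation stages are skipped and the report says
#' "not colocalized".
#'
#' @param config An `analysis_config` from [study_config()] /
#'   [read_study_config()], or a YAML path.
#' @param seed Optional seed override.
#' @return Object of class `study_report`: named list with `coloc`,
#'   `exposure_instruments`, `mediator_instruments`, `estimates` (tibble,
#'   all legs and methods), `sensitivity`, `leave_one_out`, `mediation`
#'   (a `mediation_result` or `NULL`), `secondary`, `stages` (tibble of
#'   stage status), and `provenance`.
#' @export
run_study <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_study_config(config, seed = seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dat <- load_study_inputs(config)

  stages <- tibble::tibble(stage = character(), status = character(),
                           detail = character())
  note <- function(stage, status, detail = "") {
    stages <<- dplyr::add_row(stages, stage = stage, status = status,
                              detail = detail)
  }
  try_stage <- function(stage, expr) {
    tryCatch({
      out <- expr
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  ## exposure (cis) instrument selection
  exp_inst <- try_stage("exposure_selection", select_instruments(
    dat$exposure, pvalue_threshold = config$exposure_pvalue,
    ld = dat$ld, r2_threshold = config$exposure_r2, f_min = config$f_min
  ))

  ## colocalization gate on the exposure locus
  coloc <- NULL
  gate_open <- TRUE
  if (!is.null(dat$expression)) {
    locus <- dat$exposure[dat$exposure$variant_id %in% dat$expression$variant_id, ]
    coloc <- try_stage("colocalization", coloc_abf(
      dat$expression, locus, gate = config$coloc_gate
    ))
    if (!is.null(coloc) && !coloc$colocalized) {
      gate_open <- FALSE
      note("coloc_gate", "halted", "not colocalized: exposure instruments not used")
    } else if (!is.null(coloc)) {
      note("coloc_gate", "ok", "colocalized")
    }
  }

  ## mediator instrument selection
  med_inst <- try_stage("mediator_selection", select_instruments(
    dat$mediator, pvalue_threshold = config$mediator_pvalue,
    ld = dat$ld, r2_threshold = config$mediator_r2, f_min = config$f_min,
    annotations = dat$annotations, blocked_traits = config$blocked_traits
  ))

  harmon <- function(inst, outcome_tab) {
    harmonized_kept(harmonize_effects(
      inst, outcome_tab, palindrome_policy = config$palindrome_policy))
  }

  estimates <- list()
  sensitivity <- list()
  loo <- list()
  legs <- list()

  fit_leg <- function(label, inst, outcome_tab, seed_off) {
    h <- harmon(inst, outcome_tab)
    panel <- mr_panel(h, n_boot = config$n_boot, seed = config$seed + seed_off)
    sens <- mr_sensitivity(h, seed = config$seed + seed_off + 10,
                           n_sim = config$n_sim)
    list(harmonized = h, panel = panel, sens = sens)
  }

  if (!is.null(exp_inst) && gate_open) {
    leg <- try_stage("mr_total_exposure_outcome",
                     fit_leg("total", exp_inst, dat$outcome, 0))
    if (!is.null(leg)) {
      legs$total <- leg
      estimates$total <- dplyr::mutate(leg$panel, leg = "exposure->outcome",
                                       .before = 1)
      sensitivity$total <- leg$sens
      loo$total <- leg$sens$leave_one_out
    }
    leg <- try_stage("mr_exposure_mediator",
                     fit_leg("direct_a", exp_inst, dat$mediator, 100))
    if (!is.null(leg)) {
      legs$direct_a <- leg
      estimates$direct_a <- dplyr::mutate(leg$panel, leg = "exposure->mediator",
                                          .before = 1)
      sensitivity$direct_a <- leg$sens
      loo$direct_a <- leg$sens$leave_one_out
    }
  } else if (!gate_open) {
    note("mr_total_exposure_outcome", "skipped", "coloc gate closed")
    note("mr_exposure_mediator", "skipped", "coloc gate closed")
  }

  if (!is.null(med_inst)) {
    leg <- try_stage("mr_mediator_outcome",
                     fit_leg("direct_b", med_inst, dat$outcome, 200))
    if (!is.null(leg)) {
      legs$direct_b <- leg
      estimates$direct_b <- dplyr::mutate(leg$panel, leg = "mediator->outcome",
                                          .before = 1)
      sensitivity$direct_b <- leg$sens
      loo$direct_b <- leg$sens$leave_one_out
    }
  }

  mediation <- NULL
  if (!is.null(legs$total) && !is.null(legs$direct_a) && !is.null(legs$direct_b)) {
    mediation <- try_stage("mediation", run_two_step(
      legs$total$harmonized, legs$direct_a$harmonized, legs$direct_b$harmonized,
      interval_method = config$interval_method, n_draws = config$n_draws,
      seed = config$seed + 300, sensitivity = FALSE
    ))
  } else {
    note("mediation", "skipped", "missing an upstream leg")
  }

  secondary <- list()
  if (!is.null(config$data$secondary_outcomes) && !is.null(exp_inst) && gate_open) {
    for (nm in names(config$data$secondary_outcomes)) {
      leg <- try_stage(paste0("mr_secondary_", nm),
                       fit_leg(nm, exp_inst, config$data$secondary_outcomes[[nm]],
                               400 + match(nm, names(config$data$secondary_outcomes))))
      if (!is.null(leg)) {
        secondary[[nm]] <- dplyr::mutate(leg$panel, leg = nm, .before = 1)
      }
    }
  }

  report <- structure(
    list(
      coloc = coloc,
      exposure_instruments = exp_inst,
      mediator_instruments = med_inst,
      estimates = dplyr::bind_rows(estimates),
      sensitivity = sensitivity,
      leave_one_out = loo,
      mediation = mediation,
      secondary = dplyr::bind_rows(secondary),
      stages = stages,
      provenance = list(config = config[setdiff(names(config), "data")],
                        seed = config$seed,
                        package_version = as.character(utils::packageVersion("mrmediate")))
    ),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Mediation MR study report\n")
  print(x$stages, n = Inf)
  if (nrow(x$estimates) > 0) {
    cat("\nEstimates:\n")
    print(dplyr::select(x$estimates, "leg", "method", "beta", "se", "pvalue",
                        "or", "n_variants"), n = Inf)
  }
  if (!is.null(x$mediation)) {
    cat("\n")
    print(x$mediation)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `estimates.tsv`, `leave_one_out.tsv`, `mediation.tsv`, `stages.tsv`,
#' `coloc.json`, selection logs, and `report.json` (machine-readable summary)
#' under `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(report$estimates) > 0) {
    readr::write_tsv(report$estimates, file.path(dir, "estimates.tsv"))
  }
  if (length(report$leave_one_out) > 0) {
    readr::write_tsv(
      dplyr::bind_rows(report$leave_one_out, .id = "leg"),
      file.path(dir, "leave_one_out.tsv"))
  }
  if (!is.null(report$mediation)) {
    write_mediation_table(report$mediation, file.path(dir, "mediation.tsv"))
  }
  readr::write_tsv(report$stages, file.path(dir, "stages.tsv"))
  if (!is.null(report$coloc)) {
    write_coloc_json(report$coloc, file.path(dir, "coloc.json"))
  }
  for (nm in c("exposure_instruments", "mediator_instruments")) {
    if (!is.null(report[[nm]])) {
      write_selection_log(report[[nm]], file.path(dir, paste0(nm, "_log.json")))
    }
  }
  summary <- list(
    stages = report$stages,
    seed = report$provenance$seed,
    mediation = if (!is.null(report$mediation)) tidy(report$mediation) else NULL
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
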