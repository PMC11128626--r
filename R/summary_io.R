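#' @importFrom rlang .data %||%
#' @importFrom stats pnorm qnorm pchisq rnorm runif quantile sd mad setNames
#' @importFrom utils head
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Default column mapping matching IEU OpenGWAS export headers.
default_column_map <- function() {
  c(
    variant_id = "SNP", chromosome = "chr", position = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval",
    n = "samplesize"
  )
}

#' Read and validate a GWAS summary-statistic table
#'
#' Reads a tab-separated table of per-variant associations, renames columns
#' according to `column_map`, normalizes alleles to upper case, and drops rows
#' that violate the per-variant invariants (non-ACGT or identical alleles,
#' `se <= 0`, p-value outside (0, 1], allele frequency outside (0, 1)).
#' Dropped rows are counted per reason in the `"drop_log"` attribute.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping the canonical field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`) to the file's column headers. Defaults
#'   to the IEU OpenGWAS export headers (`SNP`, `chr`, `pos`, ...). `eaf`,
#'   `n`, `chromosome` and `position` are optional; the rest are mandatory.
#' @return A tibble of validated variant associations with attribute
#'   `drop_log` (a tibble of reason / n dropped).
#' @export
read_summary_stats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    stop("summary-statistic file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("empty summary-statistic table: ", path, call. = FALSE)

  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  map <- column_map
  missing_map <- setdiff(mandatory, names(map))
  if (length(missing_map) > 0) {
    stop("column_map lacks mandatory fields: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unname(map[mandatory]), names(raw))
  if (length(absent) > 0) {
    stop("mandatory columns missing from ", path, ": ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  map <- map[map %in% names(raw)]
  dat <- tibble::as_tibble(raw[, unname(map)])
  names(dat) <- names(map)
  validate_associations(dat)
}

#' Validate a tibble of variant associations
#'
#' Applies the invariants used by [read_summary_stats()] to an in-memory table:
#' alleles are upper-cased single nucleotides and differ, `se > 0`, p-value in
#' (0, 1], and any `eaf` strictly inside (0, 1). Violating rows are dropped and
#' counted in the returned tibble's `drop_log` attribute.
#'
#' @param dat A data frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`.
#' @return The cleaned tibble with a `drop_log` attribute.
#' @export
validate_associations <- function(dat) {
  dat <- tibble::as_tibble(dat)
  dat$effect_allele <- toupper(as.character(dat$effect_allele))
  dat$other_allele <- toupper(as.character(dat$other_allele))

  bad_allele <- !(dat$effect_allele %in% NUCLEOTIDES) |
    !(dat$other_allele %in% NUCLEOTIDES) |
    dat$effect_allele == dat$other_allele
  bad_se <- !is.finite(dat$se) | dat$se <= 0
  bad_p <- !is.finite(dat$pvalue) | dat$pvalue <= 0 | dat$pvalue > 1
  bad_beta <- !is.finite(dat$beta)
  bad_eaf <- if ("eaf" %in% names(dat)) {
    !is.na(dat$eaf) & (dat$eaf <= 0 | dat$eaf >= 1)
  } else {
    rep(FALSE, nrow(dat))
  }

  drop_log <- tibble::tibble(
    reason = c("invalid_alleles", "nonpositive_se", "pvalue_out_of_range",
               "nonfinite_beta", "eaf_out_of_range"),
    n_dropped = c(sum(bad_allele), sum(bad_se & !bad_allele),
                  sum(bad_p & !bad_allele & !bad_se),
                  sum(bad_beta & !bad_allele & !bad_se & !bad_p),
                  sum(bad_eaf & !bad_allele & !bad_se & !bad_p & !bad_beta))
  )
  keep <- !(bad_allele | bad_se | bad_p | bad_beta | bad_eaf)
  out <- dat[keep, , drop = FALSE]
  attr(out, "drop_log") <- drop_log
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele, the standard
#' two-sample convention. For each variant present in both tables the outcome
#' alleles are compared with the exposure alleles directly and after strand
#' complementing; swapped orientations flip the outcome beta sign and replace
#' `eaf` by `1 - eaf`. Palindromic variants (A/T or C/G) cannot be resolved by
#' complementing and are handled per `palindrome_policy`: `"drop"` removes
#' them; `"infer"` orients them by comparing allele frequencies, dropping any
#' variant whose frequency (either study) falls inside the ambiguity window or
#' is missing. Variants with irreconcilable allele sets are dropped, never
#' silently kept.
#'
#' @param exposure,outcome Tibbles of variant associations (as returned by
#'   [read_summary_stats()] or [validate_associations()]).
#' @param palindrome_policy `"drop"` or `"infer"`.
#' @param ambiguity_window Frequency window (on either study's eaf) inside
#'   which a palindromic variant is considered unorientable under `"infer"`.
#' @return A tibble with one row per shared variant: `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf`, `pvalue_exposure`,
#'   `palindromic`, and `action` in `{"kept", "flipped", "dropped"}`.
#'   Rows with `action == "dropped"` carry a `drop_reason`. Attribute
#'   `drop_log` tabulates drops (including variants absent from one side).
#' @export
harmonize_effects <- function(exposure, outcome,
                              palindrome_policy = c("drop", "infer"),
                              ambiguity_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop("no shared variants between exposure and outcome tables", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  eaf_ex <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))
  eaf_ou <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))

  n <- length(shared)
  action <- character(n)
  reason <- rep(NA_character_, n)
  beta_out <- ou$beta
  eaf_out <- eaf_ou
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal[i]) {
      # complementing is uninformative; orientation decided by policy
      same <- (ea_y == ea_x && oa_y == oa_x)
      swapped <- (ea_y == oa_x && oa_y == ea_x)
      if (!same && !swapped) {
        action[i] <- "dropped"; reason[i] <- "irreconcilable_alleles"; next
      }
      if (palindrome_policy == "drop") {
        action[i] <- "dropped"; reason[i] <- "palindromic_policy_drop"; next
      }
      if (is.na(eaf_ex[i]) || is.na(eaf_ou[i])) {
        action[i] <- "dropped"; reason[i] <- "palindromic_missing_eaf"; next
      }
      f_x <- eaf_ex[i]
      # frequency of the exposure effect allele as reported by the outcome study
      f_y <- if (same) eaf_ou[i] else 1 - eaf_ou[i]
      ambiguous <- function(f) f >= ambiguity_window[1] && f <= ambiguity_window[2]
      if (ambiguous(f_x) || ambiguous(f_y)) {
        action[i] <- "dropped"; reason[i] <- "palindromic_ambiguous_eaf"; next
      }
      concordant <- (f_x - 0.5) * (f_y - 0.5) > 0
      if (same) {
        if (concordant) {
          action[i] <- "kept"
        } else {
          # outcome study reported the complementary strand's allele
          action[i] <- "flipped"; beta_out[i] <- -beta_out[i]
          eaf_out[i] <- 1 - eaf_out[i]
        }
      } else {
        if (concordant) {
          # swapped labels but frequency says same allele: strand flip + swap
          action[i] <- "kept"; eaf_out[i] <- 1 - eaf_out[i]
        } else {
          action[i] <- "flipped"; beta_out[i] <- -beta_out[i]
        }
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action[i] <- "flipped"; beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else if (COMPLEMENT[ea_y] == ea_x && COMPLEMENT[oa_y] == oa_x) {
      action[i] <- "kept"
    } else if (COMPLEMENT[ea_y] == oa_x && COMPLEMENT[oa_y] == ea_x) {
      action[i] <- "flipped"; beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      action[i] <- "dropped"; reason[i] <- "irreconcilable_alleles"
    }
  }

  out <- tibble::tibble(
    variant_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = beta_out,
    se_outcome = ou$se,
    eaf = eaf_ex,
    pvalue_exposure = ex$pvalue,
    palindromic = pal,
    action = action,
    drop_reason = reason
  )

  absent <- tibble::tibble(
    reason = c("absent_from_outcome", "absent_from_exposure"),
    n_dropped = c(sum(!exposure$variant_id %in% shared),
                  sum(!outcome$variant_id %in% shared))
  )
  drops <- dplyr::count(dplyr::filter(out, .data$action == "dropped"),
                        reason = .data$drop_reason, name = "n_dropped")
  attr(out, "drop_log") <- dplyr::bind_rows(absent, drops)
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' Keep only usable harmonized instruments
#'
#' @param dat Output of [harmonize_effects()].
#' @return The rows with `action != "dropped"`.
#' @export
harmonized_kept <- function(dat) {
  dplyr::filter(tibble::as_tibble(dat), .data$action != "dropped")
}

# Internal: accept harmonized tibbles in MR functions, silently excluding
# dropped rows, and check required columns.
as_instruments <- function(dat) {
  dat <- tibble::as_tibble(dat)
  req <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(req, names(dat))
  if (length(miss) > 0) {
    stop("instrument table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("action" %in% names(dat)) dat <- dat[dat$action != "dropped", , drop = FALSE]
  if (any(dat$se_exposure <= 0) || any(dat$se_outcome <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  dat
}

#' Write a harmonized instrument table to TSV
#'
#' @param dat Harmonized tibble.
#' @param path Output file.
#' @param drop_log_path Optional JSON path for the drop log.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(dat, path, drop_log_path = NULL) {
  readr::write_tsv(tibble::as_tibble(dat), path)
  if (!is.null(drop_log_path)) {
    log <- attr(dat, "drop_log") %||% tibble::tibble()
    jsonlite::write_json(log, drop_log_path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}
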