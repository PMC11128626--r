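#' Filter associations by p-value
#'
#' Keeps exactly the records with `pvalue < threshold`, preserving input
#' order. Genome-wide significance (5e-8) is the usual threshold for
#' biobank-scale traits; locus-scale instrument discovery (e.g. cis variants
#' validated through a downstream biomarker) commonly uses 1e-4.
#'
#' @param dat Tibble with a `pvalue` column.
#' @param threshold P-value cutoff in (0, 1).
#' @return The filtered tibble.
#' @export
filter_by_pvalue <- function(dat, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  dat <- tibble::as_tibble(dat)
  dat[dat$pvalue < threshold, , drop = FALSE]
}

#' Per-variant instrument-strength F statistic
#'
#' Computed as the squared z-score, `(beta/se)^2`, which needs only the
#' printed summary columns. The alternative `(n-2) R^2 / (1 - R^2)` form is
#' available when allele frequency and sample size are known.
#'
#' @param beta,se Numeric vectors; `se` must be positive.
#' @param method `"z2"` (default) or `"r2"`.
#' @param eaf,n Required for `method = "r2"`.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se, method = c("z2", "r2"), eaf = NULL, n = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("se must be positive and finite", call. = FALSE)
  }
  if (method == "z2") {
    return((beta / se)^2)
  }
  if (is.null(eaf) || is.null(n)) {
    stop("method = 'r2' requires eaf and n", call. = FALSE)
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2 /
    (2 * eaf * (1 - eaf) * beta^2 + 2 * eaf * (1 - eaf) * n * se^2)
  (n - 2) * r2 / (1 - r2)
}

#' Read a square LD correlation matrix from TSV
#'
#' Expects a header row of variant IDs and a first column of variant IDs;
#' entries are pairwise correlations r in [-1, 1].
#'
#' @param path TSV file.
#' @return A named square matrix.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(r) {
  if (is.null(rownames(r)) || is.null(colnames(r))) {
    stop("LD matrix must carry variant IDs as dimnames", call. = FALSE)
  }
  if (nrow(r) != ncol(r) || !isTRUE(all.equal(unname(r), unname(t(r)), tolerance = 1e-8))) {
    stop("LD matrix must be square and symmetric", call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-8)) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  r
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index variant and discards all remaining variants whose squared correlation
#' with it exceeds `r2_threshold`. Ties in p-value are broken by `variant_id`,
#' making the survivor set deterministic and independent of input order. The
#' returned set is mutually below threshold.
#'
#' @param dat Tibble with `variant_id` and `pvalue`.
#' @param ld Square correlation matrix (r, not r-squared) with variant IDs as
#'   dimnames. Variants absent from the matrix are an error. If `NULL`,
#'   variants are assumed uncorrelated and all are retained.
#' @param r2_threshold Squared-correlation cutoff in (0, 1].
#' @return The retained rows, ordered by p-value; attribute `clump_log` lists
#'   each removed variant and the index variant that removed it.
#' @export
ld_clump <- function(dat, ld, r2_threshold) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  dat <- tibble::as_tibble(dat)
  if (nrow(dat) == 0) return(dat)
  if (is.null(ld)) {
    attr(dat, "clump_log") <- tibble::tibble(variant_id = character(),
                                             index_variant = character())
    return(dat)
  }
  missing <- setdiff(dat$variant_id, rownames(ld))
  if (length(missing) > 0) {
    stop("variants missing from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(dat$pvalue, dat$variant_id)
  queue <- dat$variant_id[ord]
  kept <- character(0)
  removed <- tibble::tibble(variant_id = character(), index_variant = character())
  while (length(queue) > 0) {
    idx <- queue[1]
    kept <- c(kept, idx)
    queue <- queue[-1]
    if (length(queue) > 0) {
      r2 <- ld[idx, queue]^2
      gone <- queue[r2 > r2_threshold]
      if (length(gone) > 0) {
        removed <- dplyr::bind_rows(removed,
          tibble::tibble(variant_id = gone, index_variant = idx))
      }
      queue <- queue[r2 <= r2_threshold]
    }
  }
  out <- dat[match(kept, dat$variant_id), , drop = FALSE]
  attr(out, "clump_log") <- removed
  out
}

#' Remove variants annotated with confounder traits
#'
#' Screens instruments against a local variant-to-trait annotation table (a
#' desk replacement for a PhenoScanner lookup) and removes any variant
#' annotated with a blocked trait, e.g. low-density lipoprotein or coronary
#' artery disease when the outcome is cardiac death.
#'
#' @param dat Tibble with `variant_id`.
#' @param annotations Tibble with columns `variant_id` and `trait` (zero or
#'   more rows per variant).
#' @param blocked_traits Character vector of trait labels (matched
#'   case-insensitively).
#' @return Retained rows; attribute `screen_log` lists removed variants with
#'   the triggering trait.
#' @export
screen_confounders <- function(dat, annotations, blocked_traits) {
  dat <- tibble::as_tibble(dat)
  annotations <- tibble::as_tibble(annotations)
  blocked <- tolower(trimws(blocked_traits))
  hits <- dplyr::filter(annotations,
                        tolower(trimws(.data$trait)) %in% blocked,
                        .data$variant_id %in% dat$variant_id)
  out <- dat[!dat$variant_id %in% hits$variant_id, , drop = FALSE]
  attr(out, "screen_log") <- dplyr::distinct(hits, .data$variant_id, .data$trait)
  out
}

#' Select genetic instruments
#'
#' Runs the full selection pipeline in fixed order: significance filter,
#' greedy LD clumping, weak-instrument (F-statistic) exclusion, and confounder
#' screening. Each step's removals are recorded in a selection log whose
#' counts sum to input minus output.
#'
#' @param dat Tibble of variant associations (needs `variant_id`, `beta`,
#'   `se`, `pvalue`).
#' @param pvalue_threshold Significance cutoff (e.g. 5e-8 genome-wide, 1e-4
#'   locus-scale).
#' @param ld LD correlation matrix or `NULL`.
#' @param r2_threshold Clumping r-squared cutoff (e.g. 0.001 stringent, 0.8
#'   permissive cis).
#' @param f_min Minimum F statistic; variants with F below it are excluded as
#'   weak. `NULL` disables the filter.
#' @param annotations,blocked_traits Optional confounder screen inputs.
#' @return An object of class `instrument_set`: the retained tibble (with an
#'   `f_statistic` column) plus `selection_log` attribute.
#' @export
select_instruments <- function(dat, pvalue_threshold, ld = NULL,
                               r2_threshold = 0.001, f_min = 10,
                               annotations = NULL, blocked_traits = NULL) {
  dat <- tibble::as_tibble(dat)
  n0 <- nrow(dat)
  log <- tibble::tibble(step = character(), n_removed = integer(),
                        variants = list())

  sig <- filter_by_pvalue(dat, pvalue_threshold)
  log <- dplyr::add_row(log, step = "significance",
                        n_removed = n0 - nrow(sig),
                        variants = list(setdiff(dat$variant_id, sig$variant_id)))

  clumped <- ld_clump(sig, ld, r2_threshold)
  log <- dplyr::add_row(log, step = "ld_clump",
                        n_removed = nrow(sig) - nrow(clumped),
                        variants = list(setdiff(sig$variant_id, clumped$variant_id)))

  clumped$f_statistic <- f_statistic(clumped$beta, clumped$se)
  strong <- if (is.null(f_min)) clumped else
    clumped[clumped$f_statistic >= f_min, , drop = FALSE]
  log <- dplyr::add_row(log, step = "weak_instrument",
                        n_removed = nrow(clumped) - nrow(strong),
                        variants = list(setdiff(clumped$variant_id, strong$variant_id)))

  final <- strong
  if (!is.null(annotations) && !is.null(blocked_traits)) {
    final <- screen_confounders(strong, annotations, blocked_traits)
    final$f_statistic <- strong$f_statistic[match(final$variant_id, strong$variant_id)]
  }
  log <- dplyr::add_row(log, step = "confounder_screen",
                        n_removed = nrow(strong) - nrow(final),
                        variants = list(setdiff(strong$variant_id, final$variant_id)))

  attr(final, "selection_log") <- log
  class(final) <- c("instrument_set", class(final))
  final
}

#' @export
print.instrument_set <- function(x, ...) {
  log <- attr(x, "selection_log")
  cat("Instrument set:", nrow(x), "variants retained\n")
  if (!is.null(log)) {
    for (i in seq_len(nrow(log))) {
      cat(sprintf("  %-18s removed %d\n", log$step[i], log$n_removed[i]))
    }
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Write a selection log as JSON
#'
#' @param instruments An `instrument_set`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_selection_log <- function(instruments, path) {
  log <- attr(instruments, "selection_log")
  jsonlite::write_json(
    lapply(seq_len(nrow(log)), function(i) list(
      step = log$step[i], n_removed = log$n_removed[i],
      variants = log$variants[[i]]
    )),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
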