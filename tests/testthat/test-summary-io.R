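test_that("reader returns validated records and normalizes lower-case alleles", {
  tab <- tibble::tibble(
    SNP = c("rs1", "rs2", "rs3"),
    chr = c(1, 1, 2), pos = c(100, 200, 300),
    effect_allele = c("a", "C", "G"),
    other_allele = c("t", "G", "A"),
    eaf = c(0.3, 0.4, 0.5),
    beta = c(0.1, -0.2, 0.05),
    se = c(0.01, 0.02, 0.01),
    pval = c(1e-10, 1e-4, 0.5),
    samplesize = c(1000, 1000, 1000)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  out <- read_summary_stats(path)
  expect_equal(nrow(out), 3)
  expect_equal(out$effect_allele, c("A", "C", "G"))
  expect_equal(out$other_allele, c("T", "G", "A"))
  expect_equal(sum(attr(out, "drop_log")$n_dropped), 0)
})

test_that("rows violating invariants are dropped and counted", {
  tab <- assoc_table(6, seed = 2)
  tab$se[2] <- 0
  tab$pvalue[3] <- 0
  tab$pvalue[4] <- 1.5
  tab$effect_allele[5] <- tab$other_allele[5]
  tab$eaf[6] <- 1.2
  out <- validate_associations(tab)
  expect_equal(nrow(out), 1)
  expect_equal(sum(attr(out, "drop_log")$n_dropped), 5)
})

test_that("reader errors on missing mandatory columns and empty tables", {
  tab <- assoc_table(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  names(tab) <- c("SNP", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "samplesize")
  readr::write_tsv(tab[, setdiff(names(tab), "se")], path)
  expect_error(read_summary_stats(path), "missing")
  readr::write_tsv(tab[0, ], path)
  expect_error(read_summary_stats(path), "empty")
})

test_that("harmonization resolves the allele-orientation cases", {
  mk_exp <- function(ea, oa, eaf = 0.2) tibble::tibble(
    variant_id = "rs1", effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = 0.1, se = 0.01, pvalue = 1e-8
  )
  mk_out <- function(ea, oa, eaf = 0.2, beta = 0.2) tibble::tibble(
    variant_id = "rs1", effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = 0.02, pvalue = 1e-4
  )
  case <- function(exp, out, policy = "drop") {
    harmonize_effects(exp, out, palindrome_policy = policy)
  }

  # identical orientation: kept, untouched
  h <- case(mk_exp("A", "G"), mk_out("A", "G"))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, 0.2)

  # swapped alleles: sign flipped, frequency complemented
  h <- case(mk_exp("A", "G"), mk_out("G", "A", eaf = 0.8))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.2)

  # strand complement: kept
  h <- case(mk_exp("A", "G"), mk_out("T", "C"))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, 0.2)

  # strand complement + swap: flipped
  h <- case(mk_exp("A", "G"), mk_out("C", "T"))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.2)

  # irreconcilable allele sets: dropped, never silently kept
  h <- case(mk_exp("A", "G"), mk_out("A", "C"))
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "irreconcilable_alleles")

  # palindromic under drop policy
  h <- case(mk_exp("A", "T"), mk_out("A", "T"))
  expect_equal(h$action, "dropped")
  expect_true(h$palindromic)

  # palindromic, infer policy, ambiguous frequency (0.50 in window): dropped
  h <- case(mk_exp("A", "T", eaf = 0.50), mk_out("A", "T", eaf = 0.50), "infer")
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "palindromic_ambiguous_eaf")

  # palindromic, infer policy, concordant clear frequencies: kept
  h <- case(mk_exp("A", "T", eaf = 0.2), mk_out("A", "T", eaf = 0.25), "infer")
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, 0.2)

  # palindromic, infer policy, discordant frequencies: flipped
  h <- case(mk_exp("A", "T", eaf = 0.2), mk_out("A", "T", eaf = 0.8), "infer")
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.2)

  # palindromic with missing frequency under infer: dropped
  h <- case(mk_exp("A", "T", eaf = NA), mk_out("A", "T", eaf = 0.2), "infer")
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "palindromic_missing_eaf")
})

test_that("harmonization is idempotent on the survivors", {
  set.seed(11)
  exp <- assoc_table(20, seed = 11)
  out <- assoc_table(20, seed = 12)
  out[, c("effect_allele", "other_allele")] <-
    exp[, c("effect_allele", "other_allele")]
  # scramble half the outcome rows to the swapped orientation
  swap <- seq(1, 20, by = 2)
  out[swap, c("effect_allele", "other_allele")] <-
    out[swap, c("other_allele", "effect_allele")]
  out$beta[swap] <- -out$beta[swap]

  h1 <- harmonized_kept(harmonize_effects(exp, out))
  exp2 <- dplyr::transmute(h1, variant_id, effect_allele, other_allele,
                           eaf, beta = beta_exposure, se = se_exposure,
                           pvalue = 0.5)
  out2 <- dplyr::transmute(h1, variant_id, effect_allele, other_allele,
                           eaf, beta = beta_outcome, se = se_outcome,
                           pvalue = 0.5)
  h2 <- harmonize_effects(exp2, out2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
})

test_that("record accounting: output <= input and every drop has a reason", {
  exp <- assoc_table(30, seed = 3)
  out <- assoc_table(25, seed = 4)
  out$variant_id <- exp$variant_id[1:25]
  out[, c("effect_allele", "other_allele")] <-
    exp[1:25, c("effect_allele", "other_allele")]
  out$effect_allele[1] <- setdiff(c("A","C","G","T"),
                                  c(out$effect_allele[1], out$other_allele[1]))[1]
  h <- harmonize_effects(exp, out)
  expect_lte(nrow(harmonized_kept(h)), min(nrow(exp), nrow(out)))
  expect_true(all(!is.na(h$drop_reason[h$action == "dropped"])))
  log <- attr(h, "drop_log")
  expect_gte(sum(log$n_dropped[log$reason == "absent_from_outcome"]), 5)
})
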