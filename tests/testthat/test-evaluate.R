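# Evaluation metrics: nesting, multi-reference matching, stratification,
# brute-force agreement and blinded spot-check sampling.

make_refs <- function(source, target, alts = NULL, tags = "unknown") {
  parallel_corpus(source, target, alts, tags, direction = "En2Ch")
}

# independent recount: plain loops, no shared code with evaluate()
brute_force_recount <- function(results, references) {
  n_succ <- 0L
  n_str <- 0L
  n_dat <- 0L
  for (i in seq_len(nrow(results))) {
    if (results$succeeded[i]) n_succ <- n_succ + 1L
    out <- results$output[i]
    if (!is.na(out)) {
      if (out == references$target[i]) {
        n_str <- n_str + 1L
        n_dat <- n_dat + 1L
      } else if (out %in% references$alt_targets[[i]]) {
        n_dat <- n_dat + 1L
      }
    }
  }
  c(succ = n_succ, str = n_str, dat = n_dat)
}

random_results <- function(references, p_fail = 0.2, p_right = 0.5,
                           p_alt = 0.15) {
  n <- nrow(references)
  u <- stats::runif(n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (u[i] < p_right) {
      references$target[i]
    } else if (u[i] < p_right + p_alt &&
               length(references$alt_targets[[i]]) > 0) {
      references$alt_targets[[i]][1]
    } else {
      paste0("wrong", i)
    }
  }
  fail <- stats::runif(n) < p_fail
  out[fail] <- NA
  translation_results(references$source, out, !fail,
                      ifelse(fail, "segmentation", "none"))
}

test_that("metrics match a hand count on a toy result set", {
  refs <- make_refs(c("methanol", "ethanol"), c("甲醇", "乙醇"))
  res <- translation_results(c("methanol", "ethanol"),
                             c("甲醇", NA), c(TRUE, FALSE),
                             c("none", "segmentation"))
  rep <- evaluate(res, refs)
  expect_equal(rep$success_rate, 0.5)
  expect_equal(rep$string_match_accuracy, 0.5)
  expect_equal(rep$data_match_accuracy, 0.5)
  expect_equal(rep$n_total, 2L)
})

test_that("alternative translations count for data matching only", {
  refs <- make_refs("p-toluene", "对甲苯", list("p-甲苯"))
  hit <- evaluate(translation_results("p-toluene", "对甲苯", TRUE,
                                      "none"), refs)
  expect_equal(hit$n_string_match, 1L)
  expect_equal(hit$n_data_match, 1L)
  alt <- evaluate(translation_results("p-toluene", "p-甲苯", TRUE,
                                      "none"), refs)
  expect_equal(alt$n_string_match, 0L)
  expect_equal(alt$n_data_match, 1L)
  expect_equal(alt$success_rate, 1)
})

test_that("evaluate agrees exactly with a brute-force recount", {
  withr::with_seed(31, {
    refs <- generate_corpus(default_grammar(), 1000, seed = 17)
    res <- random_results(refs)
    rep <- evaluate(res, refs)
    bf <- brute_force_recount(res, refs)
    expect_equal(rep$n_succeeded, unname(bf["succ"]))
    expect_equal(rep$n_string_match, unname(bf["str"]))
    expect_equal(rep$n_data_match, unname(bf["dat"]))
  })
})

test_that("metric nesting holds on random result sets", {
  withr::with_seed(55, {
    refs <- generate_corpus(default_grammar(), 60, seed = 23)
    for (i in 1:100) {
      res <- random_results(refs, p_fail = stats::runif(1, 0, 0.6),
                            p_right = stats::runif(1, 0, 0.8))
      rep <- evaluate(res, refs)
      expect_lte(rep$n_string_match, rep$n_data_match)
      expect_lte(rep$n_data_match, rep$n_succeeded)
      expect_lte(rep$n_succeeded, rep$n_total)
      expect_equal(rep$success_rate, rep$n_succeeded / rep$n_total)
    }
  })
})

test_that("overall metrics equal the stratum-weighted mean", {
  withr::with_seed(41, {
    refs <- generate_corpus(default_grammar(), 300, seed = 29)
    res <- random_results(refs)
    for (mode in c("length_zh", "naming_system")) {
      rep <- evaluate_stratified(res, refs, mode)
      ns <- vapply(rep$strata, `[[`, numeric(1), "n_total")
      for (metric in c("success_rate", "string_match_accuracy",
                       "data_match_accuracy")) {
        vals <- vapply(rep$strata, `[[`, numeric(1), metric)
        whole <- sum(vals * ns) / sum(ns)
        if (mode == "length_zh") {
          expect_equal(whole, rep[[metric]])
        } else {
          # untagged rows are excluded from the strata, so reconstruct
          # the tagged-only aggregate
          idx <- unlist(lapply(rep$strata, `[[`, "indices"))
          sub <- evaluate(res[idx, ],
                          chemnmt:::as_corpus_rows(refs[idx, ], "En2Ch"))
          expect_equal(whole, sub[[metric]])
        }
      }
    }
  })
})

test_that("stratification conventions follow the declared rules", {
  refs <- make_refs(c("a1", "a2", "a3"),
                    c("乙酸乙酯", "7-十八烯酸甲酯", "苯"),
                    tags = c("IUPAC", "CAS", "unknown"))
  parts <- stratify(refs, "length_zh")
  expect_equal(parts[["length<=6"]], c(1L, 3L))   # 4 and 1 characters
  expect_equal(parts[["length>6"]], 2L)           # 8 incl digit and hyphen
  tags <- stratify(refs, "naming_system")
  expect_equal(sort(names(tags)), c("CAS", "IUPAC"))
  expect_equal(attr(tags, "excluded"), 3L)
  # misalignment is an error
  res <- translation_results(c("a1", "zzz", "a3"), refs$target,
                             TRUE, "none")
  expect_error(evaluate(res, refs), "misaligned")
})

test_that("spot-check samples are blinded, sized and deterministic", {
  refs <- generate_corpus(default_grammar(), 120, seed = 37)
  res <- withr::with_seed(1, random_results(refs))
  sc <- spot_check_sample(res, 100, seed = 5, system_label = "LSTM")
  expect_equal(nrow(sc$table), 100L)
  expect_named(sc$table, c("sample_id", "input", "output"))
  expect_false("system" %in% names(sc$table))     # blinded
  expect_equal(sc$key$system, rep("LSTM", 100))
  sc2 <- spot_check_sample(res, 100, seed = 5)
  expect_equal(sc$table$input, sc2$table$input)
  expect_equal(nrow(spot_check_sample(res, 0)$table), 0L)
  expect_error(spot_check_sample(res, 121), "exceeds")
})
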