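# Multi-reference exact-match evaluation of translation results.
#
# Three nested metrics, all computed over the full input set (failed
# translations stay in every denominator — a failure can never match, and
# keeping it in the denominator makes success rate and the two accuracy
# figures directly comparable across translators; this inclusive
# convention is recorded in every report):
#   success rate           an output was produced
#   string matching        output equals the primary reference exactly
#   data matching          output equals the primary or any accepted
#                          alternative translation
# String comparison is exact, case-sensitive, after NFC normalization
# and outer trim.  By construction string <= data <= success.

#' Evaluate translation results against references
#'
#' @param results A `translation_results` tibble.
#' @param references A `parallel_corpus` aligned 1:1 with `results` by
#'   input name (`results$input[i]` must equal `references$source[i]`).
#' @param zh_length_includes_all Convention flag recorded in the report:
#'   Chinese-side lengths count every character including locant digits
#'   and punctuation (the default and only implemented convention).
#' @return An `evaluation_report`: counts, the three rates (as
#'   proportions), and the stated conventions.
#' @export
evaluate <- function(results, references, zh_length_includes_all = TRUE) {
  if (nrow(results) != nrow(references)) {
    stop("results and references must have equal length", call. = FALSE)
  }
  if (!all(results$input == references$source)) {
    bad <- which(results$input != references$source)[1]
    stop(sprintf(
      "results misaligned with references (row %d: \"%s\" vs \"%s\")",
      bad, results$input[bad], references$source[bad]), call. = FALSE)
  }
  n <- nrow(results)
  out <- normalize_name(results$output)
  succeeded <- results$succeeded
  string_match <- !is.na(out) & out == references$target
  data_match <- string_match
  alt_rows <- which(!string_match & !is.na(out) &
                      lengths(references$alt_targets) > 0)
  for (i in alt_rows) {
    data_match[i] <- out[i] %in% references$alt_targets[[i]]
  }
  report <- list(
    n_total = n,
    n_succeeded = sum(succeeded),
    n_string_match = sum(string_match),
    n_data_match = sum(data_match),
    success_rate = if (n > 0) sum(succeeded) / n else NA_real_,
    string_match_accuracy = if (n > 0) sum(string_match) / n else NA_real_,
    data_match_accuracy = if (n > 0) sum(data_match) / n else NA_real_,
    conventions = list(
      denominator = "all inputs, including failed translations",
      comparison = "exact match, case-sensitive, NFC-normalized",
      zh_length_includes_all = zh_length_includes_all),
    row_string_match = string_match,
    row_data_match = data_match)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  Success Rate             %6.2f%%  (%d/%d)\n",
              100 * x$success_rate, x$n_succeeded, x$n_total))
  cat(sprintf("  String Matching Accuracy %6.2f%%  (%d/%d)\n",
              100 * x$string_match_accuracy, x$n_string_match, x$n_total))
  cat(sprintf("  Data Matching Accuracy   %6.2f%%  (%d/%d)\n",
              100 * x$data_match_accuracy, x$n_data_match, x$n_total))
  cat("  denominator:", x$conventions$denominator, "\n")
  if (!is.null(x$strata)) {
    for (s in x$strata) {
      cat(sprintf(
        "  stratum %-12s n=%4d  success %6.2f%%  string %6.2f%%  data %6.2f%%\n",
        s$label, s$n_total, 100 * s$success_rate,
        100 * s$string_match_accuracy, 100 * s$data_match_accuracy))
    }
  }
  invisible(x)
}

#' Partition references into evaluation strata
#'
#' Two stratification modes mirror the package's reporting: by the
#' length of the Chinese-side name (at most 6 characters vs more than
#' 6, counting every character including locant digits and punctuation)
#' or by naming-system tag (untagged pairs are excluded and reported).
#'
#' @param references A `parallel_corpus`.
#' @param mode `"length_zh"` or `"naming_system"`.
#' @param length_cutoff Demarcation length for `length_zh` (default 6).
#' @return Named list of integer index vectors; for `naming_system` an
#'   `excluded` attribute holds the untagged row indices.
#' @export
stratify <- function(references, mode = c("length_zh", "naming_system"),
                     length_cutoff = 6L) {
  mode <- match.arg(mode)
  if (mode == "length_zh") {
    zh <- if (corpus_direction(references) == "En2Ch") references$target
          else references$source
    len <- nchar(zh)
    out <- list(sort(which(len <= length_cutoff)),
                sort(which(len > length_cutoff)))
    names(out) <- c(sprintf("length<=%d", length_cutoff),
                    sprintf("length>%d", length_cutoff))
    out
  } else {
    tags <- references$naming_system
    keep <- tags != "unknown"
    out <- split(which(keep), tags[keep])
    attr(out, "excluded") <- which(!keep)
    out
  }
}

#' Evaluate with strata attached
#'
#' @inheritParams evaluate
#' @param mode Stratification mode passed to [stratify()].
#' @return An `evaluation_report` whose `strata` field holds the same
#'   metric set per stratum.
#' @export
evaluate_stratified <- function(results, references,
                                mode = c("length_zh", "naming_system")) {
  mode <- match.arg(mode)
  report <- evaluate(results, references)
  parts <- stratify(references, mode)
  report$strata <- lapply(names(parts), function(lbl) {
    idx <- parts[[lbl]]
    sub <- evaluate(results[idx, ], as_corpus_rows(
      references[idx, ], corpus_direction(references)))
    sub$label <- lbl
    sub$indices <- idx
    unclass(sub)[c("label", "n_total", "n_succeeded", "n_string_match",
                   "n_data_match", "success_rate",
                   "string_match_accuracy", "data_match_accuracy",
                   "indices")]
  })
  if (!is.null(attr(parts, "excluded"))) {
    report$excluded_untagged <- length(attr(parts, "excluded"))
  }
  report
}

#' Draw a blinded spot-check sample
#'
#' Uniformly samples `n` result rows for manual checking.  The returned
#' `table` shows only input and output under an anonymous sample id; the
#' mapping back to the original rows (and the system label) is kept in
#' the separate `key`, so the checker is blind to which system produced
#' each translation.
#'
#' @param results A `translation_results` tibble.
#' @param n Sample size (at most `nrow(results)`).
#' @param seed Integer seed; equal seeds give identical samples.
#' @param system_label Label stored in the key (e.g. `"LSTM"`).
#' @return A list with `table` (sample_id, input, output) and `key`
#'   (sample_id, row, system).
#' @export
spot_check_sample <- function(results, n, seed = 1L,
                              system_label = "unknown") {
  if (n > nrow(results)) {
    stop("sample size exceeds number of results", call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(results), n))
  list(table = tibble::tibble(sample_id = seq_len(n),
                              input = results$input[idx],
                              output = results$output[idx]),
       key = tibble::tibble(sample_id = seq_len(n), row = idx,
                            system = system_label))
}

#' Serialize an evaluation report to JSON
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$row_string_match <- NULL
  out$row_data_match <- NULL
  if (!is.null(out$strata)) {
    out$strata <- lapply(out$strata, function(s) {
      s$indices <- NULL
      s
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
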