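# Shared result container for every translator (neural or rule-based).

#' Construct a table of translation results
#'
#' Invariant: a row succeeded if and only if it has an output, if and only
#' if its failure reason is `"none"`.
#'
#' @param input Character vector of input names.
#' @param output Character vector of produced translations (`NA` on
#'   failure).
#' @param succeeded Logical vector.
#' @param failure_reason Character vector: `"none"` for successes;
#'   typical failure tags are `"oov_character"`, `"internal_error"`
#'   (neural translators) and `"segmentation"`, `"dictionary"` (rule-based
#'   translator).
#' @return A tibble of class `translation_results`.
#' @export
translation_results <- function(input, output, succeeded, failure_reason) {
  out <- tibble::tibble(input = as.character(input),
                        output = as.character(output),
                        succeeded = as.logical(succeeded),
                        failure_reason = as.character(failure_reason))
  bad <- out$succeeded != !is.na(out$output) |
    out$succeeded != (out$failure_reason == "none")
  if (any(bad)) {
    stop("inconsistent translation result: succeeded must match presence ",
         "of output and failure_reason == \"none\"", call. = FALSE)
  }
  class(out) <- c("translation_results", class(out))
  out
}

#' Write translation results as UTF-8 TSV
#'
#' Columns: input, output (empty on failure), succeeded, failure_reason.
#'
#' @param results A `translation_results` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", results$input,
                   ifelse(is.na(results$output), "", results$output),
                   ifelse(results$succeeded, "true", "false"),
                   results$failure_reason)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a translation results TSV
#' @param path Path written by [write_results_tsv()].
#' @return A `translation_results` tibble.
#' @export
read_results_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(translation_results(character(0), character(0), logical(0),
                               character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k) vapply(fields, function(f) {
    if (length(f) >= k) f[[k]] else ""
  }, character(1))
  output <- get(2)
  translation_results(get(1), ifelse(nzchar(output), output, NA),
                      get(3) == "true", get(4))
}
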