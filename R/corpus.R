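# Parallel-corpus data model and I/O.
#
# A parallel corpus is a tibble with one row per name pair:
#   source       character, the name in the source language
#   target       character, the primary reference translation
#   alt_targets  list of character vectors, accepted alternative translations
#   naming_system character in {"IUPAC","CAS","trivial","unknown"}
# plus a "direction" attribute ("En2Ch" or "Ch2En").  All text is NFC
# normalized and trimmed on construction so comparisons are stable across
# mixed-width punctuation and combining marks.

CORPUS_DIRECTIONS <- c("En2Ch", "Ch2En")
NAMING_SYSTEMS <- c("IUPAC", "CAS", "trivial", "unknown")

normalize_name <- function(x) {
  stringi::stri_trans_nfc(stringi::stri_trim_both(x))
}

#' Construct a parallel corpus of chemical-name pairs
#'
#' @param source Character vector of source-language names.
#' @param target Character vector of primary reference translations.
#' @param alt_targets List of character vectors of accepted alternative
#'   translations (one element per pair), or `NULL` for none.
#' @param naming_system Character vector of naming-system tags
#'   (`"IUPAC"`, `"CAS"`, `"trivial"` or `"unknown"`); recycled.
#' @param direction `"En2Ch"` or `"Ch2En"`.
#'
#' @return A tibble of class `parallel_corpus` with a `direction` attribute.
#' @export
parallel_corpus <- function(source, target, alt_targets = NULL,
                            naming_system = "unknown",
                            direction = c("En2Ch", "Ch2En")) {
  direction <- match.arg(direction)
  source <- normalize_name(as.character(source))
  target <- normalize_name(as.character(target))
  if (length(source) != length(target)) {
    stop("source and target must have equal length", call. = FALSE)
  }
  n <- length(source)
  if (is.null(alt_targets)) alt_targets <- rep(list(character(0)), n)
  if (length(alt_targets) != n) {
    stop("alt_targets must have one element per pair", call. = FALSE)
  }
  naming_system <- rep_len(as.character(naming_system), n)
  bad_tag <- setdiff(unique(naming_system), NAMING_SYSTEMS)
  if (length(bad_tag) > 0) {
    stop("unknown naming_system tag(s): ", paste(bad_tag, collapse = ", "),
         call. = FALSE)
  }
  if (n > 0 && (any(!nzchar(source)) || any(!nzchar(target)))) {
    stop("source and target names must be non-empty after trimming",
         call. = FALSE)
  }
  # normalize alternatives; the primary target never doubles as an alternative
  alt_targets <- lapply(seq_len(n), function(i) {
    a <- normalize_name(as.character(alt_targets[[i]]))
    a <- unique(a[nzchar(a)])
    setdiff(a, target[[i]])
  })
  out <- tibble::tibble(source = source, target = target,
                        alt_targets = alt_targets,
                        naming_system = naming_system)
  attr(out, "direction") <- direction
  class(out) <- c("parallel_corpus", class(out))
  out
}

#' @export
print.parallel_corpus <- function(x, ...) {
  cat(sprintf("<parallel_corpus> %s, %d pairs\n",
              corpus_direction(x), nrow(x)))
  NextMethod()
}

#' Direction tag of a parallel corpus
#' @param corpus A `parallel_corpus`.
#' @return `"En2Ch"` or `"Ch2En"`.
#' @export
corpus_direction <- function(corpus) attr(corpus, "direction")

as_corpus_rows <- function(df, direction) {
  parallel_corpus(df$source, df$target, df$alt_targets, df$naming_system,
                  direction = direction)
}

#' Read a tab-separated parallel corpus
#'
#' Each non-empty line holds at least two tab-separated columns:
#' source name, primary target, then optionally further accepted
#' translations, and optionally a final naming-system tag
#' (`IUPAC`/`CAS`/`trivial`/`unknown`).  Strings are NFC normalized and
#' trimmed; blank lines are skipped; input order is preserved.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param direction Corpus direction tag, `"En2Ch"` or `"Ch2En"`.
#' @param header If `TRUE`, the first line is discarded as a header.
#' @return A `parallel_corpus`.
#' @export
read_parallel_tsv <- function(path, direction = c("En2Ch", "Ch2En"),
                              header = FALSE) {
  direction <- match.arg(direction)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (header && length(lines) > 0) lines <- lines[-1]
  keep <- nzchar(stringi::stri_trim_both(lines))
  line_no <- which(keep) + if (header) 1L else 0L
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(parallel_corpus(character(0), character(0), direction = direction))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 2)) {
    bad <- line_no[which(ncol < 2)[1]]
    stop(sprintf("line %d: expected at least 2 tab-separated columns", bad),
         call. = FALSE)
  }
  source <- vapply(fields, `[[`, character(1), 1L)
  target <- vapply(fields, `[[`, character(1), 2L)
  tag <- character(length(fields))
  alts <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    extra <- fields[[i]][-(1:2)]
    extra <- stringi::stri_trim_both(extra)
    extra <- extra[nzchar(extra)]
    if (length(extra) > 0 && extra[length(extra)] %in% NAMING_SYSTEMS) {
      tag[i] <- extra[length(extra)]
      extra <- extra[-length(extra)]
    } else {
      tag[i] <- "unknown"
    }
    alts[[i]] <- extra
  }
  parallel_corpus(source, target, alts, tag, direction = direction)
}

#' Write a parallel corpus as UTF-8 TSV
#'
#' Inverse of [read_parallel_tsv()]: columns are source, target, any
#' alternative translations, then the naming-system tag when it is not
#' `"unknown"`.
#'
#' @param corpus A `parallel_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parallel_tsv <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    cols <- c(corpus$source[[i]], corpus$target[[i]],
              corpus$alt_targets[[i]])
    if (corpus$naming_system[[i]] != "unknown") {
      cols <- c(cols, corpus$naming_system[[i]])
    }
    paste(cols, collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Remove duplicate name pairs
#'
#' The first occurrence of each (source, target) combination is kept and
#' order is otherwise preserved.  Alternative translations of removed
#' duplicates are merged into the surviving pair, so the corpus's
#' one-to-many translation information survives deduplication.
#'
#' @param corpus A `parallel_corpus`.
#' @return The deduplicated `parallel_corpus`.
#' @export
deduplicate <- function(corpus) {
  if (nrow(corpus) == 0) return(corpus)
  key <- paste(corpus$source, corpus$target, sep = "\u0001")
  first <- !duplicated(key)
  groups <- split(seq_len(nrow(corpus)), key)
  alts <- corpus$alt_targets
  merged <- lapply(which(first), function(i) {
    idx <- groups[[key[[i]]]]
    setdiff(unique(unlist(alts[idx], use.names = FALSE)), corpus$target[[i]])
  })
  out <- corpus[first, ]
  out$alt_targets <- merged
  as_corpus_rows(out, corpus_direction(corpus))
}

#' Split a corpus into training and held-out partitions
#'
#' The held-out partition has exactly `round(n * test_fraction)` pairs,
#' drawn uniformly at random; the partition is a deterministic function of
#' the corpus, the fraction and the seed.  The held-out 20% doubles as the
#' test set by default, matching the evaluation protocol this package
#' follows; pass `validation_fraction` to carve an additional validation
#' partition out of the training pairs for a three-way split.
#'
#' @param corpus A `parallel_corpus`.
#' @param test_fraction Held-out proportion, strictly between 0 and 1.
#' @param seed Integer seed controlling the draw.
#' @param validation_fraction Optional second proportion (of the whole
#'   corpus) reserved for validation; default 0 (two-way split).
#' @return A list with elements `train`, `test` and (if requested)
#'   `validation`, each a `parallel_corpus`.
#' @export
split_corpus <- function(corpus, test_fraction = 0.2, seed = 1L,
                         validation_fraction = 0) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (validation_fraction < 0 || test_fraction + validation_fraction >= 1) {
    stop("test_fraction + validation_fraction must be below 1", call. = FALSE)
  }
  n <- nrow(corpus)
  n_test <- round(n * test_fraction)
  n_val <- round(n * validation_fraction)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_test + n_val))
  test_idx <- sort(idx[seq_len(n_test)])
  val_idx <- sort(idx[seq_len(n_val) + n_test])
  train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  direction <- corpus_direction(corpus)
  out <- list(train = as_corpus_rows(corpus[train_idx, ], direction),
              test = as_corpus_rows(corpus[test_idx, ], direction))
  if (n_val > 0) {
    out$validation <- as_corpus_rows(corpus[val_idx, ], direction)
  }
  out
}

#' Corpus summary statistics
#'
#' @param corpus A `parallel_corpus`.
#' @return A list: record count, unique character counts on each side
#'   (alternative translations included on the target side), and length
#'   maxima.
#' @export
corpus_stats <- function(corpus) {
  src_chars <- unique_chars(corpus$source)
  tgt_chars <- unique_chars(c(corpus$target,
                              unlist(corpus$alt_targets, use.names = FALSE)))
  list(
    direction = corpus_direction(corpus),
    n_pairs = nrow(corpus),
    n_unique_source_chars = length(src_chars),
    n_unique_target_chars = length(tgt_chars),
    max_source_len = if (nrow(corpus)) max(nchar(corpus$source)) else 0L,
    max_target_len = if (nrow(corpus)) max(nchar(corpus$target)) else 0L
  )
}

# unique single characters over a character vector, sorted by code point
unique_chars <- function(x) {
  ch <- unique(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE))
  if (length(ch) == 0) return(character(0))
  ch[order(vapply(ch, utf8ToInt, integer(1)))]
}
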