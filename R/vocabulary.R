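# Character vocabularies and integer encoding for teacher-forced training.
#
# Characters are indexed 1..V in code-point order; the three reserved
# symbols (pad, start-of-sequence, end-of-sequence) occupy the fixed final
# indices V+1..V+3 so that model shapes are reproducible across runs.  The
# reserved symbols are drawn from a Unicode private-use block and are
# rejected if they ever occur in corpus text.

SOS_CHAR <- "\uE000"  # private-use: start of sequence
EOS_CHAR <- "\uE001"  # private-use: end of sequence
PAD_CHAR <- "\uE002"  # private-use: padding
RESERVED_CHARS <- c(PAD_CHAR, SOS_CHAR, EOS_CHAR)

#' Build a character vocabulary from a parallel corpus
#'
#' Source characters are collected over all source names; target characters
#' over primary and alternative translations.  Each side is sorted by
#' Unicode code point, then the reserved pad / start / end symbols are
#' appended at fixed final indices.
#'
#' @param corpus A non-empty `parallel_corpus`.
#' @return An object of class `char_vocabulary` with fields
#'   `source_chars`, `target_chars` (corpus characters only), the reserved
#'   symbols, and bijective character/index maps for both sides.
#' @export
build_vocabulary <- function(corpus) {
  if (nrow(corpus) == 0) {
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  }
  src <- unique_chars(corpus$source)
  tgt <- unique_chars(c(corpus$target,
                        unlist(corpus$alt_targets, use.names = FALSE)))
  clash <- intersect(RESERVED_CHARS, c(src, tgt))
  if (length(clash) > 0) {
    stop("corpus text contains reserved private-use symbol(s)", call. = FALSE)
  }
  new_char_vocabulary(src, tgt)
}

new_char_vocabulary <- function(source_chars, target_chars) {
  v <- list(
    source_chars = source_chars,
    target_chars = target_chars,
    sos_symbol = SOS_CHAR,
    eos_symbol = EOS_CHAR,
    pad_symbol = PAD_CHAR
  )
  v$source_all <- c(source_chars, RESERVED_CHARS)
  v$target_all <- c(target_chars, RESERVED_CHARS)
  v$source_index <- stats::setNames(seq_along(v$source_all), v$source_all)
  v$target_index <- stats::setNames(seq_along(v$target_all), v$target_all)
  class(v) <- "char_vocabulary"
  v
}

#' @export
print.char_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<char_vocabulary> %d source + %d target characters (+3 reserved)\n",
    length(x$source_chars), length(x$target_chars)))
  invisible(x)
}

vocab_size <- function(vocab, side = c("source", "target")) {
  side <- match.arg(side)
  length(if (side == "source") vocab$source_all else vocab$target_all)
}

# reserved-symbol indices on one side
vocab_special <- function(vocab, side = c("source", "target")) {
  side <- match.arg(side)
  idx <- if (side == "source") vocab$source_index else vocab$target_index
  list(pad = unname(idx[[PAD_CHAR]]), sos = unname(idx[[SOS_CHAR]]),
       eos = unname(idx[[EOS_CHAR]]))
}

#' Serialize a vocabulary to JSON
#' @param vocab A `char_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(source_chars = vocab$source_chars,
         target_chars = vocab$target_chars,
         sos_symbol = vocab$sos_symbol,
         eos_symbol = vocab$eos_symbol,
         pad_symbol = vocab$pad_symbol),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path Path written by [write_vocabulary()].
#' @return A `char_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$sos_symbol, SOS_CHAR),
            identical(j$eos_symbol, EOS_CHAR),
            identical(j$pad_symbol, PAD_CHAR))
  new_char_vocabulary(as.character(j$source_chars),
                      as.character(j$target_chars))
}

# split strings into per-string integer index vectors; attributes the
# offending pair when a character is missing from the vocabulary
chars_to_indices <- function(texts, index, side, labels = texts) {
  lapply(seq_along(texts), function(i) {
    ch <- strsplit(texts[[i]], "", fixed = TRUE)[[1]]
    idx <- unname(index[ch])
    if (anyNA(idx)) {
      missing_ch <- ch[which(is.na(idx))[1]]
      stop(sprintf(
        "out-of-vocabulary %s character \"%s\" (U+%04X) in \"%s\"",
        side, missing_ch, utf8ToInt(missing_ch), labels[[i]]),
        call. = FALSE)
    }
    as.integer(idx)
  })
}

#' Encode name pairs as teacher-forcing tensors
#'
#' Produces the three integer index matrices a teacher-forced
#' sequence-to-sequence model trains on: the encoder input, the decoder
#' input (target prefixed with the start symbol), and the decoder target —
#' the same sequence offset by one timestep and closed with the end
#' symbol.  Rows are padded with the pad symbol.
#'
#' @param pairs A `parallel_corpus` (or compatible tibble) of pairs.
#' @param vocab A `char_vocabulary` covering every character of `pairs`.
#' @param max_source_len,max_target_len Matrix widths; must be at least the
#'   longest source/target in `pairs`.
#' @return A list of class `encoded_batch`: `encoder_input` (n x Ts),
#'   `decoder_input` and `decoder_target` (n x (Tt+1)), plus per-row true
#'   `source_lengths` and `target_lengths`.
#' @export
encode_batch <- function(pairs, vocab, max_source_len = NULL,
                         max_target_len = NULL) {
  n <- nrow(pairs)
  src_idx <- chars_to_indices(pairs$source, vocab$source_index, "source")
  tgt_idx <- chars_to_indices(pairs$target, vocab$target_index, "target",
                              labels = pairs$source)
  src_len <- lengths(src_idx)
  tgt_len <- lengths(tgt_idx)
  if (is.null(max_source_len)) max_source_len <- max(src_len, 1L)
  if (is.null(max_target_len)) max_target_len <- max(tgt_len, 1L)
  if (n > 0 && (max(src_len) > max_source_len || max(tgt_len) > max_target_len)) {
    stop("max lengths must be at least the longest pair", call. = FALSE)
  }
  sp_s <- vocab_special(vocab, "source")
  sp_t <- vocab_special(vocab, "target")
  enc <- matrix(sp_s$pad, nrow = n, ncol = max_source_len)
  dec_in <- matrix(sp_t$pad, nrow = n, ncol = max_target_len + 1L)
  dec_tgt <- matrix(sp_t$pad, nrow = n, ncol = max_target_len + 1L)
  for (i in seq_len(n)) {
    if (src_len[i] > 0) enc[i, seq_len(src_len[i])] <- src_idx[[i]]
    dec_in[i, seq_len(tgt_len[i] + 1L)] <- c(sp_t$sos, tgt_idx[[i]])
    dec_tgt[i, seq_len(tgt_len[i] + 1L)] <- c(tgt_idx[[i]], sp_t$eos)
  }
  structure(list(encoder_input = enc, decoder_input = dec_in,
                 decoder_target = dec_tgt,
                 source_lengths = src_len, target_lengths = tgt_len),
            class = "encoded_batch")
}

#' Decode index rows back to strings
#'
#' Inverse of [encode_batch()] for one side of the vocabulary: reserved
#' pad/start/end symbols are dropped, every other index maps back to its
#' character.
#'
#' @param mat Integer index matrix (rows are sequences).
#' @param vocab A `char_vocabulary`.
#' @param side `"source"` or `"target"`.
#' @return Character vector, one string per row.
#' @export
decode_indices <- function(mat, vocab, side = c("source", "target")) {
  side <- match.arg(side)
  if (nrow(mat) == 0) return(character(0))
  chars <- if (side == "source") vocab$source_all else vocab$target_all
  sp <- vocab_special(vocab, side)
  drop <- c(sp$pad, sp$sos, sp$eos)
  apply(mat, 1L, function(row) {
    row <- row[!(row %in% drop)]
    paste(chars[row], collapse = "")
  })
}
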