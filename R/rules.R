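# Three-stage rule-based baseline translator: a chemical name is
# disassembled into word fragments by greedy longest-match segmentation
# over a lexicon, each fragment is translated through a (fragment, role,
# context) dictionary, and the translated fragments are reassembled
# through reorder templates (esters reverse word order between English and
# Chinese).  Failures at any stage are recorded values, never exceptions,
# so that success-rate style metrics can be computed from result tables.

RULE_ROLES <- c("parent", "substituent", "suffix", "ester_acyl",
                "ester_alkyl", "locant", "punctuation", "multiplier")
RULE_CONTEXTS <- c("default", "aromatic", "ester")

#' Construct a rule set for the rule-based translator
#'
#' @param direction `"En2Ch"` or `"Ch2En"`.
#' @param lexicon Data frame with columns `fragment`, `role` and logical
#'   `aromatic` (fragments whose presence switches translation into
#'   aromatic context, e.g. an aromatic parent).
#' @param dictionary Data frame with columns `fragment`, `role`, `context`
#'   (`"default"`, `"aromatic"` or `"ester"`) and `translation`.
#' @param templates List of reorder templates; each template is a list
#'   with `match` (character vector of roles, compared against the
#'   segmentation's role sequence with punctuation removed) and `output`
#'   (list of `list(ref = i)` references into the matched fragments and
#'   `list(lit = s)` literal separators).
#' @param ester_context_roles Roles whose presence in a segmentation
#'   activates ester context for dictionary lookup.
#' @param role_priority Role order used to break ties between lexicon
#'   entries of equal fragment length.
#' @param punctuation_map Named character vector rewriting punctuation
#'   fragments on output (e.g. dropping spaces for Chinese targets).
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(direction = c("En2Ch", "Ch2En"), lexicon, dictionary,
                     templates = list(),
                     ester_context_roles = "ester_acyl",
                     role_priority = RULE_ROLES,
                     punctuation_map = character(0)) {
  direction <- match.arg(direction)
  lexicon <- tibble::as_tibble(lexicon)
  dictionary <- tibble::as_tibble(dictionary)
  if (!"aromatic" %in% names(lexicon)) lexicon$aromatic <- FALSE
  lexicon$aromatic[is.na(lexicon$aromatic)] <- FALSE
  stopifnot(all(c("fragment", "role") %in% names(lexicon)),
            all(c("fragment", "role", "context", "translation") %in%
                  names(dictionary)))
  if (any(!nzchar(lexicon$fragment))) {
    stop("lexicon fragments must be non-empty", call. = FALSE)
  }
  if (!all(lexicon$role %in% RULE_ROLES)) {
    stop("unknown role in lexicon", call. = FALSE)
  }
  if (!all(dictionary$context %in% RULE_CONTEXTS)) {
    stop("unknown context in dictionary", call. = FALSE)
  }
  lex_key <- paste(lexicon$fragment, lexicon$role)
  dict_key <- paste(dictionary$fragment, dictionary$role)
  uncovered <- setdiff(lex_key, dict_key)
  if (length(uncovered) > 0) {
    stop("lexicon entries without any dictionary entry: ",
         paste(uncovered, collapse = "; "), call. = FALSE)
  }
  for (tpl in templates) {
    if (!all(tpl$match %in% RULE_ROLES)) {
      stop("template references undeclared role", call. = FALSE)
    }
  }
  structure(list(direction = direction,
                 source_language = if (direction == "En2Ch") "en" else "zh",
                 lexicon = lexicon, dictionary = dictionary,
                 templates = templates,
                 ester_context_roles = ester_context_roles,
                 role_priority = role_priority,
                 punctuation_map = punctuation_map),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf(
    "<rule_set> %s: %d lexicon entries, %d dictionary entries, %d templates\n",
    x$direction, nrow(x$lexicon), nrow(x$dictionary), length(x$templates)))
  invisible(x)
}

is_rule_punct <- function(ch) {
  grepl("^[-,()\\s·]$", ch, perl = TRUE)
}

#' Disassemble a name into word fragments
#'
#' Greedy longest-match left-to-right segmentation: digit runs become
#' locant fragments, punctuation characters become punctuation fragments,
#' everything else is matched against the lexicon, preferring the longest
#' fragment and breaking role ties by the rule set's role priority.  There
#' is no backtracking; an unmatched position leaves the segmentation
#' uncovered rather than raising an error (Chinese names carry no word
#' boundaries, so unsegmentable inputs are an expected failure mode).
#'
#' @param name Input name (normalized internally).
#' @param rules A `rule_set`.
#' @return A list of class `segmentation`: `input`, `fragments` (tibble
#'   with `text` and `role`), `covered` flag.
#' @export
segment <- function(name, rules) {
  name <- normalize_name(name)
  chars <- strsplit(name, "", fixed = TRUE)[[1]]
  n <- length(chars)
  lex <- rules$lexicon
  lex_lens <- nchar(lex$fragment)
  max_len <- if (nrow(lex)) max(lex_lens) else 0L
  prio <- match(lex$role, rules$role_priority)
  texts <- character(0)
  roles <- character(0)
  covered <- TRUE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j < n && grepl("^[0-9]$", chars[j + 1L])) j <- j + 1L
      texts <- c(texts, paste(chars[i:j], collapse = ""))
      roles <- c(roles, "locant")
      i <- j + 1L
      next
    }
    if (is_rule_punct(ch)) {
      texts <- c(texts, ch)
      roles <- c(roles, "punctuation")
      i <- i + 1L
      next
    }
    # longest lexicon match starting at i
    best <- 0L
    best_role <- NA_character_
    upper <- min(max_len, n - i + 1L)
    for (len in rev(seq_len(upper))) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      hits <- which(lex$fragment == cand)
      if (length(hits) > 0) {
        best <- len
        best_role <- lex$role[hits[which.min(prio[hits])]]
        break
      }
    }
    if (best == 0L) {
      covered <- FALSE
      break
    }
    texts <- c(texts, paste(chars[i:(i + best - 1L)], collapse = ""))
    roles <- c(roles, best_role)
    i <- i + best
  }
  structure(list(input = name,
                 fragments = tibble::tibble(text = texts, role = roles),
                 covered = covered),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> \"%s\" %s\n", x$input,
              if (x$covered) "covered" else "NOT covered"))
  if (nrow(x$fragments)) {
    cat(paste0(" [", x$fragments$text, "|", x$fragments$role, "]",
               collapse = ""), "\n")
  }
  invisible(x)
}

fragment_failure <- function(frag) {
  structure(tibble::tibble(text = character(0), role = character(0)),
            failed_fragment = frag)
}

translation_failed <- function(translated) {
  !is.null(attr(translated, "failed_fragment"))
}

# active dictionary contexts for a segmentation, most specific first
segmentation_contexts <- function(seg, rules) {
  ctx <- character(0)
  if (any(seg$fragments$role %in% rules$ester_context_roles)) {
    ctx <- c(ctx, "ester")
  }
  arom <- rules$lexicon$fragment[rules$lexicon$aromatic]
  if (any(seg$fragments$text %in% arom)) ctx <- c(ctx, "aromatic")
  c(ctx, "default")
}

#' Translate the fragments of a covered segmentation
#'
#' Each lexicon fragment is looked up in the dictionary under the most
#' specific active context (ester, then aromatic, then default); locants
#' pass through unchanged and punctuation is rewritten through the rule
#' set's punctuation map.
#'
#' @param seg A covered `segmentation`.
#' @param rules A `rule_set`.
#' @return A tibble with columns `text` (translated fragment) and `role`;
#'   on a missing dictionary entry, a zero-row tibble carrying the
#'   offending fragment in its `failed_fragment` attribute — use
#'   [rule_translate()] for the never-throwing interface.
#' @export
translate_fragments <- function(seg, rules) {
  if (!seg$covered) {
    stop("cannot translate an uncovered segmentation", call. = FALSE)
  }
  contexts <- segmentation_contexts(seg, rules)
  dict <- rules$dictionary
  # a substituent reads as the ester alkyl only in leading position;
  # substituents inside the acyl (e.g. "3-pentyl" of "3-pentylheptanoate")
  # keep their default translation
  content <- which(!seg$fragments$role %in% c("punctuation", "locant"))
  first_content <- if (length(content)) content[1] else 0L
  out <- character(nrow(seg$fragments))
  for (i in seq_len(nrow(seg$fragments))) {
    frag <- seg$fragments$text[i]
    role <- seg$fragments$role[i]
    ctxs <- contexts
    if (role == "substituent" && i != first_content) {
      ctxs <- setdiff(ctxs, "ester")
    }
    if (role == "locant") {
      out[i] <- frag
    } else if (role == "punctuation") {
      hit <- rules$punctuation_map[frag]
      out[i] <- if (!is.na(hit)) unname(hit) else frag
    } else {
      hits <- which(dict$fragment == frag & dict$role == role)
      if (length(hits) == 0) {
        return(fragment_failure(frag))
      }
      pick <- NA_integer_
      for (ctx in ctxs) {
        ctx_hit <- hits[dict$context[hits] == ctx]
        if (length(ctx_hit) > 0) {
          pick <- ctx_hit[1]
          break
        }
      }
      if (is.na(pick)) {
        return(fragment_failure(frag))
      }
      out[i] <- dict$translation[pick]
    }
  }
  tibble::tibble(text = out, role = seg$fragments$role)
}

#' Reassemble translated fragments into a target-language name
#'
#' The first template whose `match` equals the role sequence of the
#' non-punctuation fragments is applied (this is how esters get their
#' word-order reversal and separator); otherwise fragments are emitted in
#' identity order and concatenated.
#'
#' @param translated Tibble of translated fragments (`text`, `role`).
#' @param rules A `rule_set`.
#' @return The reassembled name (single string).
#' @export
reassemble <- function(translated, rules) {
  content_idx <- which(translated$role != "punctuation")
  content_roles <- translated$role[content_idx]
  for (tpl in rules$templates) {
    if (length(tpl$match) == length(content_roles) &&
        all(tpl$match == content_roles)) {
      parts <- vapply(tpl$output, function(item) {
        if (!is.null(item$ref)) translated$text[content_idx[item$ref]]
        else item$lit
      }, character(1))
      return(paste(parts, collapse = ""))
    }
  }
  paste(translated$text, collapse = "")
}

#' Rule-based translation of one chemical name
#'
#' Composition of [segment()], [translate_fragments()] and
#' [reassemble()].  Never throws: a failure at the disassembly or
#' dictionary stage yields an unsuccessful result naming the stage, which
#' is what makes a below-100% success rate measurable for rule-based
#' translation.
#'
#' @param name Input name.
#' @param rules A `rule_set`.
#' @return A one-row `translation_results` tibble (see
#'   [translation_results()]).
#' @export
rule_translate <- function(name, rules) {
  seg <- segment(name, rules)
  if (!seg$covered) {
    return(translation_results(seg$input, NA_character_, FALSE,
                               "segmentation"))
  }
  translated <- translate_fragments(seg, rules)
  if (translation_failed(translated)) {
    return(translation_results(seg$input, NA_character_, FALSE,
                               "dictionary"))
  }
  translation_results(seg$input, reassemble(translated, rules), TRUE, "none")
}

#' Rule-based translation of many names
#'
#' @param names Character vector of input names.
#' @param rules A `rule_set`.
#' @return A `translation_results` tibble with one row per input.
#' @export
rule_translate_batch <- function(names, rules) {
  rows <- lapply(names, rule_translate, rules = rules)
  translation_results(
    vapply(rows, function(r) r$input, character(1)),
    vapply(rows, function(r) r$output, character(1)),
    vapply(rows, function(r) r$succeeded, logical(1)),
    vapply(rows, function(r) r$failure_reason, character(1)))
}
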