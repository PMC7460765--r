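# Rule-set YAML serialization.
#
# A rule set is one UTF-8 YAML document with sections:
#   direction            En2Ch | Ch2En
#   ester_context_roles  roles whose presence activates ester context
#   role_priority        tie-break order for lexicon role conflicts
#   punctuation_map      output rewrites for punctuation fragments
#   lexicon              [{fragment, role, aromatic?}, ...]
#   dictionary           [{fragment, role, context, translation}, ...]
#   templates            [{match: [roles], output: [{ref: i}|{lit: s}]}, ...]
# The files shipped under inst/extdata/ are the demonstration rule sets
# for the package's toy nomenclature (see tools/make_demo_rules.R).

#' Read a rule set from YAML
#' @param path Path to a rule-set YAML document.
#' @return A validated `rule_set`.
#' @export
read_rule_set <- function(path) {
  if (!file.exists(path)) {
    stop("rule-set file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  lex <- tibble::tibble(
    fragment = vapply(y$lexicon, function(e) normalize_name(e$fragment),
                      character(1)),
    role = vapply(y$lexicon, `[[`, character(1), "role"),
    aromatic = vapply(y$lexicon, function(e) isTRUE(e$aromatic), logical(1)))
  dict <- tibble::tibble(
    fragment = vapply(y$dictionary, function(e) normalize_name(e$fragment),
                      character(1)),
    role = vapply(y$dictionary, `[[`, character(1), "role"),
    context = vapply(y$dictionary, function(e) {
      if (is.null(e$context)) "default" else e$context
    }, character(1)),
    translation = vapply(y$dictionary, function(e) {
      normalize_name(if (is.null(e$translation)) "" else e$translation)
    }, character(1)))
  punct <- character(0)
  if (!is.null(y$punctuation_map)) {
    punct <- vapply(y$punctuation_map, function(v) {
      if (is.null(v)) "" else as.character(v)
    }, character(1))
    names(punct) <- names(y$punctuation_map)
  }
  rule_set(direction = y$direction, lexicon = lex, dictionary = dict,
           templates = if (is.null(y$templates)) list() else y$templates,
           ester_context_roles = unlist(y$ester_context_roles),
           role_priority = if (is.null(y$role_priority)) RULE_ROLES
                           else unlist(y$role_priority),
           punctuation_map = punct)
}

#' Write a rule set to YAML
#' @param rules A `rule_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_set <- function(rules, path) {
  lex <- lapply(seq_len(nrow(rules$lexicon)), function(i) {
    e <- list(fragment = rules$lexicon$fragment[i],
              role = rules$lexicon$role[i])
    if (rules$lexicon$aromatic[i]) e$aromatic <- TRUE
    e
  })
  dict <- lapply(seq_len(nrow(rules$dictionary)), function(i) {
    list(fragment = rules$dictionary$fragment[i],
         role = rules$dictionary$role[i],
         context = rules$dictionary$context[i],
         translation = rules$dictionary$translation[i])
  })
  doc <- list(direction = rules$direction,
              ester_context_roles = as.list(rules$ester_context_roles),
              role_priority = as.list(rules$role_priority),
              punctuation_map = as.list(rules$punctuation_map),
              lexicon = lex, dictionary = dict,
              templates = rules$templates)
  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(txt), con, useBytes = TRUE)
  invisible(path)
}

#' Path to a shipped demonstration rule set
#' @param direction `"En2Ch"` or `"Ch2En"`.
#' @return Path to the installed YAML file.
#' @export
demo_rule_path <- function(direction = c("En2Ch", "Ch2En")) {
  direction <- match.arg(direction)
  fname <- if (direction == "En2Ch") "rules_en2ch_demo.yaml"
           else "rules_ch2en_demo.yaml"
  system.file("extdata", fname, package = "chemnmt", mustWork = TRUE)
}
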