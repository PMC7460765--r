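# Demonstration rule sets for the package's toy nomenclature.
#
# These builders derive the rule-based translator's lexicon, dictionary
# and reorder templates from the same grammar the synthetic-corpus
# generator uses, so the shipped rule sets translate generated names
# exactly (on unambiguous productions).  They are an open demonstration of
# the three-stage architecture, not a reconstruction of any production
# rule-based tool's proprietary rule set.

lex_row <- function(fragment, role, aromatic = FALSE) {
  tibble::tibble(fragment = fragment, role = role, aromatic = aromatic)
}

dict_row <- function(fragment, role, translation, context = "default") {
  tibble::tibble(fragment = fragment, role = role, context = context,
                 translation = translation)
}

#' Demonstration rule set matching the synthetic grammar
#'
#' Builds the English-to-Chinese or Chinese-to-English rule set that
#' encodes the same toy nomenclature as [synthetic_grammar()]: greedy
#' longest-match segmentation morphemes, context-dependent suffix
#' translations (-ol as alcohol 醇 vs phenol 酚, alkyl groups as 基 vs
#' ester 酯), and the ester word-order reversal template.
#'
#' @param direction `"En2Ch"` or `"Ch2En"`.
#' @param grammar The `synthetic_grammar` to mirror.
#' @return A `rule_set`.
#' @export
demo_rule_set <- function(direction = c("En2Ch", "Ch2En"),
                          grammar = synthetic_grammar()) {
  direction <- match.arg(direction)
  if (direction == "En2Ch") demo_rules_en2ch(grammar)
  else demo_rules_ch2en(grammar)
}

demo_rules_en2ch <- function(g) {
  ane_zh <- g$suffixes$ane[["zh"]]
  acid_zh <- g$suffixes$oic_acid[["zh"]]
  lex <- rbind(
    lex_row(paste0(g$stems_en, "ane"), "parent"),
    lex_row(paste0(g$stems_en, "an"), "parent"),
    lex_row(g$aromatic_en, "parent", aromatic = TRUE),
    lex_row(g$aromatic_stem_en, "parent", aromatic = TRUE),
    lex_row(paste0(g$stems_en, "yl"), "substituent"),
    lex_row(g$ethenyl_en, "substituent"),
    lex_row(g$halogens_en, "substituent"),
    lex_row(paste0(g$stems_en, "anoate"), "ester_acyl"),
    lex_row(c(g$acetate_en, "ethanoate"), "ester_acyl"),
    lex_row(c("ol", "al", "one", "amine", "oic", "acid"), "suffix"),
    lex_row(g$multipliers_en, "multiplier"))
  dict <- rbind(
    dict_row(paste0(g$stems_en, "ane"), "parent",
             paste0(g$stems_zh, ane_zh)),
    dict_row(paste0(g$stems_en, "an"), "parent", g$stems_zh),
    dict_row(g$aromatic_en, "parent", g$aromatic_zh),
    dict_row(g$aromatic_stem_en, "parent", g$aromatic_zh),
    # alkyl groups: 基 by default, fused with 酯 inside ester names
    dict_row(paste0(g$stems_en, "yl"), "substituent",
             paste0(g$stems_zh, g$alkyl_group_char)),
    dict_row(paste0(g$stems_en, "yl"), "substituent",
             paste0(g$stems_zh, g$ester_char), context = "ester"),
    dict_row(g$ethenyl_en, "substituent", g$ethenyl_zh),
    dict_row(g$ethenyl_en, "substituent",
             paste0(g$ethenyl_zh, g$ester_char), context = "ester"),
    dict_row(g$halogens_en, "substituent", g$halogens_zh),
    dict_row(paste0(g$stems_en, "anoate"), "ester_acyl",
             paste0(g$stems_zh, acid_zh)),
    dict_row(g$acetate_en, "ester_acyl", g$acetic_zh),
    dict_row("ethanoate", "ester_acyl", g$acetic_zh),
    # -ol is 醇 on aliphatic parents but 酚 on aromatic rings
    dict_row("ol", "suffix", g$suffixes$ol[["zh"]]),
    dict_row("ol", "suffix", g$suffixes$ol_aromatic[["zh"]],
             context = "aromatic"),
    dict_row("al", "suffix", g$suffixes$al[["zh"]]),
    dict_row("one", "suffix", g$suffixes$one[["zh"]]),
    dict_row("amine", "suffix", g$suffixes$amine[["zh"]]),
    dict_row("oic", "suffix", acid_zh),
    dict_row("acid", "suffix", ""),
    dict_row(g$multipliers_en, "multiplier", g$multipliers_zh))
  rule_set(
    direction = "En2Ch", lexicon = lex, dictionary = dict,
    templates = list(
      # "<alkyl>yl <acyl>oate" -> "<acyl>酸<alkyl>酯": word order reverses
      list(match = c("substituent", "ester_acyl"),
           output = list(list(ref = 2L), list(ref = 1L))),
      # substituted acyl: "ethyl 3-chlorohexanoate" -> "3-氯己酸乙酯"
      list(match = c("substituent", "locant", "substituent", "ester_acyl"),
           output = list(list(ref = 2L), list(lit = "-"), list(ref = 3L),
                         list(ref = 4L), list(ref = 1L)))),
    ester_context_roles = "ester_acyl",
    punctuation_map = c(" " = ""))
}

demo_rules_ch2en <- function(g) {
  ane_zh <- g$suffixes$ane[["zh"]]
  acid_zh <- g$suffixes$oic_acid[["zh"]]
  alkane_zh <- paste0(g$stems_zh, ane_zh)
  acyl_zh <- paste0(g$stems_zh, acid_zh)
  alkyl_zh <- paste0(g$stems_zh, g$ester_char)
  phenol_zh <- paste0(g$aromatic_zh, g$suffixes$ol_aromatic[["zh"]])
  lex <- rbind(
    lex_row(alkane_zh, "parent"),
    lex_row(g$stems_zh, "parent"),
    lex_row(g$aromatic_zh, "parent", aromatic = TRUE),
    lex_row(phenol_zh, "parent", aromatic = TRUE),
    lex_row(paste0(g$stems_zh, g$alkyl_group_char), "substituent"),
    lex_row(g$halogens_zh, "substituent"),
    lex_row(acyl_zh, "ester_acyl"),
    lex_row(g$vinegar_zh, "ester_acyl"),
    lex_row(alkyl_zh, "ester_alkyl"),
    lex_row(paste0(g$ethenyl_zh, g$ester_char), "ester_alkyl"),
    lex_row(vapply(g$suffixes[c("ol", "ol_aromatic", "al", "one",
                                "amine", "oic_acid")],
                   `[[`, character(1), "zh"), "suffix"),
    lex_row(g$multipliers_zh, "multiplier"))
  dict <- rbind(
    dict_row(alkane_zh, "parent", paste0(g$stems_en, "ane")),
    dict_row(g$stems_zh, "parent", paste0(g$stems_en, "an")),
    dict_row(g$aromatic_zh, "parent", g$aromatic_en),
    dict_row(phenol_zh, "parent", paste0(g$aromatic_stem_en, "ol")),
    dict_row(paste0(g$stems_zh, g$alkyl_group_char), "substituent",
             paste0(g$stems_en, "yl")),
    dict_row(g$halogens_zh, "substituent", g$halogens_en),
    # acid words: full acid name alone, acyl -oate inside ester names;
    # the stem-2 acid keeps its trivial English renderings
    dict_row(g$acetic_zh, "ester_acyl", g$acetate_en, context = "ester"),
    dict_row(acyl_zh, "ester_acyl", paste0(g$stems_en, "anoic acid")),
    dict_row(acyl_zh, "ester_acyl", paste0(g$stems_en, "anoate"),
             context = "ester"),
    dict_row(g$vinegar_zh, "ester_acyl", "acetic acid"),
    dict_row(g$vinegar_zh, "ester_acyl", g$acetate_en, context = "ester"),
    dict_row(alkyl_zh, "ester_alkyl", paste0(g$stems_en, "yl")),
    dict_row(paste0(g$ethenyl_zh, g$ester_char), "ester_alkyl",
             g$ethenyl_en),
    dict_row(g$suffixes$ol[["zh"]], "suffix", "ol"),
    dict_row(g$suffixes$ol_aromatic[["zh"]], "suffix", "ol"),
    dict_row(g$suffixes$al[["zh"]], "suffix", "al"),
    dict_row(g$suffixes$one[["zh"]], "suffix", "one"),
    dict_row(g$suffixes$amine[["zh"]], "suffix", "amine"),
    dict_row(g$suffixes$oic_acid[["zh"]], "suffix", "oic acid"),
    dict_row(g$multipliers_zh, "multiplier", g$multipliers_en))
  rule_set(
    direction = "Ch2En", lexicon = lex, dictionary = dict,
    templates = list(
      # "<acyl>酸<alkyl>酯" -> "<alkyl>yl <acyl>oate"
      list(match = c("ester_acyl", "ester_alkyl"),
           output = list(list(ref = 2L), list(lit = " "),
                         list(ref = 1L))),
      # substituted acyl: "3-氯己酸乙酯" -> "ethyl 3-chlorohexanoate"
      list(match = c("locant", "substituent", "ester_acyl", "ester_alkyl"),
           output = list(list(ref = 4L), list(lit = " "), list(ref = 1L),
                         list(lit = "-"), list(ref = 2L),
                         list(ref = 3L)))),
    ester_context_roles = "ester_alkyl",
    punctuation_map = character(0))
}
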