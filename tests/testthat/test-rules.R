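# Rule-based translator: segmentation, dictionary contexts, reassembly
# templates, end-to-end fixtures and the longest-match oracle.

test_that("segmentation disassembles boundary-free Chinese names", {
  rules <- shipped_rules("Ch2En")
  seg <- segment("乙酸乙酯", rules)
  expect_true(seg$covered)
  expect_equal(seg$fragments$text, c("乙酸", "乙酯"))
  expect_equal(seg$fragments$role, c("ester_acyl", "ester_alkyl"))
  # natural-product trivial stem missing from the lexicon
  seg2 <- segment("羽扇豆醇棕榈酸酯", rules)
  expect_false(seg2$covered)
  seg3 <- segment("", rules)
  expect_true(seg3$covered)
  expect_equal(nrow(seg3$fragments), 0L)
})

test_that("covered segmentations concatenate exactly to their input", {
  rules <- shipped_rules("En2Ch")
  corpus <- generate_corpus(default_grammar(), 150, seed = 21)
  for (nm in corpus$source) {
    seg <- segment(nm, rules)
    expect_true(seg$covered)
    expect_identical(paste(seg$fragments$text, collapse = ""), nm)
  }
})

# exhaustive enumeration of covering segmentations; picks the one a
# leftmost-longest strategy prefers (longest fragment first at every
# boundary, lexicographic over fragment lengths)
oracle_segment <- function(input, fragments) {
  best <- NULL
  recurse <- function(pos, acc) {
    if (!is.null(best)) return()
    if (pos > nchar(input)) {
      best <<- acc
      return()
    }
    lens <- sort(unique(nchar(fragments)), decreasing = TRUE)
    for (len in lens) {
      piece <- substr(input, pos, pos + len - 1)
      if (nchar(piece) == len && piece %in% fragments) {
        recurse(pos + len, c(acc, piece))
      }
    }
  }
  recurse(1L, character(0))
  best
}

test_that("greedy segmentation equals the longest-match oracle when it covers", {
  withr::with_seed(77, {
    alphabet <- c("a", "b", "c")
    for (case in 1:40) {
      frags <- unique(replicate(8, paste(
        sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = "")))
      lex <- tibble::tibble(fragment = frags, role = "parent",
                            aromatic = FALSE)
      dict <- tibble::tibble(fragment = frags, role = "parent",
                             context = "default", translation = frags)
      rules <- rule_set("En2Ch", lex, dict)
      input <- paste(sample(alphabet, sample(4:10, 1), replace = TRUE),
                     collapse = "")
      seg <- segment(input, rules)
      if (seg$covered) {
        # greedy committed without backtracking: compare against the
        # leftmost-longest segmentation found by exhaustive search
        expect_identical(seg$fragments$text,
                         oracle_segment(input, frags))
      }
    }
  })
})

test_that("fragment translation respects aromatic and ester contexts", {
  rules <- shipped_rules("En2Ch")
  # -ol: alcohol on an aliphatic parent, phenol on an aromatic ring
  tr_ali <- translate_fragments(segment("methanol", rules), rules)
  expect_equal(tr_ali$text, c("甲", "醇"))
  tr_arom <- translate_fragments(segment("benzene-1,2,4-triol", rules),
                                 rules)
  expect_equal(tr_arom$text[length(tr_arom$text)], "酚")
  # ethyl: 乙基 by default, fused 乙酯 as the leading ester alkyl
  tr_sub <- translate_fragments(segment("2-ethylhexane", rules), rules)
  expect_true("乙基" %in% tr_sub$text)
  tr_ester <- translate_fragments(segment("ethyl acetate", rules), rules)
  expect_true("乙酯" %in% tr_ester$text)
  expect_error(translate_fragments(segment("羽扇豆醇棕榈酸酯",
                                           shipped_rules("Ch2En")),
                                   shipped_rules("Ch2En")),
               "uncovered")
})

test_that("reassembly applies the ester reorder template", {
  rules <- shipped_rules("En2Ch")
  ester <- tibble::tibble(text = c("乙酯", "乙酸"),
                          role = c("substituent", "ester_acyl"))
  expect_equal(reassemble(ester, rules), "乙酸乙酯")
  single <- tibble::tibble(text = "甲醇", role = "parent")
  expect_equal(reassemble(single, rules), "甲醇")
  rules_zh <- shipped_rules("Ch2En")
  back <- tibble::tibble(text = c("hexanoate", "ethenyl"),
                         role = c("ester_acyl", "ester_alkyl"))
  expect_equal(reassemble(back, rules_zh), "ethenyl hexanoate")
})

test_that("rule translation reproduces worked fixtures exactly", {
  rules <- shipped_rules("En2Ch")
  fixtures <- c("ethyl acetate" = "乙酸乙酯",
                "methanol" = "甲醇",
                "benzene-1,2,4-triol" = "苯-1,2,4-三酚",
                "ethenyl hexanoate" = "己酸乙烯基酯")
  for (nm in names(fixtures)) {
    res <- rule_translate(nm, rules)
    expect_true(res$succeeded)
    expect_equal(res$output, unname(fixtures[nm]))
    expect_equal(res$failure_reason, "none")
  }
})

test_that("rule translation records failures as values with a stage", {
  rules_zh <- shipped_rules("Ch2En")
  for (nm in c("羽扇豆醇棕榈酸酯", "异氧化前胡素", "原儿茶酸甲酯")) {
    res <- rule_translate(nm, rules_zh)
    expect_false(res$succeeded)
    expect_equal(res$failure_reason, "segmentation")
    expect_true(is.na(res$output))
  }
  # dictionary-stage failure: lexicon entry without the needed context
  lex <- tibble::tibble(fragment = c("foo", "bar"),
                        role = c("parent", "suffix"),
                        aromatic = FALSE)
  dict <- tibble::tibble(fragment = c("foo", "bar"),
                         role = c("parent", "suffix"),
                         context = c("default", "aromatic"),
                         translation = c("X", "Y"))
  rs <- rule_set("En2Ch", lex, dict)
  res <- rule_translate("foobar", rs)
  expect_false(res$succeeded)
  expect_equal(res$failure_reason, "dictionary")
  # arbitrary junk never throws
  expect_false(rule_translate("@#$%", rules_zh)$succeeded)
})

test_that("rule translation is a pure function of name and rules", {
  rules <- shipped_rules("En2Ch")
  a <- rule_translate_batch(c("hexanal", "octan-3-one"), rules)
  b <- rule_translate_batch(c("hexanal", "octan-3-one"), rules)
  expect_identical(a, b)
})

test_that("the shipped rule set translates generator output exactly", {
  corpus <- generate_corpus(default_grammar(), 300, seed = 13)
  rules <- shipped_rules("En2Ch")
  res <- rule_translate_batch(corpus$source, rules)
  expect_true(all(res$succeeded))  # same toy nomenclature on both sides
  unambiguous <- lengths(corpus$alt_targets) == 0
  expect_true(all(res$output[unambiguous] ==
                    corpus$target[unambiguous]))
  # ambiguous pairs still land inside the accepted translation set
  amb <- which(!unambiguous)
  ok <- vapply(amb, function(i) {
    res$output[i] %in% c(corpus$target[i], corpus$alt_targets[[i]])
  }, logical(1))
  expect_true(all(ok))
})

test_that("rule-set validation rejects inconsistent inputs", {
  lex <- tibble::tibble(fragment = "foo", role = "parent",
                        aromatic = FALSE)
  dict_ok <- tibble::tibble(fragment = "foo", role = "parent",
                            context = "default", translation = "X")
  expect_error(rule_set("En2Ch", lex,
                        dict_ok[0, ]), "without any dictionary entry")
  expect_error(rule_set("En2Ch",
                        tibble::tibble(fragment = "", role = "parent",
                                       aromatic = FALSE),
                        dict_ok), "non-empty")
  expect_error(rule_set("En2Ch", lex, dict_ok,
                        templates = list(list(match = "nonsense",
                                              output = list()))),
               "undeclared role")
})
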