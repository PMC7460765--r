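# Shared fixtures: all built in code at test time.

# tiny deterministic corpus for encoding/vocabulary tests
tiny_corpus <- function() {
  parallel_corpus(
    source = c("ethyl acetate", "methanol", "hexane"),
    target = c("乙酸乙酯", "甲醇", "己烷"),
    alt_targets = list("醋酸乙酯", character(0), "正己烷"),
    naming_system = c("trivial", "IUPAC", "IUPAC"),
    direction = "En2Ch")
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  con <- file(path, open = "wb")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  path
}

default_grammar <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- synthetic_grammar()
    g
  }
})

shipped_rules <- local({
  cache <- list()
  function(direction) {
    if (is.null(cache[[direction]])) {
      cache[[direction]] <<- read_rule_set(demo_rule_path(direction))
    }
    cache[[direction]]
  }
})
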