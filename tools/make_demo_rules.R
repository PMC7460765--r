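# Regenerates the shipped demonstration rule sets from the default
# synthetic grammar, keeping inst/extdata/ in lockstep with the
# generator.  Run from the package root:
#   Rscript tools/make_demo_rules.R
suppressMessages({
  library(tibble)
  library(stringi)
  library(withr)
})
for (f in list.files("R", full.names = TRUE)) source(f, encoding = "UTF-8")
g <- synthetic_grammar()
write_rule_set(demo_rule_set("En2Ch", g),
               "inst/extdata/rules_en2ch_demo.yaml")
write_rule_set(demo_rule_set("Ch2En", g),
               "inst/extdata/rules_ch2en_demo.yaml")
cat("demo rule sets written to inst/extdata/\n")
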