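Package: chemnmt
Title: Machine Translation of Chemical Nomenclature Between English and
    Chinese
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Character-level machine translation of chemical nomenclature
    between English and Chinese.  Implements two neural
    sequence-to-sequence translators (a recurrent LSTM encoder-decoder
    trained with teacher forcing, and a convolutional encoder-decoder
    with dot-product attention), a three-stage rule-based baseline
    (disassembly, fragment translation, reassembly) driven by editable
    rule-set files, a multi-reference exact-match evaluation suite
    (success rate, string-matching and data-matching accuracy,
    stratified accuracy, blinded spot-check sampling), and a seeded
    generator of paired English/Chinese chemical-style names for
    end-to-end testing without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
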