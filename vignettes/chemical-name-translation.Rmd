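---
title: "Methods: character-level translation of chemical nomenclature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: character-level translation of chemical nomenclature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chemnmt)
```

## The problem

Chemical names are structured text: a systematic name encodes a
molecular structure through morphemes (stems, suffixes, substituent
prefixes), locants and punctuation. Translating them between English
and Chinese is harder than dictionary lookup for three reasons that
drive every design choice in this package:

1. **No word boundaries in Chinese.** 乙酸乙酯 must first be segmented
   into 乙酸 (acetate) and 乙酯 (ethyl, ester-fused) before any
   fragment can be translated — and segmentation of long trivial names
   (natural products especially) routinely fails in rule systems.
2. **Word-order reversal.** Esters put the alkyl first in English
   ("ethyl acetate") and the acyl first in Chinese (乙酸乙酯).
3. **Context-dependent morphemes.** The suffix -ol is 醇 on an
   aliphatic parent (methanol → 甲醇) but 酚 on an aromatic ring
   (benzene-1,2,4-triol → 苯-1,2,4-三酚); ethyl is 乙基 or 乙 in most
   names but fuses to 乙酯 inside an ester.

The package implements both a rule-based translator that makes these
mechanisms explicit, and two neural sequence-to-sequence translators
that learn them from parallel data, plus the evaluation protocol that
compares them.

## Corpus model and encoding

A parallel corpus is a table of (source, primary target, alternative
targets, naming-system tag) rows with a direction tag (`En2Ch` or
`Ch2En`) — the two directions are separate corpora because name
translation is not symmetric (the preferred rendering of a translation
is often not the original name). All strings are normalized to Unicode
NFC on construction; chemical names mix half- and full-width
punctuation and combining marks, and exact-match evaluation is
meaningless unless comparison is performed in one normal form.
Deduplication keeps the first occurrence of each (source, target) pair
and merges the alternative-translation sets of removed duplicates, so
one-to-many translation information survives.

Character vocabularies are built per side, sorted by code point, with
three reserved symbols (pad, start, end) at fixed final indices; the
reserved symbols come from a Unicode private-use block so they can
never collide with corpus text (this is validated). Teacher-forcing
tensors follow the standard layout: `decoder_input` is the target
prefixed with the start symbol, `decoder_target` the same sequence
offset one step and closed with the end symbol; the offset invariant is
asserted on every batch before it reaches a model.

The held-out split draws exactly `round(n * fraction)` pairs
deterministically from a seed. The 20% held-out partition doubles as
the test set (an optional three-way split is available via
`validation_fraction`); vocabularies are built on the full corpus
before splitting, mirroring the usual practice for character
inventories, so held-out inputs are in-vocabulary by construction.

## The neural translators

No deep-learning framework is involved: both models, including
backpropagation and the Adam optimizer, are implemented in base R
matrix algebra and verified against numerical differentiation in the
test suite (worst relative error below 1e-4 at double precision).

**LSTM encoder–decoder (teacher forcing).** A single-layer LSTM
encoder reads the embedded source characters and emits its final
hidden and cell state, two vectors of width `latent_dim`. The decoder
LSTM starts from those states and consumes the offset target sequence;
a linear-softmax head over target characters is trained with per-step
cross-entropy, pad positions masked. Pad steps also freeze the
recurrent state (update masking) so right-padding cannot pollute the
encoder summary. Inference is greedy: from the start symbol, emit the
arg-max character and feed it back until the end symbol or a step
bound.

**Convolutional encoder–decoder with attention.** Three 1-d
convolution layers (kernel 3, same padding, ReLU) encode the source;
three *causal* convolution layers (kernel 3, left padding only)
process the offset target, so position *t* never sees positions
beyond *t* and training matches step-by-step inference — causality is
enforced by construction and checked by direct perturbation tests at
1e-6. Scaled dot-product attention (`softmax(D E'/sqrt(d))`, source
pad columns masked) lets every target position attend over encoder
outputs; the decoder stream and its context are concatenated and
passed through two further causal convolution layers and the softmax
head. The attention form, kernel width and padding scheme are this
package's choices — minimal standard options satisfying the stated
layer counts and the causality contract; no residual connections or
pooling are used. Greedy decoding re-runs the causal stack over the
growing prefix.

**Parameters that matter.** `batch_size` 64, `epochs` 100 and
`latent_dim` 256 are the defaults of the training protocol this
package follows; desk-scale runs in the tests and the acceptance
script use `latent_dim` 128 and 30 epochs (see *Problem sizes*).
Characters are represented by learned embeddings of width
`latent_dim`. The learning rate (Adam, 0.002) and the global
gradient-norm clip (5) are the package's own choices, fixed once after
a pilot run on the synthetic grammar and not tuned per experiment; the
forget-gate bias starts at 1 so early training retains state. One seed
drives initialization and shuffling; determinism is exact on a given
platform (same BLAS), while cross-platform agreement is statistical,
not bit-level.

**Failure semantics.** A trained model always produces *some* output
for in-vocabulary input — success rate 100% by construction — and an
input containing a character never seen in training yields a recorded
`oov_character` failure, not an exception. This keeps success-rate
semantics computable from result tables alone.

## The rule-based baseline

Three stages over an editable YAML rule set, matching the classical
architecture:

1. **Disassembly** — greedy longest-match left-to-right segmentation.
   Digit runs become locants and punctuation becomes literal
   fragments; everything else must match the lexicon. Ties between
   roles at equal length break by a declared role priority. There is
   deliberately no backtracking: an unmatched position leaves the
   segmentation uncovered, which is exactly the failure mode that
   caps rule-based success rates on unsegmentable (typically trivial)
   names. A property test checks greedy output against an exhaustive
   longest-match oracle on small random lexicons.
2. **Fragment translation** — dictionary lookup under the most
   specific active context: *ester* (an acyl/alkyl fragment is
   present; a substituent reads as the ester alkyl only in leading
   position, so acyl-internal substituents keep their default
   rendering), then *aromatic* (an aromatic-flagged parent is
   present — this is what flips -ol from 醇 to 酚), then *default*.
   A missing entry is a dictionary-stage failure naming the fragment.
3. **Reassembly** — the first template whose role sequence matches the
   non-punctuation fragments is applied (esters reverse order and
   insert separators); otherwise fragments are emitted in identity
   order.

Failure stage (`segmentation` / `dictionary`) is recorded per name so
evaluation can attribute error sources. The shipped demonstration rule
sets encode the same toy nomenclature as the synthetic generator —
they are an open demonstration of the architecture, not a
reconstruction of any production system's proprietary rules, and no
claim is made that they reproduce a production system's accuracy on
real corpora.

## The synthetic generator

The generator emulates, at string level, the corpus phenomena above:
four production families (aliphatic names with optional substituent
prefixes; esters, including substituted acyls; aromatics, including
polyphenols; aliphatic polyols) over ~40 morphemes, with locants
copied verbatim between languages and a configurable ambiguity model
that attaches accepted alternative translations (alkyl 基 elision,
e.g. 己酸乙烯基酯 vs 己酸乙烯酯; locant-fronted forms, 己-2-醇 vs
2-己醇; the 乙酸/醋酸 acid-name pair; the 正 straight-chain prefix) to
about 10% of eligible pairs. Every family is compositional enough that
its pool of distinct names is several times the number drawn from it,
so the configured production mixture (ester fraction 25% by default)
is approximately realized even though corpora are generated unique.

What it does *not* model: real chemical validity (locants are not
checked against chain length or ring positions), natural-product
trivial names, transliteration, CAS inverted name forms, and the long
character tail of a real corpus (the toy grammar has ~30–40 unique
characters per side against ~100 English and ~2,000 Chinese characters
in curated data). Tests passing on this grammar therefore demonstrate
that the mechanisms work — teacher forcing, causality, attention,
segmentation, reordering, multi-reference scoring — not that the
reported real-corpus accuracy figures transfer; those require the
original curated corpus and full-scale training.

## Evaluation conventions

Three nested metrics per result set: success rate (an output was
produced), string-matching accuracy (exact equality with the primary
reference), data-matching accuracy (equality with the primary or any
accepted alternative). Two conventions are deliberate and recorded in
every report: failed translations stay in every denominator (a failure
can never match, and a common denominator keeps systems comparable),
and comparison is exact, case-sensitive, after NFC normalization and
outer trim. By construction string ≤ data ≤ success, and each overall
metric equals the stratum-size-weighted mean of its stratum values.
Stratification is by Chinese-side length (cut at 6 characters,
counting *all* characters including locant digits and punctuation —
declared since "length in Chinese characters" is otherwise ambiguous)
or by naming-system tag. Spot-check sampling returns a blinded table
(input and output under an anonymous id) with the system identity in a
separate key file. Running-time comparisons are excluded from reports:
they are hardware-dependent and not a reproducible surface.

## Numerical and design notes

* Greedy decoding (no beam search) keeps success-rate semantics
  trivial and matches the reference decoding style for this task.
* The decode step bound defaults to the longest training target plus
  10, guaranteeing termination on any input.
* Softmax is computed with row-max subtraction; cross-entropy adds
  1e-12 inside the logarithm; attention masks use an additive -1e30.
* Ties in arg-max decoding break toward the lowest character index,
  making decoding deterministic.
* `epochs = 0` is a supported no-op (untrained checkpoint, empty
  history); empty corpora, empty files and empty inputs are values,
  not errors, everywhere downstream of the readers.
* Checkpoints round-trip exactly (`save_translator` /
  `load_translator` restore prediction-identical models).

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the whole pipeline exercises on one CPU in minutes: 3,000 generated
pairs (80/20 split), LSTM with latent width 128 trained 30 epochs at
batch 64 for the learnability check (held-out exact match ≥ 90%, and
non-decreasing within 2 points against the same protocol at 500
pairs); a 10-pair corpus trained to convergence (latent 32, 300
epochs) for the memorization check on both architectures; 1,000
random result sets for the metric-algebra properties. The full
protocol (latent 256, 100 epochs, tens of thousands of pairs) is
supported by the same functions given a real corpus.

## Known limitations

* The LSTM carries no attention, so very long names stress its fixed
  state — consistent with its weaker behavior on long inputs; the
  convolutional model pays for attention with slower decoding.
* The rule engine's context model is segmentation-global (plus the
  leading-position rule for ester alkyls); nested scopes (e.g. an
  aromatic fragment inside an otherwise aliphatic ester) would need
  scoped contexts.
* Reversing a corpus direction is mechanical; the reversal warning
  exists because curated corpora are direction-specific.
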