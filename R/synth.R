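# Seeded generator of paired English/Chinese chemical-style names.
#
# The toy grammar reproduces, at string level, the phenomena that make
# chemical-nomenclature translation hard: boundary-free Chinese names,
# ester word-order reversal between the two languages, context-dependent
# suffix translation (-ol is 醇 on aliphatic parents but 酚 on aromatic
# rings), locants and punctuation copied verbatim across languages, and
# one-to-many translation sets.  Chemical correctness of the generated
# names (e.g. locant validity, substitution patterns) is not claimed; the
# generator targets string-level structure only, at a scale small enough
# (~40 morphemes) that sequence models train to high accuracy in minutes
# on one CPU.  Every production family is compositional (optional
# substituent prefixes, locants) so that its pool of distinct names is
# several times larger than the number of unique pairs drawn from it and
# the configured production mixture is approximately realized in
# generated corpora.

#' Default synthetic nomenclature grammar
#'
#' @param production_weights Named numeric mixture over the four
#'   production families (`aliphatic`, `ester`, `aromatic`, `polyol`);
#'   normalized internally.
#' @param locant_prob Probability that an -ol/-one core carries a locant.
#' @param prefix_probs Probabilities of 0, 1 or 2 substituent prefixes on
#'   an aliphatic core.
#' @param acyl_prefix_prob Probability that an ester acyl carries a
#'   substituent prefix.
#' @param alt_prob Probability that a pair with an eligible variant
#'   attaches it as an accepted alternative translation (variants: alkyl
#'   基 elision, locant-fronted Chinese form, 正 straight-chain prefix).
#' @param acetate_prob Probability that an unsubstituted stem-2 ester is
#'   rendered with the trivial English acyl name (acetate) rather than
#'   the systematic one.
#' @return An object of class `synthetic_grammar`.
#' @export
synthetic_grammar <- function(production_weights = c(aliphatic = 0.45,
                                                     ester = 0.25,
                                                     aromatic = 0.18,
                                                     polyol = 0.12),
                              locant_prob = 0.6,
                              prefix_probs = c(0.12, 0.48, 0.40),
                              acyl_prefix_prob = 0.75,
                              alt_prob = 0.10,
                              acetate_prob = 0.5) {
  stopifnot(all(production_weights >= 0), sum(production_weights) > 0,
            length(prefix_probs) == 3, all(prefix_probs >= 0),
            locant_prob >= 0, locant_prob <= 1,
            acyl_prefix_prob >= 0, acyl_prefix_prob <= 1,
            alt_prob >= 0, alt_prob <= 1,
            acetate_prob >= 0, acetate_prob <= 1)
  families <- c("aliphatic", "ester", "aromatic", "polyol")
  if (!setequal(names(production_weights), families)) {
    stop("production_weights must name exactly the four production families",
         call. = FALSE)
  }
  g <- list(
    # chain-length stems 1..10, aligned English/Chinese
    stems_en = c("meth", "eth", "prop", "but", "pent",
                 "hex", "hept", "oct", "non", "dec"),
    stems_zh = c("甲", "乙", "丙", "丁", "戊",
                 "己", "庚", "辛", "壬", "癸"),
    aromatic_en = "benzene", aromatic_stem_en = "benzen",
    aromatic_zh = "苯",
    suffixes = list(
      ane = c(en = "ane", zh = "烷"),
      ol = c(en = "ol", zh = "醇"),       # 酚 in aromatic context
      ol_aromatic = c(en = "ol", zh = "酚"),
      al = c(en = "al", zh = "醛"),
      one = c(en = "one", zh = "酮"),
      amine = c(en = "amine", zh = "胺"),
      oic_acid = c(en = "oic acid", zh = "酸")
    ),
    core_suffix_weights = c(ane = 0.15, ol = 0.28, al = 0.07, one = 0.28,
                            amine = 0.07, oic_acid = 0.15),
    halogens_en = c("chloro", "bromo", "fluoro"),
    halogens_zh = c("氯", "溴", "氟"),
    multipliers_en = c("di", "tri"),
    multipliers_zh = c("二", "三"),
    ester_char = "酯",
    alkyl_group_char = "基",
    normal_prefix_zh = "正",    # straight-chain marker used in variants
    ethenyl_en = "ethenyl", ethenyl_zh = "乙烯基",
    acetate_en = "acetate",
    acetic_zh = "乙酸",     # systematic acetic acid
    vinegar_zh = "醋酸",    # trivial acetic acid
    aromatic_kind_weights = c(plain = 0.01, ol = 0.02, polyol = 0.06,
                              sub = 0.06, disub = 0.85),
    production_weights = production_weights / sum(production_weights),
    locant_prob = locant_prob,
    prefix_probs = prefix_probs / sum(prefix_probs),
    acyl_prefix_prob = acyl_prefix_prob,
    alt_prob = alt_prob,
    acetate_prob = acetate_prob,
    tag_weights = c(IUPAC = 0.70, CAS = 0.25, unknown = 0.05)
  )
  class(g) <- "synthetic_grammar"
  g
}

#' @export
print.synthetic_grammar <- function(x, ...) {
  cat("<synthetic_grammar>", length(x$stems_en),
      "chain stems; production mixture:\n")
  print(round(x$production_weights, 3))
  invisible(x)
}

# ---- production renderers (deterministic given their arguments) ----------

# combined substituent tables: 10 alkyls then 3 halogens
substituent_tables <- function(g) {
  list(en = c(paste0(g$stems_en, "yl"), g$halogens_en),
       zh = c(paste0(g$stems_zh, g$alkyl_group_char), g$halogens_zh))
}

# "<L1>-<sub1>-<L2>-<sub2>" prefix strings, ordered by locant
render_prefix <- function(g, subs, locants) {
  if (length(subs) == 0) return(list(en = "", zh = ""))
  tab <- substituent_tables(g)
  ord <- order(locants)
  subs <- subs[ord]
  locants <- locants[ord]
  list(en = paste0(paste0(locants, "-", tab$en[subs]), collapse = "-"),
       zh = paste0(paste0(locants, "-", tab$zh[subs]), collapse = "-"))
}

# aliphatic core: stem + functional suffix, optional locant
render_core <- function(g, n, suffix, locant = NULL) {
  sfx <- g$suffixes[[suffix]]
  if (suffix == "ane") {
    return(list(en = paste0(g$stems_en[n], "ane"),
                zh = paste0(g$stems_zh[n], sfx[["zh"]])))
  }
  if (is.null(locant)) {
    en <- if (suffix == "oic_acid") paste0(g$stems_en[n], "anoic acid")
          else paste0(g$stems_en[n], "an", sfx[["en"]])
    zh <- paste0(g$stems_zh[n], sfx[["zh"]])
  } else {
    en <- paste0(g$stems_en[n], "an-", locant, "-", sfx[["en"]])
    zh <- paste0(g$stems_zh[n], "-", locant, "-", sfx[["zh"]])
  }
  list(en = en, zh = zh)
}

# full aliphatic name: optional substituent prefixes + core
render_aliphatic <- function(g, n, suffix, locant = NULL,
                             subs = integer(0), sub_locs = integer(0)) {
  pre <- render_prefix(g, subs, sub_locs)
  core <- render_core(g, n, suffix, locant)
  list(en = paste0(pre$en, core$en), zh = paste0(pre$zh, core$zh))
}

# ester: acyl chain length p (with optional substituent prefix); alkyl r
# is a stem index or "ethenyl"; form matters only for unsubstituted p == 2
render_ester <- function(g, p, r, form = c("systematic", "acetate"),
                         acyl_sub = integer(0), acyl_loc = integer(0)) {
  form <- match.arg(form)
  r_en <- if (identical(r, "ethenyl")) g$ethenyl_en
          else paste0(g$stems_en[r], "yl")
  r_zh <- if (identical(r, "ethenyl")) g$ethenyl_zh else g$stems_zh[r]
  pre <- render_prefix(g, acyl_sub, acyl_loc)
  alt <- character(0)
  if (length(acyl_sub) == 0 && p == 2 && form == "acetate") {
    en <- paste(r_en, g$acetate_en)
    zh <- paste0(g$acetic_zh, r_zh, g$ester_char)
    alt <- paste0(g$vinegar_zh, r_zh, g$ester_char)
  } else if (length(acyl_sub) == 0 && p == 2) {
    # systematic English acyl; the corpus's "most used" Chinese rendering
    # of this acid is the trivial one, with the systematic form accepted
    en <- paste(r_en, "ethanoate")
    zh <- paste0(g$vinegar_zh, r_zh, g$ester_char)
    alt <- paste0(g$acetic_zh, r_zh, g$ester_char)
  } else {
    en <- paste(r_en, paste0(pre$en, g$stems_en[p], "anoate"))
    zh <- paste0(pre$zh, g$stems_zh[p],
                 g$suffixes$oic_acid[["zh"]], r_zh, g$ester_char)
  }
  list(en = en, zh = zh, alt = alt)
}

# aromatic family: hydroxyl benzenes and substituted benzenes
render_aromatic <- function(g, kind = c("plain", "ol", "polyol", "sub",
                                        "disub"),
                            locants = NULL, subs = NULL) {
  kind <- match.arg(kind)
  phenol_zh <- g$suffixes$ol_aromatic[["zh"]]
  tab <- substituent_tables(g)
  switch(kind,
    plain = list(en = g$aromatic_en, zh = g$aromatic_zh),
    ol = list(en = paste0(g$aromatic_stem_en, "ol"),
              zh = paste0(g$aromatic_zh, phenol_zh)),
    polyol = {
      k <- length(locants)
      loc <- paste(sort(locants), collapse = ",")
      list(en = paste0(g$aromatic_en, "-", loc, "-",
                       g$multipliers_en[k - 1L], "ol"),
           zh = paste0(g$aromatic_zh, "-", loc, "-",
                       g$multipliers_zh[k - 1L], phenol_zh))
    },
    sub = list(en = paste0(tab$en[subs[1]], g$aromatic_en),
               zh = paste0(tab$zh[subs[1]], g$aromatic_zh)),
    disub = {
      pre <- render_prefix(g, subs, locants)
      list(en = paste0(pre$en, g$aromatic_en),
           zh = paste0(pre$zh, g$aromatic_zh))
    })
}

# aliphatic polyol: stem n, sorted distinct locants (2 or 3 of them)
render_polyol <- function(g, n, locants) {
  k <- length(locants)
  loc <- paste(sort(locants), collapse = ",")
  list(en = paste0(g$stems_en[n], "ane-", loc, "-",
                   g$multipliers_en[k - 1L], "ol"),
       zh = paste0(g$stems_zh[n], g$suffixes$ane[["zh"]], "-", loc, "-",
                   g$multipliers_zh[k - 1L], g$suffixes$ol[["zh"]]))
}

# ---- random generation ---------------------------------------------------

# accepted-variant candidates for a finished pair, most specific first
variant_candidates <- function(g, zh, production, has_prefix, locant) {
  out <- character(0)
  if (grepl(g$alkyl_group_char, zh, fixed = TRUE)) {
    # alkyl 基 elision: 2-甲基己烷 is also written 2-甲己烷;
    # likewise 乙烯基酯 vs 乙烯酯
    out <- c(out, gsub(g$alkyl_group_char, "", zh, fixed = TRUE))
  }
  if (production == "aliphatic" && !has_prefix && !is.null(locant)) {
    # locant-fronted form: 己-2-醇 is also written 2-己醇
    out <- c(out, paste0(locant, "-", gsub("-", "", zh, fixed = TRUE)))
  }
  if (production == "aliphatic" && !has_prefix && is.null(locant)) {
    out <- c(out, paste0(g$normal_prefix_zh, zh))  # 正己烷 for 己烷
  }
  setdiff(unique(out), zh)
}

draw_tag <- function(g, trivial = FALSE) {
  if (trivial) return("trivial")
  sample(names(g$tag_weights), 1L, prob = g$tag_weights)
}

#' Generate one synthetic name pair
#'
#' Draws one production from the grammar mixture using R's current random
#' number stream (seed it, or use [generate_corpus()] which seeds for
#' you).
#'
#' @param grammar A `synthetic_grammar`.
#' @return A list with fields `source` (English), `target` (Chinese),
#'   `alt_targets` (character vector), `naming_system`, `production`.
#' @export
generate_pair <- function(grammar) {
  g <- grammar
  fam <- sample(names(g$production_weights), 1L,
                prob = g$production_weights)
  alt <- character(0)
  trivial <- FALSE
  has_prefix <- FALSE
  locant <- NULL
  pair <- switch(fam,
    aliphatic = {
      n <- sample.int(10L, 1L)
      suffix <- sample(names(g$core_suffix_weights), 1L,
                       prob = g$core_suffix_weights)
      if (suffix %in% c("ol", "one") && stats::runif(1) < g$locant_prob) {
        locant <- sample(2:9, 1L)
      }
      k <- sample(0:2, 1L, prob = g$prefix_probs)
      has_prefix <- k > 0
      subs <- if (k > 0) sample.int(13L, k, replace = TRUE) else integer(0)
      sub_locs <- if (k > 0) sample(setdiff(2:9, locant), k) else integer(0)
      render_aliphatic(g, n, suffix, locant, subs, sub_locs)
    },
    ester = {
      p_len <- sample.int(10L, 1L)
      r <- if (stats::runif(1) < 1 / 11) "ethenyl" else sample.int(10L, 1L)
      if (stats::runif(1) < g$acyl_prefix_prob) {
        p_len <- sample(3:10, 1L)
        p <- render_ester(g, p_len, r,
                          acyl_sub = sample.int(13L, 1L),
                          acyl_loc = sample(2:9, 1L))
      } else {
        form <- "systematic"
        if (p_len == 2 && stats::runif(1) < g$acetate_prob) {
          form <- "acetate"
          trivial <- TRUE
        }
        p <- render_ester(g, p_len, r, form)
      }
      alt <- p$alt
      p
    },
    aromatic = {
      kind <- sample(names(g$aromatic_kind_weights), 1L,
                     prob = g$aromatic_kind_weights)
      switch(kind,
        plain = render_aromatic(g, "plain"),
        ol = render_aromatic(g, "ol"),
        polyol = render_aromatic(g, "polyol",
                                 locants = sample(1:6, sample(2:3, 1L))),
        sub = render_aromatic(g, "sub", subs = sample.int(13L, 1L)),
        disub = render_aromatic(g, "disub",
                                locants = sample(1:6, 2L),
                                subs = sample.int(13L, 2L, replace = TRUE)))
    },
    polyol = {
      n <- sample(2:10, 1L)
      render_polyol(g, n, locants = sample(1:9, sample(2:3, 1L)))
    })
  if (length(alt) == 0 && stats::runif(1) < g$alt_prob) {
    cand <- variant_candidates(g, pair$zh, fam, has_prefix, locant)
    if (length(cand) > 0) alt <- cand[1]
  }
  list(source = pair$en, target = pair$zh, alt_targets = alt,
       naming_system = draw_tag(g, trivial), production = fam)
}

#' Generate a deterministic synthetic parallel corpus
#'
#' Draws pairs until `n` unique (source, target) combinations are
#' collected (or an attempt cap is reached), so the returned corpus is
#' already deduplicated.  Output is a deterministic function of the
#' grammar, `n` and `seed`.  Generated pairs are English-to-Chinese; use
#' [reverse_direction()] for the other direction.
#'
#' @param grammar A `synthetic_grammar`.
#' @param n Number of unique pairs requested.
#' @param seed Integer seed.
#' @param max_attempts Attempt cap before a capacity error (default
#'   `max(1000, 60 * n)`).
#' @return A `parallel_corpus` of `n` pairs with a `productions`
#'   attribute recording each pair's production family.
#' @export
generate_corpus <- function(grammar, n, seed = 1L,
                            max_attempts = max(1000L, 60L * n)) {
  stopifnot(n >= 0)
  if (n == 0) {
    return(parallel_corpus(character(0), character(0), direction = "En2Ch"))
  }
  withr::with_seed(as.integer(seed), {
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    out <- vector("list", n)
    count <- 0L
    attempts <- 0L
    while (count < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- generate_pair(grammar)
      key <- paste(p$source, p$target, sep = "\u0001")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      count <- count + 1L
      out[[count]] <- p
    }
    if (count < n) {
      stop(sprintf(
        "grammar capacity exhausted: %d unique pairs after %d attempts (requested %d)",
        count, attempts, n), call. = FALSE)
    }
    corpus <- parallel_corpus(
      source = vapply(out, `[[`, character(1), "source"),
      target = vapply(out, `[[`, character(1), "target"),
      alt_targets = lapply(out, `[[`, "alt_targets"),
      naming_system = vapply(out, `[[`, character(1), "naming_system"),
      direction = "En2Ch")
    attr(corpus, "productions") <- vapply(out, `[[`, character(1),
                                          "production")
    corpus
  })
}

#' Reverse the direction of a parallel corpus
#'
#' Swaps source and target and flips the direction tag.  Name translation
#' between English and Chinese is not symmetric — a primary translation
#' in one direction is not necessarily the preferred rendering in the
#' other — so a reversed corpus is a mechanical stand-in, not a curated
#' one; a warning of class `chemnmt_reversal_warning` records this
#' caveat.  Alternative-translation sets are carried along unchanged and
#' after reversal describe accepted variants of the new *source* side.
#'
#' @param corpus A `parallel_corpus`.
#' @return The reversed `parallel_corpus`.
#' @export
reverse_direction <- function(corpus) {
  new_dir <- setdiff(CORPUS_DIRECTIONS, corpus_direction(corpus))
  out <- parallel_corpus(corpus$target, corpus$source,
                         naming_system = corpus$naming_system,
                         direction = new_dir)
  out$alt_targets <- corpus$alt_targets
  warning(warningCondition(
    paste("reversed corpus: translation of chemical names is not symmetric;",
          "a reversed training set may be unsuitable for the opposite",
          "direction"),
    class = "chemnmt_reversal_warning"))
  out
}
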