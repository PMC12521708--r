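#' Patient handout rendering and readability scoring
#'
#' The handout presents a taper plan the way patients asked for it: fixed
#' clock times instead of "every N hours", an explicit note on whether to
#' take the tablets with food, the back-up allowance with a plain-language
#' explanation that occasional pain spikes are normal, and a functional
#' goal instead of an abstract pain score. The readability functions
#' (sentence/word/syllable counting, Flesch Reading Ease and its German
#' Amstad recalibration) support iterative simplification of such
#' materials.
#'
#' @name handout
NULL

#' Render a patient-facing taper handout (Markdown)
#'
#' @param plan A `taper_plan`.
#' @param regimens Named list mapping each plan day (as character, `"0"`,
#'   `"1"`, ...) to the `regimen` for that day; must cover every plan day.
#'   Build one with [plan_regimens()].
#' @param locale `"en"` or `"de"` (affects only fixed phrases; the shipped
#'   template is English with German-compatible structure).
#' @param functional_goal One sentence describing the functional goal of the
#'   taper (e.g. climbing stairs unaided).
#' @param backup_drug Name of the back-up opioid shown in the allowance
#'   line.
#' @return Character scalar: the Markdown document. Deterministic for fixed
#'   input.
#' @export
render_handout <- function(plan, regimens, locale = c("en", "de"),
                           functional_goal = "Stay active and increase your daily walking distance.",
                           backup_drug = NULL) {
  locale <- match.arg(locale)
  if (!inherits(plan, "taper_plan")) {
    stop_validation("'plan' must be a taper_plan")
  }
  if (!nrow(plan$steps)) stop_validation("empty plan: nothing to render")
  days <- plan$steps$day
  missing_days <- setdiff(as.character(days), names(regimens))
  if (length(missing_days)) {
    stop_validation(sprintf(
      "no regimen supplied for plan day(s): %s",
      paste(missing_days, collapse = ", ")
    ))
  }
  lines <- c(
    "# Your opioid reduction plan",
    "",
    sprintf("Starting dose: %g mg morphine equivalents per 24 hours.",
            plan$baseline_ome),
    sprintf("Target dose: %g mg morphine equivalents per 24 hours.",
            plan$policy$target_ome),
    "",
    paste("Occasional pain spikes are normal. Your back-up (reserve)",
          "medication is intended for exactly these situations; using it",
          "does not mean the reduction has failed."),
    "",
    sprintf("Your goal: %s", functional_goal),
    ""
  )
  for (i in seq_along(days)) {
    d <- days[i]
    reg <- regimens[[as.character(d)]]
    drug <- attr(reg, "drug")
    with_food <- attr(reg, "with_food")
    food_note <- if (is.null(with_food)) {
      "with or without food"
    } else if (isTRUE(with_food)) "with food" else "without food"
    lines <- c(lines, sprintf("## Day %d", d))
    if (nrow(reg)) {
      for (j in split(seq_len(nrow(reg)), reg$slot)) {
        lines <- c(lines, sprintf(
          "- At %s take %s (%s).", reg$time[j[1L]],
          paste(sprintf("%d tablet(s) of %s %g mg", reg$count[j],
                        drug$name, reg$strength_mg[j]), collapse = " and "),
          food_note
        ))
      }
    } else {
      lines <- c(lines, "- No fixed opioid dose today.")
    }
    bu <- plan$steps$backup_ome[i]
    if (bu > 0) {
      lines <- c(lines, sprintf(
        "- Back-up allowance: up to %g mg morphine equivalents%s if pain spikes.",
        bu,
        if (is.null(backup_drug)) "" else sprintf(" (as %s)", backup_drug)
      ))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Regimens for every day of a plan
#'
#' Maps each day's fixed OME dose back to mg of `drug` and packs it into a
#' tablet regimen; repeated dose levels are solved once.
#'
#' @param plan A `taper_plan`.
#' @param drug Drug name to dispense.
#' @param formulary A [formulary].
#' @param ... Passed to [map_daily_dose()].
#' @return Named list of `regimen` objects keyed by plan day.
#' @export
plan_regimens <- function(plan, drug, formulary, ...) {
  if (!inherits(plan, "taper_plan")) {
    stop_validation("'plan' must be a taper_plan")
  }
  sp <- lookup_opioid(drug, formulary)
  cache <- list()
  out <- lapply(seq_len(nrow(plan$steps)), function(i) {
    ome <- plan$steps$fixed_ome[i]
    key <- format(ome, digits = 12)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- map_daily_dose(from_ome(drug, ome, formulary), sp, ...)
    }
    cache[[key]]
  })
  names(out) <- as.character(plan$steps$day)
  out
}

abbrev_guard <- list(
  en = c("Dr.", "Mr.", "Mrs.", "Ms.", "Prof.", "e.g.", "i.e.", "etc.",
         "vs.", "approx.", "min.", "max.", "No."),
  de = c("z.B.", "z. B.", "bzw.", "ca.", "Dr.", "ggf.", "usw.", "u.a.",
         "d.h.", "d. h.", "evtl.", "inkl.", "Nr.", "bzgl.", "ggfs.",
         "mind.", "Tbl.")
)

vowel_sets <- list(en = "aeiouy", de = "aeiouy\u00e4\u00f6\u00fc")

#' Count sentences, words and syllables in a text
#'
#' Deterministic, documented counting rules so readability scores are
#' bit-reproducible: sentences are segments delimited by `.`, `!` or `?`
#' (with a per-locale abbreviation guard list); words are
#' whitespace-delimited tokens that retain at least one letter or digit
#' after punctuation stripping; syllables are maximal vowel-letter runs per
#' word (vowel sets: `aeiouy` for English, plus umlauts for German;
#' adjacent vowels — diphthongs like *ei*, *au* — count once), with the
#' English silent final *e* removed and a minimum of one syllable per word.
#'
#' @param text Non-empty character scalar.
#' @param locale `"en"` or `"de"`.
#' @return Named integer vector `c(sentences, words, syllables)`.
#' @examples
#' count_text_units("Hello world. Bye.", "en") # 2 sentences, 3 words, 4 syllables
#' @export
count_text_units <- function(text, locale = c("en", "de")) {
  locale <- match.arg(locale)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop_validation("'text' must be a non-empty string")
  }
  guarded <- text
  for (ab in abbrev_guard[[locale]]) {
    guarded <- gsub(ab, gsub(".", "\u2024", ab, fixed = TRUE), guarded,
                    fixed = TRUE)
  }
  segs <- strsplit(guarded, "[.!?]+")[[1L]]
  sentences <- sum(grepl("[[:alnum:]]", segs))
  tokens <- strsplit(gsub("\\s+", " ", trimws(guarded)), " ")[[1L]]
  tokens <- gsub("[^[:alnum:]\u2024'\u00e4\u00f6\u00fc\u00c4\u00d6\u00dc\u00df-]", "", tokens)
  words <- tokens[grepl("[[:alnum:]\u00e4\u00f6\u00fc\u00c4\u00d6\u00dc\u00df]", tokens)]
  syllables <- sum(vapply(words, count_syllables, integer(1L),
                          vowels = vowel_sets[[locale]],
                          silent_e = locale == "en"))
  c(sentences = as.integer(sentences), words = length(words),
    syllables = as.integer(syllables))
}

count_syllables <- function(word, vowels, silent_e) {
  w <- tolower(gsub("[^[:alpha:]\u00e4\u00f6\u00fc\u00df]", "", word))
  if (!nzchar(w)) return(1L)
  chars <- strsplit(w, "")[[1L]]
  is_vowel <- chars %in% strsplit(vowels, "")[[1L]]
  groups <- sum(is_vowel & !c(FALSE, is_vowel[-length(is_vowel)]))
  n <- length(chars)
  if (silent_e && groups > 1L && n >= 2L &&
      chars[n] == "e" && !is_vowel[n - 1L] &&
      !(n >= 2L && chars[n - 1L] == "l" && n >= 3L && !is_vowel[n - 2L])) {
    groups <- groups - 1L
  }
  max(groups, 1L)
}

#' Flesch Reading Ease and Amstad (German) readability score
#'
#' `flesch_en`: 206.835 - 1.015 (words/sentences) - 84.6 (syllables/words).
#' `amstad_de`: 180 - (words/sentences) - 58.5 (syllables/words).
#' Higher scores mean easier text; both variants decrease in average
#' sentence length and syllables per word.
#'
#' @param counts Numeric vector `c(sentences, words, syllables)` as from
#'   [count_text_units()]; sentences and words must be >= 1.
#' @param variant `"flesch_en"` or `"amstad_de"`.
#' @return Numeric score.
#' @examples
#' flesch_score(c(1, 1, 1), "flesch_en") # 121.22
#' flesch_score(c(1, 1, 1), "amstad_de") # 120.5
#' @export
flesch_score <- function(counts, variant = c("flesch_en", "amstad_de")) {
  variant <- match.arg(variant)
  if (length(counts) != 3L || !is.numeric(counts)) {
    stop_validation("'counts' must be c(sentences, words, syllables)")
  }
  s <- counts[[1L]]; w <- counts[[2L]]; sy <- counts[[3L]]
  if (s < 1 || w < 1) {
    stop_validation("sentences and words must both be >= 1")
  }
  asl <- w / s
  asw <- sy / w
  switch(variant,
    flesch_en = 206.835 - 1.015 * asl - 84.6 * asw,
    amstad_de = 180 - asl - 58.5 * asw
  )
}

#' Readability report for a text
#'
#' @param text Non-empty string.
#' @param locale `"en"` (scored with `flesch_en`) or `"de"` (scored with
#'   the Amstad recalibration, `amstad_de`). The variant is always carried
#'   in the report: a score is uninterpretable without it.
#' @return A `readability_report`: sentences, words, syllables, score,
#'   variant.
#' @export
readability_report <- function(text, locale = c("en", "de")) {
  locale <- match.arg(locale)
  counts <- count_text_units(text, locale)
  variant <- if (locale == "en") "flesch_en" else "amstad_de"
  structure(
    list(sentences = counts[["sentences"]], words = counts[["words"]],
         syllables = counts[["syllables"]],
         score = flesch_score(counts, variant), variant = variant),
    class = "readability_report"
  )
}

#' @export
print.readability_report <- function(x, ...) {
  cat(sprintf(
    "<readability_report> %s score %.2f (%d sentences, %d words, %d syllables)\n",
    x$variant, x$score, x$sentences, x$words, x$syllables
  ))
  invisible(x)
}

#' Change in text statistics between two drafts
#'
#' Reports absolute and percent changes in sentence, word and syllable
#' counts (percent relative to the earlier draft, rounded to the nearest
#' integer), as used to track simplification of patient materials.
#'
#' @param before,after `readability_report` objects of the same variant.
#' @return Named list: `sentences`, `words`, `syllables`, each
#'   `c(delta, pct)`.
#' @export
readability_delta <- function(before, after) {
  for (r in list(before, after)) {
    if (!inherits(r, "readability_report")) {
      stop_validation("'before'/'after' must be readability_report objects")
    }
  }
  if (before$variant != after$variant) {
    stop_validation(sprintf("variant mismatch: %s vs %s",
                            before$variant, after$variant))
  }
  one <- function(field) {
    d <- after[[field]] - before[[field]]
    c(delta = d, pct = round(100 * d / before[[field]]))
  }
  list(sentences = one("sentences"), words = one("words"),
       syllables = one("syllables"))
}
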