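#' LexTALE language-proficiency score
#'
#' The LexTALE lexical-decision test presents 40 real words and 20
#' pseudowords. Its score averages the percentage correct in the two string
#' classes: `((2.5 * words_correct) + (5 * nonwords_correct)) / 2`, a value
#' in 0-100. Participants are included when the score strictly exceeds 70.
#'
#' @param words_correct Integer(s) in 0-40.
#' @param nonwords_correct Integer(s) in 0-20.
#' @param inclusion_cutoff Score above which a participant is included.
#' @return A tibble with `words_correct`, `nonwords_correct`, `score`,
#'   `included`.
#' @examples
#' lextale_score(30, 15) # score 75, included
#' @export
lextale_score <- function(words_correct, nonwords_correct,
                          inclusion_cutoff = 70) {
  w <- words_correct; nw <- nonwords_correct
  if (length(w) != length(nw)) {
    abort("`words_correct` and `nonwords_correct` must have equal length.")
  }
  ok_int <- function(x) is.numeric(x) && all(!is.na(x)) && all(x == round(x))
  if (!ok_int(w) || any(w < 0 | w > 40)) {
    abort("`words_correct` must be integers in 0-40.")
  }
  if (!ok_int(nw) || any(nw < 0 | nw > 20)) {
    abort("`nonwords_correct` must be integers in 0-20.")
  }
  score <- ((2.5 * w) + (5 * nw)) / 2
  tibble(
    words_correct = as.integer(w),
    nonwords_correct = as.integer(nw),
    score = score,
    included = score > inclusion_cutoff
  )
}

#' Arcsine-square-root transform for proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilising transform for
#' proportions; used as a robustness check when modelling partial-press
#' frequencies.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed values in \[0, pi/2\].
#' @export
arcsine_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  asin(sqrt(p))
}
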