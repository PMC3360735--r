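# Classic Porter (1980) suffix-stripping stemmer, pure R.
# Implemented here because stem-sequence matching is the package's keyword
# matching primitive; follows the original five-step definition with
# longest-match-wins semantics inside each rule group.

.p_vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel pattern of a word; "y" is a vowel when preceded by a
# consonant, a consonant at word start or after a vowel
.p_cvpat <- function(letters) {
  n <- length(letters)
  out <- character(n)
  for (i in seq_len(n)) {
    ch <- letters[i]
    if (ch %in% .p_vowels) {
      out[i] <- "v"
    } else if (ch == "y") {
      out[i] <- if (i > 1L && out[i - 1L] == "c") "v" else "c"
    } else {
      out[i] <- "c"
    }
  }
  out
}

.p_letters <- function(w) strsplit(w, "", fixed = TRUE)[[1L]]

# measure m: number of vowel->consonant transitions in [C](VC)^m[V]
.p_m <- function(w) {
  p <- .p_cvpat(.p_letters(w))
  n <- length(p)
  if (n < 2L) return(0L)
  sum(p[-n] == "v" & p[-1L] == "c")
}

.p_has_vowel <- function(w) any(.p_cvpat(.p_letters(w)) == "v")

.p_double_c <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  substr(w, n - 1L, n - 1L) == substr(w, n, n) &&
    .p_cvpat(.p_letters(w))[n] == "c"
}

# *o condition: ends consonant-vowel-consonant, final letter not w, x or y
.p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  p <- .p_cvpat(.p_letters(w))
  p[n] == "c" && p[n - 1L] == "v" && p[n - 2L] == "c" &&
    !(substr(w, n, n) %in% c("w", "x", "y"))
}

.p_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

.p_step1a <- function(w) {
  if (endsWith(w, "sses")) return(.p_chop(w, 2L))
  if (endsWith(w, "ies")) return(.p_chop(w, 2L))
  if (endsWith(w, "ss")) return(w)
  if (endsWith(w, "s")) return(.p_chop(w, 1L))
  w
}

.p_step1b <- function(w) {
  if (endsWith(w, "eed")) {
    if (.p_m(.p_chop(w, 3L)) > 0L) w <- .p_chop(w, 1L)
    return(w)
  }
  fired <- FALSE
  if (endsWith(w, "ed") && .p_has_vowel(.p_chop(w, 2L))) {
    w <- .p_chop(w, 2L); fired <- TRUE
  } else if (endsWith(w, "ing") && .p_has_vowel(.p_chop(w, 3L))) {
    w <- .p_chop(w, 3L); fired <- TRUE
  }
  if (fired) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_c(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .p_chop(w, 1L)
    } else if (.p_m(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.p_step1c <- function(w) {
  if (endsWith(w, "y") && .p_has_vowel(.p_chop(w, 1L))) {
    w <- paste0(.p_chop(w, 1L), "i")
  }
  w
}

# suffix tables; within a step the first (longest-compatible) matching suffix
# decides, and its m-condition is final even when it fails
.p_step2_suf <- c("ational", "tional", "enci", "anci", "izer", "abli",
                  "alli", "entli", "eli", "ousli", "ization", "ation",
                  "ator", "alism", "iveness", "fulness", "ousness",
                  "aliti", "iviti", "biliti")
.p_step2_rep <- c("ate", "tion", "ence", "ance", "ize", "able",
                  "al", "ent", "e", "ous", "ize", "ate",
                  "ate", "al", "ive", "ful", "ous",
                  "al", "ive", "ble")

.p_step3_suf <- c("icate", "ative", "alize", "iciti", "ical", "ful", "ness")
.p_step3_rep <- c("ic", "", "al", "ic", "ic", "", "")

.p_step4_suf <- c("ement", "ment", "ent", "al", "ance", "ence", "er", "ic",
                  "able", "ible", "ant", "ion", "ou", "ism", "ate", "iti",
                  "ous", "ive", "ize")

.p_replace <- function(w, sufs, reps, mmin) {
  for (i in seq_along(sufs)) {
    if (endsWith(w, sufs[i])) {
      stem <- .p_chop(w, nchar(sufs[i]))
      if (.p_m(stem) > mmin) w <- paste0(stem, reps[i])
      return(w)
    }
  }
  w
}

.p_step4 <- function(w) {
  for (suf in .p_step4_suf) {
    if (endsWith(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      ok <- .p_m(stem) > 1L
      if (suf == "ion") {
        ok <- ok && (endsWith(stem, "s") || endsWith(stem, "t"))
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

.p_step5 <- function(w) {
  if (endsWith(w, "e")) {
    stem <- .p_chop(w, 1L)
    m <- .p_m(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }
  if (.p_m(w) > 1L && .p_double_c(w) && endsWith(w, "l")) {
    w <- .p_chop(w, 1L)
  }
  w
}

.p_stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)
  w <- .p_step1a(w)
  w <- .p_step1b(w)
  w <- .p_step1c(w)
  w <- .p_replace(w, .p_step2_suf, .p_step2_rep, 0L)
  w <- .p_replace(w, .p_step3_suf, .p_step3_rep, 0L)
  w <- .p_step4(w)
  .p_step5(w)
}

#' Porter stem of lowercase word tokens
#'
#' Reduces English words to their morphological roots with the classic Porter
#' suffix-stripping algorithm, so that e.g. `"cancers"` and `"cancer"`, or
#' `"smoking"` and `"smoked"`, collapse to a common stem. Inputs are assumed
#' lowercase; words of two letters or fewer are returned unchanged.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("cancers", "smoking", "generalization"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0L) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .p_stem1, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}
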