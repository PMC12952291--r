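#' Porter stemming
#'
#' Reduces English words to their stems using the classic Porter (1980)
#' suffix-stripping algorithm: five ordered rule groups conditioned on the
#' consonant-vowel "measure" of the stem. Used by the `bm25plus` backend mode,
#' which indexes stemmed, stop-word-free tokens.
#'
#' @param words Character vector of lower-case word tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("relational", "hopping", "ponies", "happy"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# Letter classes: a letter is a consonant unless it is a,e,i,o,u, or a y that
# follows a consonant. Returns a logical vector, TRUE = consonant.
porter_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  if (n > 1) {
    for (i in 2:n) {
      if (chars[i] == "y" && cons[i - 1]) cons[i] <- FALSE
    }
  }
  cons
}

# The measure m of a word: number of VC alternations in [C](VC)^m[V].
porter_measure <- function(word) {
  chars <- strsplit(word, "")[[1]]
  if (length(chars) == 0) return(0L)
  cons <- porter_cons(chars)
  runs <- rle(cons)$values
  # count VC pairs: every FALSE (vowel run) followed by TRUE (consonant run)
  if (length(runs) < 2) return(0L)
  sum(!runs[-length(runs)] & runs[-1])
}

porter_has_vowel <- function(word) {
  chars <- strsplit(word, "")[[1]]
  any(!porter_cons(chars))
}

porter_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  porter_cons(chars)[n]
}

# *o condition: stem ends cvc where the final c is not w, x, or y.
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  cons <- porter_cons(chars)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(chars[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1, n) == suffix
}

porter_chop <- function(word, k) substr(word, 1, nchar(word) - k)

# Apply the first matching (suffix -> replacement) rule whose stem satisfies
# the measure condition; returns the (possibly unchanged) word.
porter_rule_set <- function(word, rules, min_m) {
  for (r in rules) {
    if (porter_ends(word, r[[1]])) {
      stem <- porter_chop(word, nchar(r[[1]]))
      if (porter_measure(stem) > min_m) word <- paste0(stem, r[[2]])
      return(word)
    }
  }
  word
}

porter_stem1 <- function(word) {
  if (nchar(word) <= 2) return(word)

  # Step 1a
  if (porter_ends(word, "sses")) {
    word <- porter_chop(word, 2)
  } else if (porter_ends(word, "ies")) {
    word <- paste0(porter_chop(word, 3), "i")
  } else if (!porter_ends(word, "ss") && porter_ends(word, "s")) {
    word <- porter_chop(word, 1)
  }

  # Step 1b
  if (porter_ends(word, "eed")) {
    if (porter_measure(porter_chop(word, 3)) > 0) word <- porter_chop(word, 1)
  } else {
    stripped <- FALSE
    if (porter_ends(word, "ed") && porter_has_vowel(porter_chop(word, 2))) {
      word <- porter_chop(word, 2); stripped <- TRUE
    } else if (porter_ends(word, "ing") && porter_has_vowel(porter_chop(word, 3))) {
      word <- porter_chop(word, 3); stripped <- TRUE
    }
    if (stripped) {
      if (porter_ends(word, "at") || porter_ends(word, "bl") || porter_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (porter_ends_double_cons(word) &&
                 !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
        word <- porter_chop(word, 1)
      } else if (porter_measure(word) == 1 && porter_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (porter_ends(word, "y") && porter_has_vowel(porter_chop(word, 1))) {
    word <- paste0(porter_chop(word, 1), "i")
  }

  # Step 2 (m > 0)
  word <- porter_rule_set(word, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")
  ), 0L)

  # Step 3 (m > 0)
  word <- porter_rule_set(word, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""), list("ness", "")
  ), 0L)

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (porter_ends(word, suf)) {
      stem <- porter_chop(word, nchar(suf))
      ok <- porter_measure(stem) > 1
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (porter_ends(word, "e")) {
    stem <- porter_chop(word, 1)
    m <- porter_measure(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) word <- stem
  }

  # Step 5b
  if (porter_measure(word) > 1 && porter_ends_double_cons(word) &&
      porter_ends(word, "l")) {
    word <- porter_chop(word, 1)
  }

  word
}
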