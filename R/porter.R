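# Porter's suffix-stripping algorithm (the original 1980 definition).
# No stemming package ships with the environments this package targets, so
# the algorithm is implemented here in full; the test suite pins it to the
# per-step examples published with the algorithm definition.

.porter_vowels <- c("a", "e", "i", "o", "u")

# consonant test at position i; "y" is a consonant at word start or after a
# vowel, a vowel after a consonant
.p_cons <- function(b, i) {
  l <- b[i]
  if (l %in% .porter_vowels) return(FALSE)
  if (l == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_cons(b, i - 1L))
  }
  TRUE
}

.p_flags <- function(b) vapply(seq_along(b), function(i) .p_cons(b, i), logical(1))

# the measure m in the [C](VC)^m[V] decomposition
.p_measure <- function(b) {
  if (length(b) == 0L) return(0L)
  runs <- rle(.p_flags(b))$values
  sum(!runs[-length(runs)] & runs[-1L])
}

.p_has_vowel <- function(b) length(b) > 0L && any(!.p_flags(b))

.p_double_cons <- function(b) {
  n <- length(b)
  n >= 2L && b[n] == b[n - 1L] && .p_cons(b, n)
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w,x,y
.p_cvc <- function(b) {
  n <- length(b)
  n >= 3L && .p_cons(b, n) && !.p_cons(b, n - 1L) && .p_cons(b, n - 2L) &&
    !(b[n] %in% c("w", "x", "y"))
}

.p_ends <- function(w, suf) {
  nc <- nchar(w)
  ns <- nchar(suf)
  nc >= ns && substring(w, nc - ns + 1L, nc) == suf
}

.p_chop <- function(w, k) substring(w, 1L, nchar(w) - k)

.p_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1L]]

# rule tables: suffix -> replacement, longest/most specific first
.porter_step2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

.porter_step3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.porter_step4 <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement", "ment",
  "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter_one <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  # step 1a: plurals
  if (.p_ends(w, "sses")) {
    w <- .p_chop(w, 2L)
  } else if (.p_ends(w, "ies")) {
    w <- .p_chop(w, 2L)
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- .p_chop(w, 1L)
  }

  # step 1b: -eed / -ed / -ing
  cleanup <- FALSE
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_chars(.p_chop(w, 3L))) > 0L) w <- .p_chop(w, 1L)
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_chars(.p_chop(w, 2L)))) {
    w <- .p_chop(w, 2L)
    cleanup <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_chars(.p_chop(w, 3L)))) {
    w <- .p_chop(w, 3L)
    cleanup <- TRUE
  }
  if (cleanup) {
    b <- .p_chars(w)
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(b) && !(b[length(b)] %in% c("l", "s", "z"))) {
      w <- .p_chop(w, 1L)
    } else if (.p_measure(b) == 1L && .p_cvc(b)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: y -> i after a stem containing a vowel
  if (.p_ends(w, "y") && .p_has_vowel(.p_chars(.p_chop(w, 1L)))) {
    w <- paste0(.p_chop(w, 1L), "i")
  }

  # steps 2 and 3: double-suffix reduction, condition m(stem) > 0
  for (tab in list(.porter_step2, .porter_step3)) {
    for (rule in tab) {
      if (.p_ends(w, rule[[1L]])) {
        stem <- .p_chop(w, nchar(rule[[1L]]))
        if (.p_measure(.p_chars(stem)) > 0L) w <- paste0(stem, rule[[2L]])
        break
      }
    }
  }

  # step 4: strip residual suffix when m(stem) > 1
  for (suf in .porter_step4) {
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      ok <- .p_measure(.p_chars(stem)) > 1L
      if (suf == "ion") ok <- ok && (.p_ends(stem, "s") || .p_ends(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop trailing e
  if (.p_ends(w, "e")) {
    stem <- .p_chars(.p_chop(w, 1L))
    mm <- .p_measure(stem)
    if (mm > 1L || (mm == 1L && !.p_cvc(stem))) w <- .p_chop(w, 1L)
  }

  # step 5b: -ll -> -l when m > 1
  b <- .p_chars(w)
  if (.p_measure(b) > 1L && .p_double_cons(b) && b[length(b)] == "l") {
    w <- .p_chop(w, 1L)
  }

  w
}

#' Porter stemmer
#'
#' Reduces English words to stems with the classic suffix-stripping
#' algorithm.  Input is expected lowercase; tokens containing characters
#' outside `a-z` (numbers, coded vocabulary such as `"w0017"`) and tokens of
#' one or two characters are returned unchanged.
#'
#' @param words character vector of lowercase word tokens.
#' @return character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("colds", "relational", "hopping", "agreement"))
porter_stem <- function(words) {
  vapply(words, .porter_one, character(1), USE.NAMES = FALSE)
}
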