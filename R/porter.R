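# Porter suffix-stripping stemmer (classic 1980 algorithm).
#
# Written against the published rule tables; within each rule block only the
# longest matching suffix is considered, and words of length <= 2 are left
# unchanged, matching the reference implementations. Letters are classified
# consonant/vowel with 'y' treated as a vowel exactly when preceded by a
# consonant (or word-initial 'y' a consonant).

p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!p_is_cons(chars, i - 1L))
  }
  TRUE
}

# consonant/vowel mask for a word, TRUE = consonant
p_mask <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  m <- logical(n)
  for (i in seq_len(n)) m[i] <- p_is_cons(chars, i)
  m
}

# the measure m: number of VC sequences in the word
p_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- p_mask(word)
  # collapse runs, count V-followed-by-C transitions
  runs <- rle(cons)$values
  sum(runs[-length(runs)] == FALSE & runs[-1L] == TRUE)
}

p_has_vowel <- function(word) {
  nzchar(word) && any(!p_mask(word))
}

p_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  a == b && p_mask(word)[n]
}

# *o: stem ends cvc where the final consonant is not w, x or y
p_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- p_mask(word)
  if (!(cons[n] && !cons[n - 1L] && cons[n - 2L])) return(FALSE)
  !substr(word, n, n) %in% c("w", "x", "y")
}

p_chop <- function(word, n_off) substr(word, 1L, nchar(word) - n_off)

# longest suffix of `word` present in `sufs`; "" if none
p_longest_suffix <- function(word, sufs) {
  hits <- sufs[vapply(sufs, function(s) endsWith(word, s), logical(1L))]
  if (!length(hits)) return("")
  hits[which.max(nchar(hits))]
}

p_step1ab <- function(w) {
  if (endsWith(w, "sses")) {
    w <- p_chop(w, 2L)
  } else if (endsWith(w, "ies")) {
    w <- paste0(p_chop(w, 3L), "i")
  } else if (endsWith(w, "s") && !endsWith(w, "ss")) {
    w <- p_chop(w, 1L)
  }
  if (endsWith(w, "eed")) {
    if (p_measure(p_chop(w, 3L)) > 0L) w <- p_chop(w, 1L)
  } else {
    fired <- FALSE
    if (endsWith(w, "ed") && p_has_vowel(p_chop(w, 2L))) {
      w <- p_chop(w, 2L); fired <- TRUE
    } else if (endsWith(w, "ing") && p_has_vowel(p_chop(w, 3L))) {
      w <- p_chop(w, 3L); fired <- TRUE
    }
    if (fired) {
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (p_ends_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- p_chop(w, 1L)
      } else if (p_measure(w) == 1L && p_ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }
  w
}

p_step1c <- function(w) {
  if (endsWith(w, "y") && p_has_vowel(p_chop(w, 1L))) {
    w <- paste0(p_chop(w, 1L), "i")
  }
  w
}

P_STEP2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")

P_STEP3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")

P_STEP4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")

p_apply_map <- function(w, map, min_m) {
  suf <- p_longest_suffix(w, names(map))
  if (!nzchar(suf)) return(w)
  stem <- p_chop(w, nchar(suf))
  if (p_measure(stem) >= min_m) w <- paste0(stem, map[[suf]])
  w
}

p_step4 <- function(w) {
  suf <- p_longest_suffix(w, P_STEP4)
  if (!nzchar(suf)) return(w)
  stem <- p_chop(w, nchar(suf))
  if (suf == "ion" &&
      !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
    return(w)
  }
  if (p_measure(stem) > 1L) w <- stem
  w
}

p_step5 <- function(w) {
  if (endsWith(w, "e")) {
    stem <- p_chop(w, 1L)
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_ends_cvc(stem))) w <- stem
  }
  if (endsWith(w, "l") && p_ends_double_cons(w) && p_measure(w) > 1L) {
    w <- p_chop(w, 1L)
  }
  w
}

#' Porter stem of a single lowercase token
#'
#' The suffix-stripping algorithm used by the metadata full-text index:
#' inflected English word forms collapse onto a common stem (for example
#' \code{"antibiotics"}, \code{"antibiotic"} and a hypothetical
#' \code{"antibiotically"} all stem to \code{"antibiot"}), so a single index
#' key retrieves samples however the annotator worded the value.
#'
#' @param word Character vector of tokens; each is lowercased and stemmed
#'   independently. Tokens of length 2 or less are returned unchanged.
#' @return Character vector of stems, same length as \code{word}.
#' @export
#' @examples
#' porter_stem(c("Antibiotics", "saline", "soils"))
porter_stem <- function(word) {
  vapply(tolower(as.character(word)), function(w) {
    if (is.na(w) || nchar(w) <= 2L) return(w)
    w <- p_step1ab(w)
    w <- p_step1c(w)
    w <- p_apply_map(w, P_STEP2, 1L)
    w <- p_apply_map(w, P_STEP3, 1L)
    w <- p_step4(w)
    w <- p_step5(w)
    w
  }, character(1L), USE.NAMES = FALSE)
}
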