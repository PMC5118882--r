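#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b`. Vectorized over pairs; either argument may be
#' length 1 and is recycled.
#'
#' @param a,b character vectors.
#' @return integer vector of edit distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  .lev_cpp(as.character(a), as.character(b))
}

#' Jaro-Winkler similarity
#'
#' Jaro similarity boosted by a common-prefix term of up to four characters:
#' `jw = jaro + l * p * (1 - jaro)` where `l` is the shared-prefix length and
#' `p` the prefix weight. Symmetric in its arguments; returns values in
#' \[0, 1\] with 1 for identical strings.
#'
#' @param a,b character vectors.
#' @param prefix_weight prefix scaling factor `p`, at most 0.25 so the score
#'   cannot exceed 1.
#' @return numeric vector of similarities.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # ~0.961
#' @export
jaro_winkler <- function(a, b, prefix_weight = 0.1) {
  .jw_cpp(as.character(a), as.character(b), prefix_weight)
}

#' Original Metaphone phonetic encoding
#'
#' Encodes the alphabetic content of a string into the original Metaphone
#' consonant-sound code. Non-alphabetic characters are ignored; a string with
#' no letters encodes to `""`. Vowels are emitted only in initial position,
#' and the sixteen consonant classes (including `0` for the th-sound and `X`
#' for sh/ch) follow the published transformation table.
#'
#' @param s character vector.
#' @return character vector of phonetic codes.
#' @examples
#' metaphone("Hemoglobin") == metaphone("Haemoglobin")
#' @export
metaphone <- function(s) {
  vapply(as.character(s), metaphone_one, character(1), USE.NAMES = FALSE)
}

metaphone_one <- function(s) {
  if (is.na(s)) return(NA_character_)
  w <- toupper(gsub("[^A-Za-z]", "", s))
  if (nchar(w) == 0) return("")
  ch <- strsplit(w, "", fixed = TRUE)[[1]]

  # initial-letter exceptions
  first2 <- paste(ch[seq_len(min(2, length(ch)))], collapse = "")
  if (first2 %in% c("AE", "GN", "KN", "PN", "WR")) {
    ch <- ch[-1]
  } else if (ch[1] == "X") {
    ch[1] <- "S"
  } else if (first2 == "WH") {
    ch <- c("W", ch[-(1:2)])  # WH- sounds as W
  }
  n <- length(ch)
  if (n == 0) return("")

  vowels <- c("A", "E", "I", "O", "U")
  is_vowel <- function(i) i >= 1 && i <= n && ch[i] %in% vowels
  out <- character(0)
  i <- 1
  while (i <= n) {
    c0 <- ch[i]
    prev <- if (i > 1) ch[i - 1] else ""
    nxt <- if (i < n) ch[i + 1] else ""
    nxt2 <- if (i + 2 <= n) ch[i + 2] else ""

    # duplicate adjacent letters collapse, except C (as in "accept")
    if (c0 == prev && c0 != "C") {
      i <- i + 1
      next
    }

    if (c0 %in% vowels) {
      if (i == 1) out <- c(out, c0)
      i <- i + 1
    } else if (c0 == "B") {
      if (!(i == n && prev == "M")) out <- c(out, "B")
      i <- i + 1
    } else if (c0 == "C") {
      if (prev == "S" && nxt %in% c("I", "E", "Y")) {
        i <- i + 1  # silent in SCI/SCE/SCY
      } else if (nxt == "I" && nxt2 == "A") {
        out <- c(out, "X"); i <- i + 1
      } else if (nxt == "H") {
        out <- c(out, if (prev == "S") "K" else "X")
        i <- i + 2  # consume the H
      } else if (nxt %in% c("I", "E", "Y")) {
        out <- c(out, "S"); i <- i + 1
      } else {
        out <- c(out, "K"); i <- i + 1
      }
    } else if (c0 == "D") {
      if (nxt == "G" && nxt2 %in% c("E", "Y", "I")) {
        out <- c(out, "J"); i <- i + 2  # consume the G
      } else {
        out <- c(out, "T"); i <- i + 1
      }
    } else if (c0 == "G") {
      if (nxt == "H") {
        if (i + 2 <= n && is_vowel(i + 2)) {
          out <- c(out, "K")  # "ghost"
        }                     # else GH silent ("weight", "laugh")
        i <- i + 2
      } else if (nxt == "N") {
        # silent in -GN at end and -GNED
        at_end <- (i + 1 == n)
        gned <- (i + 3 == n && nxt2 == "E" && ch[i + 3] == "D")
        if (!at_end && !gned) out <- c(out, "K")
        i <- i + 1
      } else if (nxt %in% c("I", "E", "Y")) {
        out <- c(out, "J"); i <- i + 1
      } else {
        out <- c(out, "K"); i <- i + 1
      }
    } else if (c0 == "H") {
      # silent after a vowel when no vowel follows
      if (!(is_vowel(i - 1) && !is_vowel(i + 1))) out <- c(out, "H")
      i <- i + 1
    } else if (c0 == "K") {
      if (prev != "C") out <- c(out, "K")
      i <- i + 1
    } else if (c0 == "P") {
      if (nxt == "H") { out <- c(out, "F"); i <- i + 2 }
      else { out <- c(out, "P"); i <- i + 1 }
    } else if (c0 == "Q") {
      out <- c(out, "K"); i <- i + 1
    } else if (c0 == "S") {
      if (nxt == "H") { out <- c(out, "X"); i <- i + 2 }
      else if (nxt == "I" && nxt2 %in% c("O", "A")) { out <- c(out, "X"); i <- i + 1 }
      else { out <- c(out, "S"); i <- i + 1 }
    } else if (c0 == "T") {
      if (nxt == "I" && nxt2 %in% c("O", "A")) { out <- c(out, "X"); i <- i + 1 }
      else if (nxt == "H") { out <- c(out, "0"); i <- i + 2 }
      else if (nxt == "C" && nxt2 == "H") { i <- i + 1 }  # silent in -TCH-
      else { out <- c(out, "T"); i <- i + 1 }
    } else if (c0 == "V") {
      out <- c(out, "F"); i <- i + 1
    } else if (c0 == "W") {
      if (is_vowel(i + 1)) out <- c(out, "W")
      i <- i + 1
    } else if (c0 == "X") {
      out <- c(out, "K", "S"); i <- i + 1
    } else if (c0 == "Y") {
      if (is_vowel(i + 1)) out <- c(out, "Y")
      i <- i + 1
    } else if (c0 == "Z") {
      out <- c(out, "S"); i <- i + 1
    } else {
      # F J L M N R encode as themselves
      out <- c(out, c0); i <- i + 1
    }
  }
  paste(out, collapse = "")
}
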