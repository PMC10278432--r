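#' English number words 0-99
#'
#' Biopsy reports sometimes spell small counts out ("Ten glomeruli are
#' globally sclerosed"). Glomerulus counts in a native kidney biopsy are
#' two-digit numbers, so the vocabulary covers 0-99, with hyphenated
#' compounds ("twenty-one").
#'
#' @return Named integer vector mapping lower-case number words to values.
#' @keywords internal
number_word_table <- function() {
  ones <- c(
    "zero", "one", "two", "three", "four", "five", "six", "seven", "eight",
    "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
    "sixteen", "seventeen", "eighteen", "nineteen"
  )
  tens <- c(
    "twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty",
    "ninety"
  )
  words <- ones
  values <- 0:19
  for (i in seq_along(tens)) {
    words <- c(words, tens[i], paste0(tens[i], "-", ones[2:10]))
    values <- c(values, 10 * (i + 1), 10 * (i + 1) + 1:9)
  }
  stats::setNames(as.integer(values), words)
}

the_number_words <- NULL # populated lazily; see .onLoad-free accessor below

number_words <- function() {
  if (is.null(the_number_words)) {
    utils::assignInMyNamespace("the_number_words", number_word_table())
  }
  the_number_words
}

#' Normalize a count token to an integer
#'
#' Accepts a digit string or an English number word between 0 and 99
#' (case-insensitive, hyphenated compounds allowed).
#'
#' @param token Character vector of tokens.
#' @return Integer vector. Unrecognized tokens raise an error naming the
#'   offending token.
#' @examples
#' normalize_number_word(c("Ten", "0", "twenty-one"))
#' @export
normalize_number_word <- function(token) {
  token <- as.character(token)
  out <- suppressWarnings(as.integer(token))
  word <- is.na(out) & !is.na(token)
  if (any(word)) {
    looked <- number_words()[tolower(token[word])]
    bad <- is.na(looked)
    if (any(bad)) {
      rlang::abort(
        paste0(
          "Unrecognized count token(s): ",
          paste(unique(token[word][bad]), collapse = ", ")
        ),
        class = "glomreg_number_word_error",
        token = unique(token[word][bad])
      )
    }
    out[word] <- looked
  }
  out
}

#' Render an integer 0-99 as an English number word
#'
#' Inverse of [normalize_number_word()] for the generator's word-style
#' templates. The first letter is capitalized when `capitalize = TRUE`
#' (sentence-initial position).
#'
#' @param x Integer vector in 0-99.
#' @param capitalize Capitalize the first letter?
#' @return Character vector of number words.
#' @export
number_to_words <- function(x, capitalize = FALSE) {
  stopifnot(all(x >= 0 & x <= 99, na.rm = TRUE))
  tbl <- number_words()
  words <- names(tbl)[match(as.integer(x), tbl)]
  if (capitalize) {
    words <- paste0(toupper(substr(words, 1, 1)), substr(words, 2, nchar(words)))
  }
  words
}

# Regex alternation matching a digit string or any number word 0-99.
# Used as the single capture slot of count-valued field patterns.
count_token_regex <- function() {
  words <- names(number_words())
  # longest first so "twenty-one" wins over "twenty"
  words <- words[order(-nchar(words))]
  paste0("(\\d{1,3}|", paste(words, collapse = "|"), ")")
}
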