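#' Binary input words
#'
#' An input word is a string of n characters from \{"0","1"\}. The leftmost
#' character is bit position 1 and the most significant bit, so the integer
#' value of a word is its ordinary base-2 reading: `word_value("110")` is 6.
#' This is the number a compiled display device renders when the word is
#' applied as an antibiotic input.
#'
#' @param n_bits number of input bits (>= 1).
#' @return `word_strings()` returns all `2^n_bits` words ordered by value.
#' @examples
#' word_strings(2)          # "00" "01" "10" "11"
#' word_value("101")        # 5
#' word_from_value(6, 3)    # "110"
#' @export
word_strings <- function(n_bits) {
  stopifnot(is.numeric(n_bits), length(n_bits) == 1, n_bits >= 1)
  vapply(0:(2^n_bits - 1), word_from_value, character(1), n_bits = n_bits)
}

#' @rdname word_strings
#' @param word a word string such as "101".
#' @export
word_value <- function(word) {
  assert_word(word)
  sum(word_bits(word) * 2^((nchar(word) - 1):0))
}

#' @rdname word_strings
#' @param value integer in `[0, 2^n_bits)`.
#' @export
word_from_value <- function(value, n_bits) {
  stopifnot(value >= 0, value < 2^n_bits)
  paste(rev((value %/% 2^(0:(n_bits - 1))) %% 2), collapse = "")
}

#' @rdname word_strings
#' @export
word_bits <- function(word) {
  assert_word(word)
  as.integer(strsplit(word, "")[[1]])
}

assert_word <- function(word, n_bits = NULL) {
  if (!is.character(word) || length(word) != 1 || !grepl("^[01]+$", word)) {
    stop("not a binary input word: ", deparse(word), call. = FALSE)
  }
  if (!is.null(n_bits) && nchar(word) != n_bits) {
    stop("word '", word, "' has ", nchar(word), " bits; expected ", n_bits,
         call. = FALSE)
  }
  invisible(word)
}
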