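#' Pixel fonts for the calculator-style display
#'
#' The display device renders the value of a 3-bit input word as a digit on
#' a 5-row by 3-column grid of wells ("3 columns x 5 rows", portrait digit,
#' row-major, top-left origin). A `digit_font` holds one binary 5x3 pixel
#' mask per digit 0–7; masks must be pairwise distinct so that exact-match
#' decoding is unambiguous. The canonical calculator-style font ships as a
#' versioned JSON file under `inst/extdata/`; alternative fonts can be
#' supplied, and the compiler and decoder are both font-parameterized.
#'
#' @param glyphs either `NULL` (load the shipped font) or a named list
#'   mapping "0".."7" to 5x3 0/1 matrices.
#' @return an object of class `digit_font`: a list with `rows`, `cols`, and
#'   `glyphs` (list of 0/1 matrices named "0".."7").
#' @examples
#' font <- digit_font()
#' glyph(font, 6)
#' @export
digit_font <- function(glyphs = NULL) {
  if (is.null(glyphs)) return(load_default_font())
  validate_font(glyphs)
}

validate_font <- function(glyphs, rows = 5, cols = 3) {
  need <- as.character(0:7)
  if (!is.list(glyphs) || !setequal(names(glyphs), need)) {
    stop("a digit font needs exactly the glyphs named \"0\"..\"7\"")
  }
  glyphs <- glyphs[need]
  for (d in need) {
    m <- glyphs[[d]]
    if (!is.matrix(m) || !all(dim(m) == c(rows, cols)) ||
        !all(m %in% c(0, 1))) {
      stop("glyph '", d, "' must be a ", rows, "x", cols, " 0/1 matrix")
    }
    storage.mode(glyphs[[d]]) <- "integer"
  }
  keys <- vapply(glyphs, function(m) paste(m, collapse = ""), character(1))
  if (anyDuplicated(keys)) stop("glyph masks must be pairwise distinct")
  structure(list(rows = rows, cols = cols, glyphs = glyphs),
            class = "digit_font")
}

# the shipped font is parsed once and cached for the session
.font_cache <- new.env(parent = emptyenv())

load_default_font <- function() {
  if (!is.null(.font_cache$default)) return(.font_cache$default)
  path <- system.file("extdata", "digit_font_3x5.json", package = "platelogic",
                      mustWork = TRUE)
  obj <- jsonlite::read_json(path)
  glyphs <- lapply(obj$glyphs, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  })
  font <- validate_font(glyphs, rows = obj$rows, cols = obj$cols)
  .font_cache$default <- font
  font
}

#' @rdname digit_font
#' @param font a `digit_font`.
#' @param digit integer 0–7.
#' @export
glyph <- function(font, digit) {
  stopifnot(inherits(font, "digit_font"))
  key <- as.character(digit)
  if (!key %in% names(font$glyphs)) stop("no glyph for digit ", digit)
  font$glyphs[[key]]
}

#' @export
print.digit_font <- function(x, ...) {
  cat("<digit_font> ", length(x$glyphs), " glyphs, ",
      x$rows, "x", x$cols, " pixels\n", sep = "")
  invisible(x)
}
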