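#' Well specifications and plate designs
#'
#' A `well_spec` is one well of a compiled plate: a grid location, a label
#' (output name or display pixel id), the set of input words for which the
#' well must read 1 (`on_set`), and the strain mixture realizing it — by
#' construction exactly the one-hot genotype of each word in `on_set`. An
#' empty mixture is legal and encodes a constant-0 well.
#'
#' @param row,col 1-based grid coordinates (row 1 = top, col 1 = left).
#' @param label well label.
#' @param on_set character vector of word strings for which the well reads 1.
#' @param enc the [bit_encoding()] used to derive the mixture.
#' @return an object of class `well_spec` with fields `row`, `col`, `label`,
#'   `on_set`, `mixture` (named list of genotypes).
#' @export
well_spec <- function(row, col, label, on_set, enc) {
  stopifnot(row >= 1, col >= 1)
  on_set <- unique(as.character(on_set))
  for (w in on_set) assert_word(w, n_bits(enc))
  on_set <- on_set[order(vapply(on_set, word_value, numeric(1)))]
  mixture <- lapply(on_set, genotype_for_word, enc = enc)
  names(mixture) <- vapply(mixture, function(g) g$label, character(1))
  structure(list(row = as.integer(row), col = as.integer(col),
                 label = label, on_set = on_set, mixture = mixture),
            class = "well_spec")
}

#' @rdname well_spec
#' @param encoding a [bit_encoding()].
#' @param wells list of `well_spec` objects.
#' @param grid_shape integer vector `c(n_rows, n_cols)`.
#' @param device_name free-text device name.
#' @param metadata named list of free-text metadata.
#' @export
plate_design <- function(encoding, wells, grid_shape, device_name = "device",
                         metadata = list()) {
  stopifnot(inherits(encoding, "bit_encoding"),
            length(grid_shape) == 2, all(grid_shape >= 1))
  plate <- structure(list(encoding = encoding, wells = wells,
                          grid_shape = as.integer(grid_shape),
                          device_name = device_name, metadata = metadata),
                     class = "plate_design")
  issues <- validate_design(plate)
  bad <- issues$message[issues$severity == "error"]
  if (length(bad) > 0) {
    stop("invalid plate design:\n  ", paste(bad, collapse = "\n  "))
  }
  plate
}

#' @export
print.plate_design <- function(x, ...) {
  cat("<plate_design> '", x$device_name, "': ", length(x$wells),
      " well(s) on a ", x$grid_shape[1], "x", x$grid_shape[2],
      " grid, ", n_bits(x$encoding), "-bit encoding\n", sep = "")
  for (w in x$wells) {
    cat(sprintf("  %s (%d,%d): on {%s} <- mix {%s}\n", w$label, w$row, w$col,
                paste(w$on_set, collapse = ","),
                paste(names(w$mixture), collapse = ",")))
  }
  invisible(x)
}

#' Compile a Boolean function to a plate design
#'
#' One well per output. Each well's mixture contains exactly the one-hot
#' strain of every minterm of that output, so the well grows (reads 1, turns
#' yellow on development) precisely when the applied word is a minterm: the
#' plate computes the function in canonical sum-of-minterms form. Layout is
#' deterministic — outputs left to right in a single row unless explicit
#' `locations` are given.
#'
#' @param f a [boolean_function()] with `f$n_bits == n_bits(enc)`.
#' @param enc a [bit_encoding()].
#' @param locations optional list of `c(row, col)` per output, and
#'   `grid_shape` the matching grid; defaults to a 1-row strip.
#' @param grid_shape optional explicit grid shape.
#' @return a [plate_design()].
#' @examples
#' plate <- compile_function(full_adder(), default_encoding())
#' names(plate$wells[[1]]$mixture)  # strains in the S well
#' @export
compile_function <- function(f, enc, locations = NULL, grid_shape = NULL) {
  stopifnot(inherits(f, "boolean_function"), inherits(enc, "bit_encoding"))
  if (f$n_bits != n_bits(enc)) {
    stop("function arity (", f$n_bits, ") does not match encoding (",
         n_bits(enc), " bits)")
  }
  outs <- names(f$outputs)
  if (is.null(locations)) {
    locations <- lapply(seq_along(outs), function(i) c(1L, i))
    if (is.null(grid_shape)) grid_shape <- c(1L, length(outs))
  } else if (is.null(grid_shape)) {
    locs <- do.call(rbind, locations)
    grid_shape <- c(max(locs[, 1]), max(locs[, 2]))
  }
  wells <- lapply(seq_along(outs), function(i) {
    well_spec(locations[[i]][1], locations[[i]][2], outs[i],
              minterms(f, outs[i]), enc)
  })
  plate_design(enc, wells, grid_shape, device_name = "compiled function",
               metadata = list(outputs = outs))
}

#' Compile the calculator-style digit display
#'
#' Fifteen wells on a 5-row x 3-column grid, one per display pixel. The well
#' at pixel (r, c) mixes the one-hot strains of every word whose value's
#' glyph lights that pixel, so applying any 3-bit word grows exactly the
#' pixel pattern of its decimal value.
#'
#' @param font a [digit_font()]; defaults to the shipped 3x5 font.
#' @param enc a 3-bit [bit_encoding()].
#' @return a [plate_design()] with `grid_shape = c(5, 3)`.
#' @export
compile_display <- function(font = digit_font(), enc = default_encoding()) {
  stopifnot(inherits(font, "digit_font"), inherits(enc, "bit_encoding"))
  if (n_bits(enc) != 3) {
    stop("the digit display needs a 3-bit encoding (digits 0-7)")
  }
  words <- word_strings(3)
  wells <- list()
  for (r in seq_len(font$rows)) {
    for (cc in seq_len(font$cols)) {
      lit <- words[vapply(words, function(w) {
        glyph(font, word_value(w))[r, cc] == 1L
      }, logical(1))]
      wells[[length(wells) + 1]] <-
        well_spec(r, cc, sprintf("px_%d_%d", r, cc), lit, enc)
    }
  }
  plate_design(enc, wells, c(font$rows, font$cols),
               device_name = "digit display",
               metadata = list(font_version = "1.0"))
}

#' One-hot decoder array
#'
#' One well per input word, each containing a single library strain; the
#' well for word w reads 1 only under w. For any applied input exactly one
#' well of the array grows. Wells are laid out as a single column in
#' word-value order, mirroring a vertical strip of a microplate.
#'
#' @param enc a [bit_encoding()].
#' @return a [plate_design()] with `2^n` wells.
#' @export
one_hot_array <- function(enc) {
  stopifnot(inherits(enc, "bit_encoding"))
  words <- word_strings(n_bits(enc))
  lib <- strain_library(enc)
  wells <- lapply(seq_along(words), function(i) {
    well_spec(i, 1, lib[[i]]$label, words[i], enc)
  })
  plate_design(enc, wells, c(length(words), 1L),
               device_name = sprintf("%d-bit one-hot array", n_bits(enc)))
}

#' Validate a plate design
#'
#' Checks structural integrity: wells inside the grid, unique locations,
#' every mixture consistent with its on_set (exactly the one-hot genotype of
#' each word, drawn from the encoding's library). Empty mixtures are
#' reported as warnings (they encode constant-0 outputs, which may or may
#' not be intended). All shipped devices validate with zero issues.
#'
#' @param plate a [plate_design()] (or a bare list with the same fields,
#'   so that hand-built designs can be checked before construction).
#' @return a data.frame with columns `severity` ("error"/"warning"),
#'   `well` (label) and `message`; zero rows when the design is clean.
#' @export
validate_design <- function(plate) {
  issues <- list()
  note <- function(severity, well, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, well = well, message = message,
      stringsAsFactors = FALSE)
  }
  enc <- plate$encoding
  nb <- n_bits(enc)
  lib <- strain_library(enc)
  locs <- vapply(plate$wells, function(w) paste(w$row, w$col), character(1))
  for (loc in unique(locs[duplicated(locs)])) {
    note("error", paste(vapply(plate$wells[locs == loc],
                               function(w) w$label, character(1)),
                        collapse = "+"),
         paste0("duplicate well location (", loc, ")"))
  }
  for (w in plate$wells) {
    if (w$row > plate$grid_shape[1] || w$col > plate$grid_shape[2] ||
        w$row < 1 || w$col < 1) {
      note("error", w$label,
           sprintf("location (%d,%d) outside %dx%d grid", w$row, w$col,
                   plate$grid_shape[1], plate$grid_shape[2]))
    }
    expected <- sort(vapply(w$on_set, function(word) {
      genotype_for_word(word, enc)$label
    }, character(1), USE.NAMES = FALSE))
    got <- sort(names(w$mixture))
    if (!identical(expected, got)) {
      note("error", w$label,
           sprintf("mixture {%s} inconsistent with on_set {%s} (expect {%s})",
                   paste(got, collapse = ","),
                   paste(w$on_set, collapse = ","),
                   paste(expected, collapse = ",")))
    }
    if (length(got) > 0 && !all(got %in% names(lib))) {
      note("error", w$label, "mixture contains strains outside the library")
    }
    if (length(w$on_set) == 0) {
      note("warning", w$label, "empty mixture: well is constant 0")
    }
    if (length(w$on_set) > 2^nb) {
      note("error", w$label, "on_set larger than the word space")
    }
  }
  if (length(issues) == 0) {
    data.frame(severity = character(0), well = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}
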