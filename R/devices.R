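#' Pre-built reference devices
#'
#' Bundles wiring the compiler, encoding and simulator together into the
#' four benchmark devices of the architecture: the 1/2/3-bit one-hot
#' decoder arrays, the 3-bit calculator-style digit display, and the full
#' adder and full subtractor. Devices are compiled at call time from the
#' current encoding and font — never loaded from frozen files — so they
#' always stay consistent with those inputs; JSON snapshots are for export
#' and regression only.
#'
#' A `device_bundle` carries the compiled plate, the reference object used
#' to verify it (a [boolean_function()], or a [digit_font()] for the
#' display), and a free-text provenance note.
#'
#' @name devices
#' @return `build_one_hot_arrays()` returns a named list of three bundles
#'   (`"1-bit"`, `"2-bit"`, `"3-bit"`); the other builders return a single
#'   `device_bundle`.
NULL

device_bundle <- function(name, plate, reference, note = "") {
  structure(list(name = name, plate = plate, reference = reference,
                 note = note),
            class = "device_bundle")
}

#' @export
print.device_bundle <- function(x, ...) {
  cat("<device_bundle> ", x$name, if (nzchar(x$note)) paste0(" — ", x$note),
      "\n", sep = "")
  print(x$plate)
  invisible(x)
}

#' @rdname devices
#' @param enc a 3-bit [bit_encoding()]; the 1- and 2-bit arrays use its
#'   leading positions.
#' @export
build_one_hot_arrays <- function(enc = default_encoding()) {
  stopifnot(n_bits(enc) >= 3)
  bundles <- lapply(1:3, function(k) {
    sub <- subset_encoding(enc, seq_len(k))
    device_bundle(sprintf("%d-bit one-hot array", k), one_hot_array(sub),
                  reference = NULL,
                  note = "one well per input word; exactly one grows")
  })
  names(bundles) <- paste0(1:3, "-bit")
  bundles
}

#' @rdname devices
#' @export
build_adder <- function(enc = default_encoding()) {
  f <- full_adder()
  device_bundle("full adder", compile_function(f, enc), f,
                note = "inputs A,B,Cin; wells S and Cout")
}

#' @rdname devices
#' @export
build_subtractor <- function(enc = default_encoding()) {
  f <- full_subtractor()
  device_bundle("full subtractor", compile_function(f, enc), f,
                note = "inputs X,Y,Bin; wells D and Bout")
}

#' @rdname devices
#' @param font a [digit_font()].
#' @export
build_display <- function(enc = default_encoding(), font = digit_font()) {
  device_bundle("digit display", compile_display(font, enc), font,
                note = "5x3 pixel matrix; shows the word's decimal value")
}
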