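#' Multi-output Boolean functions as dense truth tables
#'
#' A `boolean_function` stores, for each named output, the full mapping from
#' all `2^n_bits` input words to \{0, 1\}. Truth tables are kept dense rather
#' than as expressions: the compiler consumes minterms directly, and n stays
#' small (3 for all shipped devices) by design. No minimization is ever
#' applied — the plate architecture realizes the canonical sum-of-minterms
#' form, one strain per minterm, and minimizing would change which strains
#' go into a well.
#'
#' @param n_bits input arity (>= 1).
#' @param outputs a named list; each element is a 0/1 vector either named by
#'   word string (any order, must be total) or unnamed of length `2^n_bits`
#'   in word-value order. Unnamed list elements get names "out0", "out1", ...
#' @return an object of class `boolean_function`.
#' @examples
#' f <- boolean_function(2, list(AND = c(0, 0, 0, 1)))
#' minterms(f, "AND")  # "11"
#' @export
boolean_function <- function(n_bits, outputs) {
  stopifnot(is.numeric(n_bits), length(n_bits) == 1, n_bits >= 1)
  n_bits <- as.integer(n_bits)
  if (!is.list(outputs) || length(outputs) == 0) {
    stop("'outputs' must be a non-empty list of truth vectors")
  }
  words <- word_strings(n_bits)
  nms <- names(outputs)
  if (is.null(nms)) nms <- rep("", length(outputs))
  blank <- !nzchar(nms)
  nms[blank] <- paste0("out", seq_along(outputs)[blank] - 1)
  if (anyDuplicated(nms)) stop("output names must be unique")
  tables <- lapply(seq_along(outputs), function(i) {
    v <- outputs[[i]]
    if (!is.null(names(v))) {
      missing <- setdiff(words, names(v))
      if (length(missing) > 0) {
        stop("output '", nms[i], "' is not total; missing words: ",
             paste(missing, collapse = ", "))
      }
      v <- v[words]
    } else if (length(v) != length(words)) {
      stop("output '", nms[i], "' has length ", length(v),
           "; expected ", length(words))
    }
    v <- as.integer(v)
    if (!all(v %in% c(0L, 1L))) stop("truth values must be 0 or 1")
    names(v) <- words
    v
  })
  names(tables) <- nms
  structure(list(n_bits = n_bits, outputs = tables),
            class = "boolean_function")
}

#' @export
print.boolean_function <- function(x, ...) {
  cat("<boolean_function> ", x$n_bits, " input bit(s), outputs: ",
      paste(names(x$outputs), collapse = ", "), "\n", sep = "")
  tab <- do.call(cbind, x$outputs)
  rownames(tab) <- word_strings(x$n_bits)
  print(tab)
  invisible(x)
}

#' Evaluate a Boolean function on one input word
#'
#' @param f a [boolean_function()].
#' @param word an input word string of matching arity.
#' @return named integer vector, one 0/1 entry per output.
#' @export
eval_function <- function(f, word) {
  stopifnot(inherits(f, "boolean_function"))
  assert_word(word, f$n_bits)
  vapply(f$outputs, function(tab) tab[[word]], integer(1))
}

#' Minterms and maxterms of one output
#'
#' The minterms of an output are the input words mapped to 1; in a compiled
#' plate each minterm contributes exactly one strain to that output's well.
#' Maxterms are the complement set (words mapped to 0); together they
#' partition the `2^n` words.
#'
#' @inheritParams eval_function
#' @param output_name which output to inspect.
#' @return character vector of word strings in value order (possibly empty).
#' @export
minterms <- function(f, output_name) {
  stopifnot(inherits(f, "boolean_function"))
  if (!output_name %in% names(f$outputs)) {
    stop("unknown output name: '", output_name, "'")
  }
  tab <- f$outputs[[output_name]]
  names(tab)[tab == 1L]
}

#' @rdname minterms
#' @export
maxterms <- function(f, output_name) {
  stopifnot(inherits(f, "boolean_function"))
  if (!output_name %in% names(f$outputs)) {
    stop("unknown output name: '", output_name, "'")
  }
  tab <- f$outputs[[output_name]]
  names(tab)[tab == 0L]
}

#' The 3-bit full adder and full subtractor
#'
#' `full_adder()` adds three binary inputs A, B and Cin (word = "A B Cin",
#' A most significant) into a sum S and carry Cout, so that
#' A + B + Cin = 2*Cout + S for every word. `full_subtractor()` computes
#' X - Y - Bin as a difference D and borrow Bout, so that
#' X - Y - Bin = D - 2*Bout.
#'
#' @return a [boolean_function()] with outputs S, Cout (adder) or
#'   D, Bout (subtractor).
#' @examples
#' eval_function(full_adder(), "101")       # S = 0, Cout = 1
#' eval_function(full_subtractor(), "011")  # D = 0, Bout = 1
#' @export
full_adder <- function() {
  words <- word_strings(3)
  sums <- vapply(words, function(w) sum(word_bits(w)), integer(1))
  boolean_function(3, list(S = sums %% 2L, Cout = sums %/% 2L))
}

#' @rdname full_adder
#' @export
full_subtractor <- function() {
  words <- word_strings(3)
  d <- vapply(words, function(w) {
    b <- word_bits(w)
    b[1] - b[2] - b[3]
  }, integer(1))
  # d in {-2,-1,0,1}; D is d mod 2, Bout flags a borrow (d < 0)
  boolean_function(3, list(D = ((d %% 2L) + 2L) %% 2L,
                           Bout = as.integer(d < 0)))
}

#' Random Boolean function fixture
#'
#' Draws every truth-table entry as an independent fair coin flip; used for
#' property tests of compiler/simulator equivalence. Reproducible: the same
#' seed always yields the same function, and the caller's RNG state is left
#' untouched.
#'
#' @param n_bits,n_outputs arities (both >= 1).
#' @param seed integer seed (mandatory).
#' @return a [boolean_function()].
#' @export
random_function <- function(n_bits, n_outputs = 1, seed) {
  stopifnot(n_bits >= 1, n_outputs >= 1)
  if (missing(seed)) stop("'seed' must be given explicitly")
  with_seed(seed, {
    outs <- lapply(seq_len(n_outputs), function(i) {
      stats::rbinom(2^n_bits, 1, 0.5)
    })
    names(outs) <- paste0("out", seq_len(n_outputs) - 1)
    boolean_function(n_bits, outs)
  })
}

#' Truth-table JSON serialization
#'
#' Format: `{"format_version": "1.0", "n_bits": n, "outputs":
#' {name: {"000": 0, "001": 1, ...}}}`. The reader validates totality (every
#' word present for every output) and rejects stray words.
#'
#' @param f a [boolean_function()].
#' @param path file path.
#' @return `read_truth_table()` returns a [boolean_function()];
#'   `write_truth_table()` returns `path` invisibly.
#' @export
write_truth_table <- function(f, path) {
  stopifnot(inherits(f, "boolean_function"))
  obj <- list(
    format_version = "1.0",
    n_bits = f$n_bits,
    outputs = lapply(f$outputs, as.list)
  )
  write_json_atomic(obj, path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$n_bits) || is.null(obj$outputs)) {
    stop("truth-table JSON must have 'n_bits' and 'outputs' fields")
  }
  n_bits <- as.integer(obj$n_bits)
  words <- word_strings(n_bits)
  outs <- lapply(names(obj$outputs), function(nm) {
    tab <- obj$outputs[[nm]]
    extra <- setdiff(names(tab), words)
    if (length(extra) > 0) {
      stop("output '", nm, "': unexpected words ", paste(extra, collapse = ", "))
    }
    unlist(tab)
  })
  names(outs) <- names(obj$outputs)
  boolean_function(n_bits, outs)
}
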