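#' Antibiotics, bit encodings and resistance genotypes
#'
#' In the distributed-logic architecture every input bit is realized as a
#' pair of mutually exclusive antibiotics: one drug denotes the bit's ZERO
#' form, the other its ONE form. Exactly one drug of each pair is present in
#' the medium for any input word, so a strain carrying one resistance marker
#' per bit survives exactly one of the `2^n` words — the strain library is a
#' one-hot decoder by construction.
#'
#' `drug()` builds a drug record. Working concentration and marker-plasmid
#' name are metadata only: antibiotic action in the simulator is binary
#' (survive/die), never concentration-dependent.
#'
#' @param name full drug name, e.g. "chloramphenicol".
#' @param abbrev short label used in genotype labels, e.g. "Ch". The first
#'   character is the genotype-label initial, so initials should be unique
#'   within an encoding.
#' @param conc_ug_ml optional working concentration in µg/ml (> 0).
#' @param plasmid optional free-text name of the plasmid carrying the
#'   resistance marker.
#' @return an object of class `drug`.
#' @export
drug <- function(name, abbrev, conc_ug_ml = NULL, plasmid = NULL) {
  stopifnot(is.character(name), is.character(abbrev), nzchar(abbrev))
  if (!is.null(conc_ug_ml)) {
    stopifnot(conc_ug_ml > 0)
    conc_ug_ml <- as.numeric(conc_ug_ml)
  }
  structure(list(name = name, abbrev = abbrev,
                 conc_ug_ml = conc_ug_ml, plasmid = plasmid),
            class = "drug")
}

#' @export
print.drug <- function(x, ...) {
  cat("<drug> ", x$abbrev, " (", x$name, ")",
      if (!is.null(x$conc_ug_ml)) paste0(", ", x$conc_ug_ml, " ug/ml"),
      "\n", sep = "")
  invisible(x)
}

#' Bit encoding: ordered antibiotic pairs
#'
#' @param pairs a list of length n; element i is `list(zero = drug,
#'   one = drug)` for bit position i (position 1 = leftmost = most
#'   significant bit of the word string). All 2n drugs must have pairwise
#'   distinct abbreviations.
#' @return an object of class `bit_encoding`.
#' @seealso [default_encoding()] for the six-antibiotic reference scheme.
#' @export
bit_encoding <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1)
  for (p in pairs) {
    if (!inherits(p$zero, "drug") || !inherits(p$one, "drug")) {
      stop("each pair must have 'zero' and 'one' drug objects")
    }
  }
  abbrevs <- unlist(lapply(pairs, function(p) c(p$zero$abbrev, p$one$abbrev)))
  if (anyDuplicated(abbrevs)) {
    stop("drug abbreviations must be pairwise distinct: ",
         paste(abbrevs[duplicated(abbrevs)], collapse = ", "))
  }
  structure(list(pairs = pairs), class = "bit_encoding")
}

#' @export
print.bit_encoding <- function(x, ...) {
  cat("<bit_encoding> ", n_bits(x), " bit(s)\n", sep = "")
  for (i in seq_along(x$pairs)) {
    p <- x$pairs[[i]]
    cat("  bit ", i, ": 0 = ", p$zero$abbrev, " (", p$zero$name,
        "), 1 = ", p$one$abbrev, " (", p$one$name, ")\n", sep = "")
  }
  invisible(x)
}

#' Number of bits of an encoding
#' @param enc a [bit_encoding()].
#' @export
n_bits <- function(enc) {
  stopifnot(inherits(enc, "bit_encoding"))
  length(enc$pairs)
}

#' The reference three-bit antibiotic encoding
#'
#' Six antibiotics encode three bits, one ZERO/ONE pair per position:
#' bit 1 ampicillin-class (Am, 0) / chloramphenicol (Ch, 1); bit 2
#' tetracycline (Tc, 0) / kanamycin (Km, 1); bit 3 gentamicin (Gm, 0) /
#' spectinomycin (Sm, 1). Under this scheme input 101 is the drug set
#' \{Ch, Tc, Sm\} and only the CTS strain survives it; input 000 is
#' \{Am, Tc, Gm\}, survived only by ATG. Working concentrations (µg/ml) and
#' marker plasmids are attached as metadata. The Am entry covers the
#' ampicillin/carbenicillin class selected at 100 µg/ml.
#'
#' @return a 3-bit [bit_encoding()].
#' @examples
#' vapply(drugs_for_word("101", default_encoding()),
#'        function(d) d$abbrev, character(1))
#' @export
default_encoding <- function() {
  bit_encoding(list(
    list(zero = drug("ampicillin-class", "Am", 100, "pSB4A5"),
         one  = drug("chloramphenicol",  "Ch", 20,  "pSB4C5")),
    list(zero = drug("tetracycline",     "Tc", 10,  "pSB1T3"),
         one  = drug("kanamycin",        "Km", 50,  "pSB1K3")),
    list(zero = drug("gentamicin",       "Gm", 10,  "pSEVA631"),
         one  = drug("spectinomycin",    "Sm", 50,  "pMO9075"))
  ))
}

#' Restrict an encoding to a subset of bit positions
#'
#' Used to derive the 1- and 2-bit devices from the 3-bit reference scheme
#' (e.g. positions 1:2 give the Am/Ch, Tc/Km two-bit system whose four
#' strains carry the printed two-marker combinations).
#'
#' @param enc a [bit_encoding()].
#' @param positions integer vector of bit positions to keep (1-based).
#' @export
subset_encoding <- function(enc, positions) {
  stopifnot(inherits(enc, "bit_encoding"),
            all(positions >= 1), all(positions <= n_bits(enc)))
  bit_encoding(enc$pairs[positions])
}

#' Map an input word to its antibiotic set
#'
#' Returns one drug per bit position: the pair's ZERO drug where the word
#' has a 0, the ONE drug where it has a 1. This is the drug cocktail added
#' to every well of the plate when that word is applied.
#'
#' @param word input word string, arity matching the encoding.
#' @param enc a [bit_encoding()].
#' @return named list of `drug` objects (names = abbreviations), in position
#'   order.
#' @export
drugs_for_word <- function(word, enc) {
  stopifnot(inherits(enc, "bit_encoding"))
  assert_word(word, n_bits(enc))
  bits <- word_bits(word)
  drugs <- lapply(seq_along(bits), function(i) {
    if (bits[i] == 1L) enc$pairs[[i]]$one else enc$pairs[[i]]$zero
  })
  names(drugs) <- vapply(drugs, function(d) d$abbrev, character(1))
  drugs
}

#' One-hot resistance genotypes
#'
#' `genotype_for_word()` builds the strain that survives exactly the given
#' word: it carries, at each bit position, the resistance marker for the
#' drug encoding that bit's value. Its label concatenates the marker
#' initials in position order (e.g. CTS = Ch/Tc/Sm, the strain for 101).
#' For two-bit libraries a reversed-initial display alias (e.g. KA for the
#' Am/Km strain) is attached, matching the bench convention of naming
#' double-resistant strains by the later marker first.
#'
#' @inheritParams drugs_for_word
#' @return an object of class `strain_genotype` with fields `markers`
#'   (list of drugs), `label`, `word`, and optional `alias`.
#' @export
genotype_for_word <- function(word, enc) {
  markers <- drugs_for_word(word, enc)
  label <- paste(substr(names(markers), 1, 1), collapse = "")
  alias <- if (length(markers) == 2) {
    paste(rev(substr(names(markers), 1, 1)), collapse = "")
  }
  structure(list(markers = markers, label = label, word = word,
                 alias = alias),
            class = "strain_genotype")
}

#' @export
print.strain_genotype <- function(x, ...) {
  cat("<strain_genotype> ", x$label, " (",
      paste(names(x$markers), collapse = "/"), ") <-> word ", x$word,
      if (!is.null(x$alias)) paste0(" [alias ", x$alias, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Recover the input word a genotype responds to
#'
#' Inverse of [genotype_for_word()]: reads each marker back through the
#' encoding's pairs. Errors if a marker is not one of the two drugs of its
#' position's pair.
#'
#' @param genotype a `strain_genotype`.
#' @param enc a [bit_encoding()].
#' @return the word string.
#' @export
word_for_genotype <- function(genotype, enc) {
  stopifnot(inherits(genotype, "strain_genotype"),
            inherits(enc, "bit_encoding"))
  if (length(genotype$markers) != n_bits(enc)) {
    stop("genotype has ", length(genotype$markers),
         " markers; encoding has ", n_bits(enc), " bits")
  }
  bits <- vapply(seq_along(genotype$markers), function(i) {
    ab <- genotype$markers[[i]]$abbrev
    pair <- enc$pairs[[i]]
    if (ab == pair$zero$abbrev) return(0L)
    if (ab == pair$one$abbrev) return(1L)
    stop("marker '", ab, "' at position ", i,
         " is not in that bit's pair (",
         pair$zero$abbrev, "/", pair$one$abbrev, ")")
  }, integer(1))
  paste(bits, collapse = "")
}

#' The full strain library of an encoding
#'
#' One genotype per input word — `2^n` strains, each surviving exactly its
#' own word. The reference 3-bit scheme yields the eight strains ATG, ATS,
#' AKG, AKS, CTG, CTS, CKG, CKS.
#'
#' @param enc a [bit_encoding()].
#' @return named list of `strain_genotype` objects (names = labels), in
#'   word-value order.
#' @export
strain_library <- function(enc) {
  stopifnot(inherits(enc, "bit_encoding"))
  genos <- lapply(word_strings(n_bits(enc)), genotype_for_word, enc = enc)
  labels <- vapply(genos, function(g) g$label, character(1))
  if (anyDuplicated(labels)) {
    stop("strain labels collide; drug abbreviation initials must be unique")
  }
  names(genos) <- labels
  genos
}

#' Encoding JSON serialization
#'
#' Format: `{"format_version": "1.0", "bits": [{"zero": {...},
#' "one": {...}}, ...]}` with drug fields name/abbrev/conc_ug_ml/plasmid.
#' Distinctness of abbreviations is enforced on read.
#'
#' @param enc a [bit_encoding()].
#' @param path file path.
#' @export
write_encoding <- function(enc, path) {
  stopifnot(inherits(enc, "bit_encoding"))
  write_json_atomic(list(format_version = "1.0",
                         bits = encoding_to_list(enc)), path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$bits)) stop("encoding JSON must have a 'bits' field")
  encoding_from_list(obj$bits)
}

encoding_to_list <- function(enc) {
  lapply(enc$pairs, function(p) {
    list(zero = drug_to_list(p$zero), one = drug_to_list(p$one))
  })
}

drug_to_list <- function(d) {
  out <- list(name = d$name, abbrev = d$abbrev)
  if (!is.null(d$conc_ug_ml)) out$conc_ug_ml <- d$conc_ug_ml
  if (!is.null(d$plasmid)) out$plasmid <- d$plasmid
  out
}

encoding_from_list <- function(bits) {
  from <- function(x) {
    if (is.null(x$name) || is.null(x$abbrev)) {
      stop("drug entries need 'name' and 'abbrev' fields")
    }
    drug(x$name, x$abbrev, x$conc_ug_ml, x$plasmid)
  }
  bit_encoding(lapply(bits, function(p) {
    list(zero = from(p$zero), one = from(p$one))
  }))
}
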