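#' Plate-design JSON serialization
#'
#' Schema (format_version "1.0"): device name, grid shape, the full bit
#' encoding, and one record per well with 0-based row/col, label, on_set
#' (word strings) and mixture (strain labels). Writing is atomic (temp file
#' + rename). Reading rebuilds genotypes from the embedded encoding and
#' re-validates the design, rejecting wells outside the grid, unknown
#' strain labels and mixture/on_set mismatches with per-well messages;
#' write–read round trips are deep-equal.
#'
#' @param plate a [plate_design()].
#' @param path file path.
#' @return `read_design()` returns a [plate_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(plate, path) {
  stopifnot(inherits(plate, "plate_design"))
  obj <- list(
    format_version = "1.0",
    device = plate$device_name,
    grid_shape = plate$grid_shape,
    encoding = encoding_to_list(plate$encoding),
    metadata = plate$metadata,
    wells = lapply(plate$wells, function(w) {
      list(row = w$row - 1L, col = w$col - 1L, label = w$label,
           on_set = as.list(w$on_set),
           mixture = as.list(names(w$mixture)))
    })
  )
  write_json_atomic(obj, path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path)
  for (field in c("grid_shape", "encoding", "wells")) {
    if (is.null(obj[[field]])) {
      stop("plate JSON is missing the '", field, "' field")
    }
  }
  enc <- encoding_from_list(obj$encoding)
  lib <- strain_library(enc)
  grid_shape <- unlist(obj$grid_shape)
  wells <- lapply(obj$wells, function(w) {
    for (field in c("row", "col", "label", "on_set", "mixture")) {
      if (is.null(w[[field]])) {
        stop("well record is missing the '", field, "' field")
      }
    }
    labels <- unlist(w$mixture)
    unknown <- setdiff(labels, names(lib))
    if (length(unknown) > 0) {
      stop("well '", w$label, "': unknown strain label(s) ",
           paste(unknown, collapse = ", "))
    }
    spec <- well_spec(w$row + 1L, w$col + 1L, w$label, unlist(w$on_set), enc)
    if (!setequal(names(spec$mixture), labels)) {
      stop("well '", w$label, "': mixture {",
           paste(sort(labels), collapse = ","),
           "} does not match its on_set {",
           paste(spec$on_set, collapse = ","), "}")
    }
    spec
  })
  plate_design(enc, wells, grid_shape,
               device_name = if (is.null(obj$device)) "device" else obj$device,
               metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Readout JSON export
#'
#' Writes the word, development endpoint and per-well binary/color results
#' of a simulated plate; biomass trajectories are summarized by their
#' endpoint only.
#'
#' @param readout a `plate_readout`.
#' @param path file path.
#' @export
write_readout <- function(readout, path) {
  stopifnot(inherits(readout, "plate_readout"))
  wells <- lapply(seq_along(readout$well_labels), function(i) {
    loc <- readout$well_locations[[i]]
    rec <- list(row = loc[1] - 1L, col = loc[2] - 1L,
                label = readout$well_labels[i],
                binary = readout$binary[loc[1], loc[2]],
                color = readout$color[loc[1], loc[2]])
    if (!is.null(readout$wells)) {
      st <- readout$wells[[i]]
      rec$final_biomass <- st$final_biomass
      rec$threshold_crossing_time <- st$threshold_crossing_time
    }
    rec
  })
  write_json_atomic(list(format_version = "1.0",
                         device = readout$device_name,
                         word = readout$word,
                         grid_shape = readout$grid_shape,
                         wells = wells), path)
}

#' Render a readout as a character grid
#'
#' The software analog of developing the plate: 'Y' for yellow (growth,
#' binary 1), 'B' for blue (no growth, 0), '.' for grid positions that hold
#' no well. Deterministic; printing shows the caption and the grid.
#'
#' @param readout a `plate_readout`.
#' @return an object of class `rendered_plate` with fields `grid`
#'   (character matrix) and `caption`.
#' @export
render_ascii <- function(readout) {
  stopifnot(inherits(readout, "plate_readout"))
  grid <- ifelse(is.na(readout$binary), ".",
                 ifelse(readout$binary == 1L, "Y", "B"))
  structure(list(grid = grid,
                 caption = sprintf("%s | input %s", readout$device_name,
                                   readout$word)),
            class = "rendered_plate")
}

#' @export
print.rendered_plate <- function(x, ...) {
  cat(x$caption, "\n")
  for (r in seq_len(nrow(x$grid))) {
    cat(paste(x$grid[r, ], collapse = " "), "\n")
  }
  invisible(x)
}

#' Bench-facing well map CSV
#'
#' One row per well with 0-based row/col, the A1-style microplate label
#' (row letter + 1-based column), the well label, its on_set and the strain
#' labels to mix.
#'
#' @param plate a [plate_design()].
#' @param path file path.
#' @export
write_well_map <- function(plate, path) {
  stopifnot(inherits(plate, "plate_design"))
  rows <- do.call(rbind, lapply(plate$wells, function(w) {
    data.frame(row = w$row - 1L, col = w$col - 1L,
               well = paste0(LETTERS[w$row], w$col),
               label = w$label,
               on_set = paste(w$on_set, collapse = ";"),
               mixture = paste(names(w$mixture), collapse = ";"),
               n_strains = length(w$mixture),
               stringsAsFactors = FALSE)
  }))
  write_atomic(path, function(tmp) {
    utils::write.csv(rows, tmp, row.names = FALSE)
  })
}

#' Read growth parameters from a config file
#'
#' Flat YAML key:value namespace mirroring the [growth_params()] arguments
#' (mu, K, inoculum_fraction, delta, theta, t_read, dt); unknown keys are
#' an error, missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a [growth_params()].
#' @export
read_params <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  known <- names(formals(growth_params))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    stop("unknown growth parameter(s): ", paste(unknown, collapse = ", "))
  }
  do.call(growth_params, obj)
}
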