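#' Growth and readout parameters
#'
#' The well model is deliberately minimal, matching a binary live/dead
#' endpoint readout: strains resistant to every drug present grow
#' logistically with a carrying capacity shared by all biomass in the well,
#' `dB_i/dt = mu_i * B_i * (1 - sum(B)/K)`; sensitive strains decay
#' exponentially at rate `delta`. A well reads 1 (develops yellow) when its
#' total biomass at the development time reaches `theta * K`, else 0 (blue).
#'
#' Defaults: each strain is inoculated at 1/100 of capacity
#' (`inoculum_fraction = 0.01`, the 1:100 inoculation), `theta = 0.5`, and
#' `mu = 0.383`/h, chosen so that a single resistant strain crosses the
#' threshold at `ln((theta/(1-theta)) * (1-f0)/f0) / mu = ln(99)/0.383 ~ 12`
#' hours — the system's response time — while the readout is taken at
#' `t_read = 18` h, after the endpoint has saturated. `delta = 0.5`/h drives
#' sensitive biomass below 1% of its inoculum well before 18 h. Integration
#' uses a fixed-step classical 4th-order Runge-Kutta scheme, `dt = 0.05` h.
#'
#' @param mu maximum specific growth rate, 1/h.
#' @param K carrying capacity (arbitrary biomass units).
#' @param inoculum_fraction initial biomass per strain as a fraction of K;
#'   must be below `theta`.
#' @param delta death rate of sensitive strains, 1/h.
#' @param theta readout threshold as a fraction of K, in (0, 1).
#' @param t_read development (readout) time, h.
#' @param dt integration step, h.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(mu = 0.383, K = 1, inoculum_fraction = 0.01,
                          delta = 0.5, theta = 0.5, t_read = 18, dt = 0.05) {
  p <- list(mu = mu, K = K, inoculum_fraction = inoculum_fraction,
            delta = delta, theta = theta, t_read = t_read, dt = dt)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                 !is.finite(v), logical(1)))) {
    stop("all growth parameters must be finite scalars")
  }
  if (mu < 0 || delta < 0 || K <= 0) stop("rates must be >= 0 and K > 0")
  if (theta <= 0 || theta >= 1) stop("'theta' must lie strictly in (0, 1)")
  if (inoculum_fraction <= 0 || inoculum_fraction >= theta) {
    stop("'inoculum_fraction' must lie in (0, theta)")
  }
  if (t_read <= 0 || dt <= 0) stop("'t_read' and 'dt' must be positive")
  structure(p, class = "growth_params")
}

#' Does a genotype survive a drug cocktail?
#'
#' Survival is the conjunction over drugs present: the strain lives iff it
#' carries a resistance marker for every drug in the well. No
#' cross-resistance, no concentration dependence; the empty cocktail is
#' survived by everything.
#'
#' @param genotype a `strain_genotype`.
#' @param drugs a list of `drug` objects (as from [drugs_for_word()]).
#' @return logical scalar.
#' @examples
#' enc <- default_encoding()
#' cts <- genotype_for_word("101", enc)
#' survives(cts, drugs_for_word("101", enc))  # TRUE
#' survives(cts, drugs_for_word("000", enc))  # FALSE
#' @export
survives <- function(genotype, drugs) {
  stopifnot(inherits(genotype, "strain_genotype"))
  marker_abbrevs <- vapply(genotype$markers, function(d) d$abbrev,
                           character(1))
  drug_abbrevs <- vapply(drugs, function(d) d$abbrev, character(1))
  all(drug_abbrevs %in% marker_abbrevs)
}

# Fixed-step classical RK4 for the shared-capacity logistic/decay system,
# vectorized across replicates: B, mu, surv are (n_reps x n_strains)
# matrices. Tracks first threshold crossing of the per-replicate total
# (linearly interpolated within the bracketing step). trajectory = TRUE
# (single replicate only) additionally records the full per-strain path.
grow_core <- function(B0, mu, surv, delta, K, t_read, dt, threshold,
                      trajectory = FALSE) {
  B <- B0
  smask <- surv * 1
  dmask <- (!surv) * 1
  deriv <- function(B) {
    B * (smask * mu * (1 - rowSums(B) / K) - dmask * delta)
  }
  n_steps <- ceiling(t_read / dt - 1e-9)
  times <- c(seq_len(n_steps) - 1, t_read / dt) * dt
  times[n_steps + 1] <- t_read
  tot <- rowSums(B)
  cross <- ifelse(tot >= threshold, 0, NA_real_)
  if (trajectory) {
    stopifnot(nrow(B) == 1)
    path <- matrix(NA_real_, n_steps + 1, ncol(B))
    path[1, ] <- B
  }
  for (k in seq_len(n_steps)) {
    h <- times[k + 1] - times[k]
    k1 <- deriv(B)
    k2 <- deriv(B + h / 2 * k1)
    k3 <- deriv(B + h / 2 * k2)
    k4 <- deriv(B + h * k3)
    B <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    B[B < 0] <- 0
    prev <- tot
    tot <- rowSums(B)
    hit <- is.na(cross) & tot >= threshold
    if (any(hit)) {
      frac <- (threshold - prev[hit]) / (tot[hit] - prev[hit])
      cross[hit] <- times[k] + frac * h
    }
    if (trajectory) path[k + 1, ] <- B
  }
  out <- list(endpoint = B, total = tot, crossing = cross, times = times)
  if (trajectory) out$path <- path
  out
}

#' Simulate one well to readout
#'
#' Integrates the mixture's growth/death dynamics under the given drug
#' cocktail from inoculation to the development time and applies the binary
#' threshold readout. Noise-free simulation is fully deterministic; when a
#' [noise_model()] is supplied a seed is mandatory, survival decisions are
#' Bernoulli-perturbed (leak/dropout) and per-strain growth rate and
#' inoculum are jittered log-normally.
#'
#' @param mixture a list of `strain_genotype` objects (possibly empty).
#' @param drugs a list of `drug` objects present in the well.
#' @param params a [growth_params()].
#' @param noise optional [noise_model()].
#' @param seed integer seed; required whenever `noise` is supplied (defaults
#'   to `noise$seed` when that was set).
#' @param mu_per_strain optional vector of per-strain growth rates (1/h),
#'   one per mixture member, overriding the uniform `params$mu` — for
#'   modeling growth-rate disparities between marker combinations.
#'   Multiplicative `mu_cv` noise applies on top of it.
#' @return an object of class `well_state`: times, per-strain biomass
#'   trajectory, total endpoint biomass, `binary_output` (0/1), `color`
#'   ("yellow"/"blue"), and `threshold_crossing_time` (h, or NA if the
#'   threshold is never reached).
#' @examples
#' enc <- default_encoding()
#' st <- simulate_well(list(genotype_for_word("101", enc)),
#'                     drugs_for_word("101", enc))
#' st$binary_output             # 1
#' st$threshold_crossing_time   # ~12 h
#' @export
simulate_well <- function(mixture, drugs, params = growth_params(),
                          noise = NULL, seed = NULL, mu_per_strain = NULL) {
  stopifnot(inherits(params, "growth_params"))
  n <- length(mixture)
  labels <- vapply(mixture, function(g) g$label, character(1))
  if (n == 0) {
    times <- c(0, params$t_read)
    return(well_state(times, matrix(0, 2, 0), labels, params))
  }
  surv <- vapply(mixture, survives, logical(1), drugs = drugs)
  if (!is.null(mu_per_strain)) {
    stopifnot(length(mu_per_strain) == n, all(mu_per_strain >= 0))
    mu <- matrix(mu_per_strain, 1, n)
  } else {
    mu <- matrix(params$mu, 1, n)
  }
  B0 <- matrix(params$inoculum_fraction * params$K, 1, n)
  if (!is.null(noise)) {
    if (is.null(seed)) seed <- noise$seed
    if (is.null(seed)) stop("a seed is required when noise is supplied")
    drawn <- with_seed(seed, draw_noise(matrix(surv, 1, n), 1, noise,
                                        params))
    surv <- drawn$surv[1, ]
    mu <- mu * (drawn$mu / params$mu)  # keep per-strain base, apply jitter
    B0 <- drawn$B0
  }
  res <- grow_core(B0, mu, matrix(surv, 1, n), params$delta, params$K,
                   params$t_read, params$dt, params$theta * params$K,
                   trajectory = TRUE)
  well_state(res$times, res$path, labels, params, res$crossing[1])
}

well_state <- function(times, path, labels, params, crossing = NA_real_) {
  colnames(path) <- labels
  total <- rowSums(path)
  final <- total[length(total)]
  binary <- as.integer(final >= params$theta * params$K)
  structure(list(times = times, biomass = path, total = total,
                 final_biomass = final, binary_output = binary,
                 color = if (binary == 1L) "yellow" else "blue",
                 threshold_crossing_time = crossing, params = params),
            class = "well_state")
}

#' @export
print.well_state <- function(x, ...) {
  cat("<well_state> ", ncol(x$biomass), " strain(s); output ",
      x$binary_output, " (", x$color, "), total biomass ",
      signif(x$final_biomass, 4), " at ", max(x$times), " h",
      if (!is.na(x$threshold_crossing_time))
        sprintf("; threshold crossed at %.2f h", x$threshold_crossing_time),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a whole plate under one input word
#'
#' Every well of the design is simulated under the drug cocktail encoding
#' the word; the result aligns binary and color matrices to the plate grid
#' (grid positions with no well are NA).
#'
#' @param plate a [plate_design()].
#' @param word input word string, arity matching the plate's encoding.
#' @inheritParams simulate_well
#' @return an object of class `plate_readout`: `word`, `binary` and `color`
#'   matrices of the grid shape, and the per-well `well_state` list.
#' @export
simulate_plate <- function(plate, word, params = growth_params(),
                           noise = NULL, seed = NULL) {
  stopifnot(inherits(plate, "plate_design"))
  assert_word(word, n_bits(plate$encoding))
  drugs <- drugs_for_word(word, plate$encoding)
  if (!is.null(noise) && is.null(seed)) seed <- noise$seed
  states <- vector("list", length(plate$wells))
  for (i in seq_along(plate$wells)) {
    # distinct per-well seed stream so wells stay independent under noise
    well_seed <- if (is.null(seed)) NULL else seed + i - 1
    states[[i]] <- simulate_well(plate$wells[[i]]$mixture, drugs, params,
                                 noise = noise, seed = well_seed)
  }
  names(states) <- vapply(plate$wells, function(w) w$label, character(1))
  plate_readout(plate, word, vapply(states, function(s) s$binary_output,
                                    integer(1)), states)
}

plate_readout <- function(plate, word, binary_by_well, states = NULL) {
  binary <- matrix(NA_integer_, plate$grid_shape[1], plate$grid_shape[2])
  for (i in seq_along(plate$wells)) {
    w <- plate$wells[[i]]
    binary[w$row, w$col] <- binary_by_well[i]
  }
  color <- ifelse(is.na(binary), NA_character_,
                  ifelse(binary == 1L, "yellow", "blue"))
  structure(list(device_name = plate$device_name, word = word,
                 grid_shape = plate$grid_shape, binary = binary,
                 color = color, wells = states,
                 well_labels = vapply(plate$wells, function(w) w$label,
                                      character(1)),
                 well_locations = lapply(plate$wells,
                                         function(w) c(w$row, w$col))),
            class = "plate_readout")
}

#' @export
print.plate_readout <- function(x, ...) {
  cat("<plate_readout> '", x$device_name, "', input ", x$word, "\n",
      sep = "")
  print(render_ascii(x))
  invisible(x)
}

#' Decode a display readout into a digit
#'
#' Compares the 5x3 binary matrix of a display readout against every glyph
#' of the font. The default policy is exact match: anything that is not
#' precisely one glyph raises an error carrying the nearest digit and its
#' Hamming distance, so a faulty plate is reported rather than silently
#' guessed. `nearest = TRUE` opts into nearest-glyph decoding (used by the
#' robustness module); a tie for nearest is still an error.
#'
#' @param readout a `plate_readout` from a 5x3 display plate.
#' @param font a [digit_font()].
#' @param nearest decode to the nearest glyph instead of requiring equality.
#' @return integer digit in 0..7.
#' @export
decode_display <- function(readout, font = digit_font(), nearest = FALSE) {
  stopifnot(inherits(readout, "plate_readout"), inherits(font, "digit_font"))
  mat <- readout$binary
  if (!all(dim(mat) == c(font$rows, font$cols)) || anyNA(mat)) {
    stop("readout is not a complete ", font$rows, "x", font$cols,
         " display matrix")
  }
  dists <- vapply(names(font$glyphs), function(d) {
    sum(mat != font$glyphs[[d]])
  }, integer(1))
  best <- min(dists)
  hits <- names(dists)[dists == best]
  if (!nearest && best > 0) {
    stop(sprintf(
      "display pattern matches no glyph (nearest digit %s at Hamming distance %d)",
      paste(hits, collapse = "/"), best))
  }
  if (length(hits) > 1) {
    stop("display pattern is equidistant from digits ",
         paste(hits, collapse = ", "), " (Hamming distance ", best, ")")
  }
  as.integer(hits)
}

#' Verify a compiled device against its truth table
#'
#' Simulates the plate noise-free under every input word and compares each
#' labeled well's binary output with the function's truth table — the
#' exhaustive endpoint check every shipped device must pass. Well labels
#' must match the function's output names exactly.
#'
#' @param plate a [plate_design()] compiled from `f`.
#' @param f the reference [boolean_function()].
#' @param params a [growth_params()].
#' @return an object of class `device_verification`: a data.frame `results`
#'   (word x output with simulated, expected and pass columns), `n_pass`,
#'   `n_words` and the overall `equivalent` flag.
#' @export
verify_device <- function(plate, f, params = growth_params()) {
  stopifnot(inherits(plate, "plate_design"), inherits(f, "boolean_function"))
  labels <- vapply(plate$wells, function(w) w$label, character(1))
  if (!setequal(labels, names(f$outputs))) {
    stop("plate well labels {", paste(labels, collapse = ","),
         "} do not match function outputs {",
         paste(names(f$outputs), collapse = ","), "}")
  }
  words <- word_strings(f$n_bits)
  rows <- list()
  for (w in words) {
    ro <- simulate_plate(plate, w, params)
    sim <- vapply(seq_along(plate$wells), function(i) {
      ro$wells[[i]]$binary_output
    }, integer(1))
    names(sim) <- labels
    expected <- eval_function(f, w)
    rows[[w]] <- data.frame(word = w, output = names(expected),
                            simulated = sim[names(expected)],
                            expected = unname(expected),
                            pass = sim[names(expected)] == expected,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  word_pass <- tapply(results$pass, results$word, all)
  structure(list(results = results,
                 n_pass = sum(word_pass), n_words = length(words),
                 failing_words = names(word_pass)[!word_pass],
                 equivalent = all(results$pass)),
            class = "device_verification")
}

#' @export
print.device_verification <- function(x, ...) {
  cat(sprintf("%d/%d inputs correct%s\n", x$n_pass, x$n_words,
              if (x$equivalent) "" else
                paste0("; failing: ", paste(x$failing_words, collapse = ", "))))
  invisible(x)
}
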