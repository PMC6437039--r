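#' Biological noise model for readout reliability
#'
#' Noise acts at the survival decision and on kinetic parameters, never
#' inside the integrator, so closed-form cross-checks stay available:
#' \itemize{
#'   \item `leak_prob` — probability that a sensitive strain nonetheless
#'     grows (false positive, e.g. resistance leakage or drug degradation);
#'   \item `dropout_prob` — probability that a resistant strain fails to
#'     grow (false negative, e.g. plasmid loss or a bad inoculum);
#'   \item `mu_cv`, `inoculum_cv` — coefficients of variation of per-strain
#'     growth rate and initial biomass, drawn log-normally with the stated
#'     mean and CV.
#' }
#' Flips are independent per strain, per well and per replicate.
#'
#' @param leak_prob,dropout_prob probabilities in \[0, 1\].
#' @param mu_cv,inoculum_cv coefficients of variation (>= 0).
#' @param seed optional default seed; an explicit seed passed to the
#'   simulation functions takes precedence.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(leak_prob = 0, dropout_prob = 0, mu_cv = 0,
                        inoculum_cv = 0, seed = NULL) {
  stopifnot(leak_prob >= 0, leak_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            mu_cv >= 0, inoculum_cv >= 0)
  structure(list(leak_prob = leak_prob, dropout_prob = dropout_prob,
                 mu_cv = mu_cv, inoculum_cv = inoculum_cv, seed = seed),
            class = "noise_model")
}

# Sample noisy survival masks and kinetic parameters for one well.
# surv: (n_reps x n_strains) logical matrix of noise-free survival (rows
# identical). Uniforms are always drawn so that runs with different
# leak/dropout probabilities but the same seed stay coupled (matched
# randomness for monotonicity comparisons).
draw_noise <- function(surv, n_reps, noise, params) {
  n <- ncol(surv)
  u <- matrix(stats::runif(n_reps * n), n_reps, n)
  p_flip <- ifelse(surv, noise$dropout_prob, noise$leak_prob)
  flipped <- u < p_flip
  surv_out <- xor(surv, flipped)
  mu <- matrix(params$mu, n_reps, n)
  if (noise$mu_cv > 0) mu <- mu * lognormal_factor(n_reps * n, noise$mu_cv)
  B0 <- matrix(params$inoculum_fraction * params$K, n_reps, n)
  if (noise$inoculum_cv > 0) {
    B0 <- B0 * lognormal_factor(n_reps * n, noise$inoculum_cv)
  }
  list(surv = surv_out, mu = mu, B0 = B0)
}

# multiplicative log-normal jitter with mean 1 and the given CV
lognormal_factor <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Vectorized noisy endpoint readouts: binary output of every well of the
# plate under `word`, for n_reps independent replicates, integrating all
# replicates of a well simultaneously. Returns an (n_reps x n_wells) 0/1
# matrix. Caller owns the RNG state.
noisy_binary_matrix <- function(plate, word, noise, n_reps, params) {
  drugs <- drugs_for_word(word, plate$encoding)
  threshold <- params$theta * params$K
  out <- matrix(0L, n_reps, length(plate$wells))
  for (j in seq_along(plate$wells)) {
    mix <- plate$wells[[j]]$mixture
    if (length(mix) == 0) next  # empty well never grows
    base <- vapply(mix, survives, logical(1), drugs = drugs)
    surv <- matrix(base, n_reps, length(mix), byrow = TRUE)
    drawn <- draw_noise(surv, n_reps, noise, params)
    res <- grow_core(drawn$B0, drawn$mu, drawn$surv, params$delta,
                     params$K, params$t_read, params$dt, threshold)
    out[, j] <- as.integer(res$total >= threshold)
  }
  out
}

#' Monte-Carlo readout reliability
#'
#' Estimates, for each input word, the fraction of noisy replicates whose
#' plate readout is fully correct (every well matches the design's on_set
#' semantics), and the mean per-well accuracy. With `n_replicates = 2k + 1`
#' each trial reads the plate that many times independently and takes a
#' per-well majority vote before scoring, quantifying how population-level
#' redundancy buys back reliability from noisy individual readouts.
#'
#' Output is reproducible bit-for-bit for a fixed seed; runs that differ
#' only in leak/dropout probabilities share the same underlying uniform
#' draws, so reliability comparisons across noise levels are matched.
#'
#' @param plate a [plate_design()].
#' @param noise a [noise_model()].
#' @param n_reps number of Monte-Carlo trials per word (>= 1).
#' @param seed integer seed (mandatory).
#' @param words words to test; defaults to all `2^n`.
#' @param n_replicates odd number of plate replicates per trial
#'   (1 = no voting).
#' @param params a [growth_params()].
#' @param reference optional [boolean_function()]; when given, the expected
#'   binary pattern is taken from its truth table (well labels must match
#'   output names) instead of from the plate's on_sets.
#' @return a `reliability_table`: data.frame with columns `word`,
#'   `reliability` (fraction of trials fully correct), `well_accuracy`
#'   (mean per-well correctness) and `n_reps`; the overall mean reliability
#'   is attached as attribute `overall`.
#' @export
monte_carlo_reliability <- function(plate, noise, n_reps, seed,
                                    words = NULL, n_replicates = 1,
                                    params = growth_params(),
                                    reference = NULL) {
  stopifnot(inherits(plate, "plate_design"), inherits(noise, "noise_model"),
            n_reps >= 1)
  if (missing(seed) || is.null(seed)) seed <- noise$seed
  if (is.null(seed)) stop("'seed' is mandatory for Monte-Carlo runs")
  if (n_replicates %% 2 == 0) {
    stop("'n_replicates' must be odd (majority voting needs a tiebreaker)")
  }
  if (is.null(words)) words <- word_strings(n_bits(plate$encoding))
  labels <- vapply(plate$wells, function(w) w$label, character(1))
  expected_for <- function(word) {
    if (is.null(reference)) {
      vapply(plate$wells, function(w) as.integer(word %in% w$on_set),
             integer(1))
    } else {
      vals <- eval_function(reference, word)
      unname(vals[labels])
    }
  }
  if (!is.null(reference) && !setequal(labels, names(reference$outputs))) {
    stop("plate well labels do not match the reference function's outputs")
  }
  rows <- with_seed(seed, {
    lapply(words, function(word) {
      expected <- expected_for(word)
      bin <- noisy_binary_matrix(plate, word, noise,
                                 n_reps * n_replicates, params)
      if (n_replicates > 1) {
        arr <- array(bin, c(n_replicates, n_reps, ncol(bin)))
        bin <- apply(arr, c(2, 3), function(v) {
          as.integer(sum(v) * 2 > length(v))
        })
      }
      correct <- bin == matrix(expected, nrow(bin), length(expected),
                               byrow = TRUE)
      data.frame(word = word,
                 reliability = mean(apply(correct, 1, all)),
                 well_accuracy = mean(correct),
                 n_reps = n_reps, stringsAsFactors = FALSE)
    })
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  structure(tbl, overall = mean(tbl$reliability),
            n_replicates = n_replicates,
            class = c("reliability_table", "data.frame"))
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("<reliability_table> overall reliability ",
      signif(attr(x, "overall"), 4),
      " (", attr(x, "n_replicates"), " replicate(s)/trial)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Majority-vote consensus of replicate readouts
#'
#' Per-well majority over an odd number of plate readouts of identical
#' shape — the redundancy mechanism that gives a population-based readout
#' its fault tolerance: with per-well accuracy p > 1/2, three replicates
#' read correctly with probability p^3 + 3 p^2 (1 - p) > p.
#'
#' @param readouts list of `plate_readout` objects, odd length, same grid.
#' @return a consensus `plate_readout` (binary/color matrices only; no
#'   biomass trajectories).
#' @export
majority_vote <- function(readouts) {
  stopifnot(is.list(readouts), length(readouts) >= 1)
  if (length(readouts) %% 2 == 0) {
    stop("an odd number of replicates is required (ties are ambiguous)")
  }
  shapes <- vapply(readouts, function(r) paste(r$grid_shape, collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) stop("replicate grids differ in shape")
  stack <- simplify2array(lapply(readouts, function(r) r$binary))
  votes <- apply(stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_integer_ else as.integer(sum(v) * 2 > length(v))
  })
  consensus <- readouts[[1]]
  consensus$binary <- votes
  consensus$color <- ifelse(is.na(votes), NA_character_,
                            ifelse(votes == 1L, "yellow", "blue"))
  consensus$wells <- NULL
  consensus$device_name <- paste0(consensus$device_name, " (consensus of ",
                                  length(readouts), ")")
  consensus
}

#' Write a reliability table to CSV
#'
#' @param tbl a `reliability_table`.
#' @param path output file.
#' @export
write_reliability <- function(tbl, path) {
  stopifnot(inherits(tbl, "reliability_table"))
  write_atomic(path, function(tmp) {
    utils::write.csv(as.data.frame(tbl), tmp, row.names = FALSE)
  })
}
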