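enc <- default_encoding()

test_that("survival is the conjunction over drugs present", {
  cts <- genotype_for_word("101", enc)
  expect_true(survives(cts, drugs_for_word("101", enc)))
  expect_false(survives(cts, drugs_for_word("000", enc)))
  expect_true(survives(cts, list()))  # vacuous AND
  expect_true(survives(cts, drugs_for_word("101", enc)[1:2]))  # subset
})

test_that("growth_params rejects out-of-range values", {
  expect_error(growth_params(theta = 1.2), "theta")
  expect_error(growth_params(inoculum_fraction = 0.6), "inoculum_fraction")
  expect_error(growth_params(dt = 0), "positive")
  expect_error(growth_params(mu = -1), "rates")
})

test_that("a lone resistant strain crosses threshold near 12 h and reads 1 at 18 h", {
  st <- simulate_well(list(genotype_for_word("101", enc)),
                      drugs_for_word("101", enc))
  expect_equal(st$binary_output, 1L)
  expect_equal(st$color, "yellow")
  expect_lt(abs(st$threshold_crossing_time - 12), 0.5)
  expect_equal(max(st$times), 18)
})

test_that("sensitive-only and empty wells stay blue", {
  dead <- simulate_well(list(genotype_for_word("000", enc)),
                        drugs_for_word("111", enc))
  expect_equal(dead$binary_output, 0L)
  expect_equal(dead$color, "blue")
  expect_true(is.na(dead$threshold_crossing_time))
  # sensitive biomass has decayed well below its inoculum by 18 h
  expect_lt(dead$final_biomass, 0.01 * 0.01)

  empty <- simulate_well(list(), drugs_for_word("111", enc))
  expect_equal(empty$binary_output, 0L)
  expect_equal(empty$final_biomass, 0)
})

test_that("trajectories are non-negative and bounded by the carrying capacity", {
  p <- growth_params()
  mix <- lapply(c("101", "111", "000"), genotype_for_word, enc = enc)
  st <- simulate_well(mix, drugs_for_word("101", enc), p)
  expect_true(all(st$biomass >= 0))
  expect_true(all(st$total <= p$K * (1 + 1e-9)))
})

test_that("single-strain endpoint matches the analytic logistic to 1e-6", {
  p <- growth_params()
  st <- simulate_well(list(genotype_for_word("101", enc)),
                      drugs_for_word("101", enc), p)
  expected <- logistic_closed_form(st$times, p$mu, p$K,
                                   p$inoculum_fraction * p$K)
  rel <- abs(st$total - expected) / expected
  expect_lt(max(rel), 1e-6)
})

test_that("the integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- growth_params()
  mix <- lapply(c("101", "111", "000"), genotype_for_word, enc = enc)
  drugs <- drugs_for_word("101", enc)
  st <- simulate_well(mix, drugs, p)
  surv <- vapply(mix, survives, logical(1), drugs = drugs)
  rhs <- function(t, y, parms) {
    list(ifelse(surv, p$mu * y * (1 - sum(y) / p$K), -p$delta * y))
  }
  ref <- deSolve::ode(y = rep(p$inoculum_fraction * p$K, 3), times = st$times,
                      func = rhs, parms = NULL, method = "rk4")
  expect_lt(max(abs(ref[, -1] - st$biomass)), 1e-8)
})

test_that("halving dt changes the endpoint by less than 1e-6 K", {
  p1 <- growth_params()
  p2 <- growth_params(dt = p1$dt / 2)
  mix <- lapply(c("101", "111"), genotype_for_word, enc = enc)
  s1 <- simulate_well(mix, drugs_for_word("101", enc), p1)
  s2 <- simulate_well(mix, drugs_for_word("101", enc), p2)
  expect_lt(abs(s1$final_biomass - s2$final_biomass), 1e-6 * p1$K)
})

test_that("per-strain growth-rate overrides shift crossing times", {
  mix <- list(genotype_for_word("101", enc))
  drugs <- drugs_for_word("101", enc)
  slow <- simulate_well(mix, drugs, mu_per_strain = 0.3)
  fast <- simulate_well(mix, drugs, mu_per_strain = 0.6)
  expect_gt(slow$threshold_crossing_time, fast$threshold_crossing_time)
  expect_error(simulate_well(mix, drugs, mu_per_strain = c(0.3, 0.4)),
               "mu_per_strain")
})

test_that("threshold-crossing time decreases strictly with growth rate", {
  # slowest mu still crosses theta before t_read (ln(99)/0.3 ~ 15.3 h < 18 h)
  times <- vapply(c(0.3, 0.4, 0.5, 0.6, 0.8), function(mu) {
    st <- simulate_well(list(genotype_for_word("101", enc)),
                        drugs_for_word("101", enc), growth_params(mu = mu))
    st$threshold_crossing_time
  }, numeric(1))
  expect_true(all(diff(times) < 0))
})

test_that("noise-free well readout equals set-logic membership for n <= 3", {
  for (n in 1:3) {
    senc <- synthetic_encoding(n)
    words <- word_strings(n)
    on_sets <- list(character(0), words, words[1],
                    minterms(random_function(n, 1, seed = n), "out0"))
    for (on_set in on_sets) {
      plate <- single_well_plate(on_set, senc)
      for (w in words) {
        ro <- simulate_plate(plate, w)
        expect_identical(ro$binary[1, 1], as.integer(w %in% on_set),
                         info = paste("n", n, "word", w, "on_set",
                                      paste(on_set, collapse = ",")))
      }
    }
  }
})

test_that("plate simulation is deterministic and aligned to the grid", {
  plate <- one_hot_array(enc)
  r1 <- simulate_plate(plate, "101")
  r2 <- simulate_plate(plate, "101")
  expect_identical(r1$binary, r2$binary)
  expect_equal(dim(r1$binary), c(8L, 1L))
  expect_equal(sum(r1$binary), 1L)
  expect_error(simulate_plate(plate, "10"), "3")
})

test_that("noisy well simulation needs a seed and is seed-reproducible", {
  mix <- list(genotype_for_word("101", enc))
  drugs <- drugs_for_word("000", enc)
  nm <- noise_model(leak_prob = 0.5)
  expect_error(simulate_well(mix, drugs, noise = nm), "seed")
  s1 <- simulate_well(mix, drugs, noise = nm, seed = 11)
  s2 <- simulate_well(mix, drugs, noise = nm, seed = 11)
  expect_identical(s1$binary_output, s2$binary_output)
  outs <- vapply(1:40, function(s) {
    simulate_well(mix, drugs, noise = nm, seed = s)$binary_output
  }, integer(1))
  expect_true(any(outs == 1) && any(outs == 0))  # leak flips do occur
})

test_that("display decoding is exact-match with informative failures", {
  bundle <- build_display()
  ro <- simulate_plate(bundle$plate, "110")
  expect_equal(decode_display(ro), 6L)
  expect_equal(decode_display(simulate_plate(bundle$plate, "000")), 0L)
  # corrupt one pixel: exact decode errors with the Hamming distance,
  # nearest-glyph mode recovers the digit
  ro$binary[1, 1] <- 1L - ro$binary[1, 1]
  expect_error(decode_display(ro), "Hamming distance 1")
  expect_equal(decode_display(ro, nearest = TRUE), 6L)
  ro$binary[] <- 0L
  expect_error(decode_display(ro), "no glyph|equidistant|Hamming")
})

test_that("verify_device reports exact failing words for a corrupted plate", {
  f <- full_adder()
  plate <- compile_function(f, enc)
  rep_ok <- verify_device(plate, f)
  expect_true(rep_ok$equivalent)
  expect_equal(rep_ok$n_pass, 8)

  # removing the CKS strain from the S well must flip S exactly at 111
  bad <- plate
  i <- which(vapply(bad$wells, function(w) w$label, character(1)) == "S")
  keep <- names(bad$wells[[i]]$mixture) != "CKS"
  bad$wells[[i]]$mixture <- bad$wells[[i]]$mixture[keep]
  bad$wells[[i]]$on_set <- setdiff(bad$wells[[i]]$on_set, "111")
  rep_bad <- verify_device(bad, f)
  expect_false(rep_bad$equivalent)
  expect_equal(rep_bad$failing_words, "111")
  fails <- rep_bad$results[!rep_bad$results$pass, ]
  expect_equal(fails$output, "S")

  expect_error(verify_device(plate, full_subtractor()), "labels")
})
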