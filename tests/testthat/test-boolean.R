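test_that("word string/value conversion is a bijection", {
  for (n in c(1, 3, 8)) {
    words <- word_strings(n)
    expect_length(words, 2^n)
    expect_false(anyDuplicated(words) > 0)
    vals <- vapply(words, word_value, numeric(1))
    expect_equal(unname(vals), 0:(2^n - 1))
    expect_equal(vapply(vals, word_from_value, character(1), n_bits = n),
                 words, ignore_attr = TRUE)
  }
  expect_equal(word_value("110"), 6)  # leftmost character is the MSB
  expect_error(word_value("10a"), "not a binary")
  expect_error(word_bits("2"), "not a binary")
})

test_that("minterms and maxterms partition the word space", {
  f <- full_adder()
  expect_setequal(minterms(f, "S"), c("001", "010", "100", "111"))
  expect_setequal(minterms(f, "Cout"), c("011", "101", "110", "111"))
  for (out in names(f$outputs)) {
    expect_setequal(c(minterms(f, out), maxterms(f, out)), word_strings(3))
    expect_length(intersect(minterms(f, out), maxterms(f, out)), 0)
  }
  zero <- boolean_function(3, list(z = rep(0, 8)))
  expect_length(minterms(zero, "z"), 0)
  one_bit <- boolean_function(1, list(id = c(0, 1)))
  expect_equal(minterms(one_bit, "id"), "1")
  expect_error(minterms(f, "nope"), "unknown output")
})

test_that("full adder and subtractor satisfy their arithmetic identities", {
  ad <- full_adder()
  sub <- full_subtractor()
  for (w in word_strings(3)) {
    b <- word_bits(w)
    a_out <- eval_function(ad, w)
    expect_equal(sum(b), 2 * a_out[["Cout"]] + a_out[["S"]],
                 info = paste("adder word", w))
    s_out <- eval_function(sub, w)
    expect_equal(b[1] - b[2] - b[3], s_out[["D"]] - 2 * s_out[["Bout"]],
                 info = paste("subtractor word", w))
  }
  expect_equal(eval_function(ad, "101"), c(S = 0L, Cout = 1L))
  expect_equal(eval_function(ad, "000"), c(S = 0L, Cout = 0L))
  expect_equal(eval_function(ad, "111"), c(S = 1L, Cout = 1L))
  expect_equal(eval_function(sub, "011"), c(D = 0L, Bout = 1L))
  expect_equal(eval_function(sub, "110"), c(D = 0L, Bout = 0L))
  expect_equal(eval_function(sub, "001"), c(D = 1L, Bout = 1L))
})

test_that("boolean_function validates totality, names and values", {
  expect_error(boolean_function(2, list(f = c("00" = 0, "01" = 1))),
               "not total")
  expect_error(boolean_function(2, list(f = c(0, 1, 2, 0))), "0 or 1")
  expect_error(boolean_function(2, list(a = c(0, 0, 0, 0),
                                        a = c(1, 1, 1, 1))), "unique")
  f <- boolean_function(2, list(c(0, 1, 1, 0), c(1, 0, 0, 1)))
  expect_equal(names(f$outputs), c("out0", "out1"))
  # named input in scrambled word order is accepted and reordered
  g <- boolean_function(1, list(f = c("1" = 1, "0" = 0)))
  expect_equal(unname(g$outputs$f), c(0L, 1L))
})

test_that("random_function is seed-reproducible and leaves the RNG alone", {
  f1 <- random_function(3, 2, seed = 7)
  f2 <- random_function(3, 2, seed = 7)
  expect_identical(f1, f2)
  expect_false(identical(f1, random_function(3, 2, seed = 8)))
  expect_error(random_function(3, 1), "seed")
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(random_function(3, 1, seed = 1))
  expect_identical(runif(1), before)
})

test_that("minterm counts of random 3-bit functions look Binomial(8, 1/2)", {
  counts <- vapply(1:100, function(s) {
    length(minterms(random_function(3, 1, seed = s), "out0"))
  }, numeric(1))
  expect_true(all(counts >= 0 & counts <= 8))
  # mean 4, per-function sd sqrt(2); 3 standard errors over 100 draws
  expect_lt(abs(mean(counts) - 4), 3 * sqrt(2) / sqrt(100))
  expect_gt(stats::var(counts), 0)
})

test_that("truth-table JSON round-trips and validates", {
  f <- full_subtractor()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_table(f, path)
  expect_identical(read_truth_table(path), f)
  bad <- jsonlite::read_json(path)
  bad$outputs$D[["000"]] <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_truth_table(path2), "not total")
})
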