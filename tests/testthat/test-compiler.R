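test_that("compiled function wells mix exactly the minterm genotypes", {
  enc <- default_encoding()
  plate <- compile_function(full_adder(), enc)
  expect_length(plate$wells, 2)
  labels <- vapply(plate$wells, function(w) w$label, character(1))
  expect_equal(labels, c("S", "Cout"))
  expect_setequal(names(plate$wells[[1]]$mixture),
                  c("ATS", "AKG", "CTG", "CKS"))
  expect_setequal(names(plate$wells[[2]]$mixture),
                  c("AKS", "CTS", "CKG", "CKS"))
  for (w in plate$wells) expect_length(w$mixture, length(w$on_set))

  const1 <- compile_function(boolean_function(3, list(one = rep(1, 8))), enc)
  expect_length(const1$wells[[1]]$mixture, 8)
  const0 <- compile_function(boolean_function(3, list(zero = rep(0, 8))), enc)
  expect_length(const0$wells[[1]]$mixture, 0)

  expect_error(compile_function(boolean_function(2, list(f = rep(0, 4))),
                                enc), "arity")
})

test_that("display compiles to 15 wells on a 5x3 grid with glyph-driven mixtures", {
  font <- digit_font()
  plate <- compile_display(font, default_encoding())
  expect_equal(plate$grid_shape, c(5L, 3L))
  expect_length(plate$wells, 15)
  for (w in plate$wells) {
    lit <- vapply(word_strings(3), function(word) {
      glyph(font, word_value(word))[w$row, w$col] == 1L
    }, logical(1))
    expect_setequal(w$on_set, word_strings(3)[lit])
    expect_length(w$mixture, length(w$on_set))
  }
  # a pixel lit by every digit mixes the whole library; every pixel of this
  # font is lit by at least one digit, so no well is empty
  sizes <- vapply(plate$wells, function(w) length(w$mixture), integer(1))
  expect_true(any(sizes == 8))
  expect_true(all(sizes >= 1))
  expect_error(compile_display(font, synthetic_encoding(2)), "3-bit")
})

test_that("one-hot arrays hold one library strain per word", {
  for (n in 1:3) {
    enc <- synthetic_encoding(n)
    plate <- one_hot_array(enc)
    expect_length(plate$wells, 2^n)
    sizes <- vapply(plate$wells, function(w) length(w$mixture), integer(1))
    expect_true(all(sizes == 1))
    on_sets <- vapply(plate$wells, function(w) w$on_set, character(1))
    expect_setequal(on_sets, word_strings(n))
  }
  # 1-bit array wells have complementary on_sets
  p1 <- one_hot_array(synthetic_encoding(1))
  expect_setequal(c(p1$wells[[1]]$on_set, p1$wells[[2]]$on_set), c("0", "1"))
})

test_that("validate_design flags structural faults and passes shipped devices", {
  enc <- default_encoding()
  for (plate in list(compile_function(full_adder(), enc),
                     one_hot_array(enc))) {
    issues <- validate_design(plate)
    expect_equal(nrow(issues), 0)
  }
  expect_equal(nrow(validate_design(compile_display(digit_font(), enc))), 0)

  dup <- list(encoding = enc, grid_shape = c(2L, 2L),
              wells = list(well_spec(1, 1, "a", "000", enc),
                           well_spec(1, 1, "b", "001", enc)))
  issues <- validate_design(dup)
  expect_true(any(grepl("duplicate", issues$message)))

  outside <- list(encoding = enc, grid_shape = c(1L, 1L),
                  wells = list(well_spec(2, 1, "a", "000", enc)))
  expect_true(any(grepl("outside", validate_design(outside)$message)))

  broken <- well_spec(1, 1, "S", c("001", "010"), enc)
  broken$mixture <- broken$mixture[1]  # drop a minterm genotype
  issues <- validate_design(list(encoding = enc, grid_shape = c(1L, 1L),
                                 wells = list(broken)))
  expect_true(any(grepl("inconsistent", issues$message)))

  empty <- list(encoding = enc, grid_shape = c(1L, 1L),
                wells = list(well_spec(1, 1, "z", character(0), enc)))
  issues <- validate_design(empty)
  expect_true(all(issues$severity == "warning"))

  expect_error(plate_design(enc, dup$wells, c(2, 2)), "duplicate")
})

test_that("digit font glyphs are distinct 5x3 masks and user fonts validate", {
  font <- digit_font()
  expect_length(font$glyphs, 8)
  keys <- vapply(font$glyphs, function(m) paste(m, collapse = ""),
                 character(1))
  expect_length(unique(keys), 8)
  for (m in font$glyphs) expect_equal(dim(m), c(5L, 3L))
  bad <- font$glyphs
  bad[["7"]] <- bad[["1"]]
  expect_error(digit_font(bad), "distinct")
  expect_error(digit_font(font$glyphs[1:7]), "glyphs named")
})
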