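test_that("the quartet has the canonical structure", {
  a <- anscombe_quartet()
  expect_named(a, c("I", "II", "III", "IV"))
  for (d in a) {
    expect_length(d$x, 11)
    expect_length(d$y, 11)
    rc <- reference_coefficients(d$x, d$y)
    expect_equal(round(rc$pearson, 2), 0.82)
  }
  expect_identical(a$I$x, a$II$x)
  expect_identical(a$I$x, a$III$x)
})

test_that("generators are bit-identical under the same seed", {
  for (nm in c("random", "non_coexistence", "quadratic", "two_lines")) {
    d1 <- make_pattern(nm, n = 50, seed = 99)
    d2 <- make_pattern(nm, n = 50, seed = 99)
    expect_identical(d1, d2)
    expect_false(identical(d1$y, make_pattern(nm, n = 50, seed = 100)$y))
  }
  expect_identical(make_categorical_pattern("cat_num_assoc", seed = 7),
                   make_categorical_pattern("cat_num_assoc", seed = 7))
  expect_identical(make_substructure("diagonal", n = 100, seed = 7),
                   make_substructure("diagonal", n = 100, seed = 7))
})

test_that("generators do not disturb the caller's random stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(make_pattern("random", seed = 1))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("unknown pattern names and bad sizes error", {
  expect_error(make_pattern("spiral"))
  expect_error(make_pattern("random", n = 3), "at least 4")
  expect_error(make_categorical_pattern("cat_num_assoc", n = 5), "at least 9")
  expect_error(make_substructure("diagonal", n = 7), "even")
})

test_that("non-coexistence places points on opposite axes", {
  d <- make_pattern("non_coexistence", n = 200, seed = 2)
  expect_true(all(pmin(d$x, d$y) <= 0.1))
  expect_true(all(pmax(d$x, d$y) >= 1))
})

test_that("categorical-numerical association recovers the stated mixture", {
  d <- make_categorical_pattern("cat_num_assoc", n = 30000, seed = 13)
  mu <- tapply(d$y, d$x, mean)
  sig <- tapply(d$y, d$x, sd)
  expect_equal(as.vector(mu[c("A", "B", "C")]), c(0, 1, 1), tolerance = 0.05)
  expect_equal(as.vector(sig[c("A", "B", "C")]), c(0.5, 0.25, 0.75),
               tolerance = 0.05)
  # categories are roughly uniform
  expect_true(all(abs(table(d$x) / 30000 - 1 / 3) < 0.02))
})

test_that("two-categorical association skews the stated cells", {
  d <- make_categorical_pattern("two_cat_assoc", n = 20000, seed = 17)
  pb <- tapply(d$x == "blue", d$y, mean)
  expect_gt(pb[["A"]], 0.75)
  expect_lt(pb[["B"]], 0.35)
})

test_that("substructure clusters sit at the requested orientation", {
  for (o in c("diagonal", "horizontal", "vertical")) {
    d <- make_substructure(o, n = 400, seed = 23, separation = 5)
    cl <- d$params$cluster
    dx <- abs(diff(tapply(d$x, cl, mean)))
    dy <- abs(diff(tapply(d$y, cl, mean)))
    if (o != "vertical") expect_gt(dx, 4) else expect_lt(dx, 0.5)
    if (o != "horizontal") expect_gt(dy, 4) else expect_lt(dy, 0.5)
  }
})

test_that("reference coefficients are the textbook quantities", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1)
  y <- x^3
  rc <- reference_coefficients(x, y)
  expect_equal(rc$pearson, cor(x, y))
  expect_equal(rc$spearman, 1)
  expect_identical(reference_coefficients(x, x)$pearson, 1)
  expect_error(reference_coefficients(c("a", "b", "c"), 1:3), "numerical")
  expect_error(reference_coefficients(1:2, 1:2), "at least 3")
})
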