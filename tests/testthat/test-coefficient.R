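test_that("perfect monotone relationships give ccc = 1", {
  x <- seq_len(20)
  expect_equal(ccc(x, 2 * x), 1)
  expect_equal(ccc(x, -x), 1)       # clusters still match under reversal
  expect_equal(ccc(x, exp(x / 5)), 1)
})

test_that("ties on the maximum resolve to the least complex partition pair", {
  x <- seq_len(30)
  r <- ccc_pair(x, 3 * x + 1)
  expect_equal(r$value, 1)
  # ARI = 1 at every matched k; smallest kx*ky wins
  expect_equal(r$kx, 2)
  expect_equal(r$ky, 2)
  expect_equal(r$labels_x, r$labels_y)
})

test_that("ccc is symmetric and bounded in [0, 1]", {
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(10:80, 1)
    x <- rnorm(n)
    y <- if (rep %% 3 == 0) sample(letters[1:3], n, TRUE) else rnorm(n)
    a <- ccc(x, y)
    expect_gte(a, 0)
    expect_lte(a, 1)
    expect_equal(a, ccc(y, x))
  }
})

test_that("ccc is invariant under strictly increasing transforms", {
  set.seed(17)
  x <- rnorm(100)
  y <- x^2 + rnorm(100, 0, 0.3)
  base <- ccc(x, y)
  expect_equal(ccc(exp(x), y), base)
  expect_equal(ccc(x, y^3 + 10), base)
})

test_that("ccc is non-decreasing in kmax", {
  set.seed(29)
  x <- runif(200, -2, 2)
  y <- x^2 + rnorm(200, 0, 0.4)
  vals <- vapply(c(2, 3, 5, 8, 10, 14), function(k) ccc(x, y, kmax = k), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("constant variables give an undefined coefficient with a warning", {
  expect_warning(r <- ccc_pair(rep(1, 10), rnorm(10)), "undefined")
  expect_true(is.na(r$value))
  expect_warning(v <- ccc(rnorm(10), rep("A", 10)), "undefined")
  expect_true(is.na(v))
})

test_that("input contracts: lengths, size, missing values", {
  expect_error(ccc(1:5, 1:6), "same length")
  expect_error(ccc(1, 1), "at least 2")
  expect_error(ccc(c(1, NA, 3, 4), c(1, 2, 3, 4)), "missing")
  # pairwise-complete mode drops objects missing in either variable
  x <- c(1, NA, 3, 4, 5, 6, 7, 8)
  y <- c(8, 7, 6, NA, 4, 3, 2, 1)
  expect_equal(ccc(x, y, na_action = "pairwise-complete"), 1)
})

test_that("categorical-numerical pairs compare categories to quantile clusters", {
  set.seed(41)
  z <- rep(c("A", "B"), each = 30)
  y <- rnorm(60, ifelse(z == "A", 0, 5), 0.5)  # cleanly separated by category
  r <- ccc_pair(z, y)
  expect_equal(r$value, 1)
  expect_equal(r$kx, 2)
  expect_equal(sort(unique(r$labels_x)), 1:2)
})

test_that("candidate cluster counts are capped near sqrt(n)", {
  # at n = 11 only k = 2, 3 are candidates, so a pattern that rewards finer
  # partitions cannot use them
  a2 <- anscombe_xy("II")
  r <- ccc_pair(a2$x, a2$y, kmax = 10)
  expect_lte(r$kx, 3)
  expect_lte(r$ky, 3)
  # at n >= 100 the full k range up to kmax is available
  set.seed(3)
  d <- make_pattern("two_lines", n = 100, seed = 3)
  r2 <- ccc_pair(d$x, d$y, kmax = 10)
  expect_gte(max(r2$kx, r2$ky), 4)
})

test_that("ccc_matrix matches pairwise recomputation and handles mixed types", {
  set.seed(53)
  rows <- list(g1 = rnorm(40), g2 = rnorm(40)^2, g3 = sample(c("m", "f"), 40, TRUE))
  cm <- ccc_matrix(rows)
  expect_length(cm$condensed, 3)
  expect_equal(cm$condensed[1], ccc(rows$g1, rows$g2))
  expect_equal(cm$condensed[2], ccc(rows$g1, rows$g3))
  expect_equal(cm$condensed[3], ccc(rows$g2, rows$g3))
})

test_that("duplicated rows correlate at exactly 1", {
  m <- rbind(a = rnorm(30), b = rnorm(30))
  m <- rbind(m, a2 = m["a", ])
  cm <- ccc_matrix(m)
  df <- as.data.frame(cm)
  expect_equal(df$ccc[df$var_i == "a" & df$var_j == "a2"], 1)
})

test_that("ccc_matrix output is identical for any worker count", {
  set.seed(61)
  m <- matrix(rnorm(8 * 50), nrow = 8,
              dimnames = list(paste0("g", 1:8), NULL))
  cm1 <- ccc_matrix(m, jobs = 1, permutations = 200, seed = 9)
  cm3 <- ccc_matrix(m, jobs = 3, permutations = 200, seed = 9)
  expect_identical(as.data.frame(cm1), as.data.frame(cm3))
})

test_that("constant rows yield NA entries but the run completes", {
  m <- rbind(a = rnorm(20), flat = rep(2, 20), b = rnorm(20))
  expect_warning(cm <- ccc_matrix(m), "constant")
  df <- as.data.frame(cm)
  expect_true(all(is.na(df$ccc[df$var_i == "flat" | df$var_j == "flat"])))
  expect_false(anyNA(df$ccc[df$var_i == "a" & df$var_j == "b"]))
})

test_that("ragged inputs error", {
  expect_error(ccc_matrix(list(a = 1:10, b = 1:9)), "ragged")
})

test_that("square form is symmetric with unit diagonal", {
  m <- rbind(a = 1:12, b = (1:12)^2, c = rnorm(12))
  sq <- as.matrix(ccc_matrix(m))
  expect_equal(sq, t(sq))
  expect_equal(unname(diag(sq)), rep(1, 3))
  expect_equal(sq["a", "b"], 1)
})

test_that("condensed indexing is a row-major bijection", {
  expect_equal(condensed_index(1, 2, 4), 1)
  expect_equal(condensed_index(3, 4, 4), 6)
  # full enumeration order for n = 4: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  got <- unlist(lapply(1:3, function(i)
    vapply((i + 1):4, function(j) condensed_index(i, j, 4), 0L)))
  expect_equal(got, 1:6)
  for (idx in 1:45) {
    ij <- condensed_pair(idx, 10)
    expect_equal(condensed_index(ij[1], ij[2], 10), idx)
  }
  expect_error(condensed_index(3, 3, 5), "smaller")
})
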