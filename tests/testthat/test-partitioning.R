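test_that("quantile cutpoints use rank-based linear interpolation", {
  expect_equal(quantile_cutpoints(1:10, 2), 5.5)
  expect_equal(quantile_cutpoints(rep(3.2, 7), 5), rep(3.2, 4))
  # near-constant vector with one outlier: all interior quantiles sit on the
  # repeated value
  x4 <- anscombe_xy("IV")$x
  expect_equal(quantile_cutpoints(x4, 10), rep(8, 9))
  expect_error(quantile_cutpoints(numeric(0), 2), "non-empty")
  expect_error(quantile_cutpoints(1:5, 1), ">= 2")
})

test_that("numerical partitions are equal-frequency on the rank scale", {
  p <- partition_numeric(1:10, 2)
  expect_s3_class(p, "ccc_partition")
  expect_equal(p$labels, rep(1:2, each = 5))
  expect_equal(p$k, 2)

  p3 <- partition_numeric(c(5, 1, 9, 3, 7, 2, 8, 4, 6), 3)
  expect_equal(p3$k, 3)
  expect_equal(as.vector(tabulate(p3$labels)), c(3, 3, 3))
  # cluster order follows value order
  expect_equal(p3$labels[order(c(5, 1, 9, 3, 7, 2, 8, 4, 6))],
               rep(1:3, each = 3))
})

test_that("degenerate numerical partitions are invalid, not errors", {
  expect_null(partition_numeric(rep(4.2, 6), 2))
  expect_null(partition_numeric(rep(4.2, 6), 5))
  expect_error(partition_numeric(5, 2), "at least 2")
  expect_error(partition_numeric(1:10, 1), ">= 2")
  expect_error(partition_numeric(c(1, NA, 3), 2), "missing")
})

test_that("tied groups stay together and empty clusters are compacted", {
  # ten identical values and one outlier: the tied block shares its average
  # rank, so every k collapses to the same {10, 1} split
  x4 <- anscombe_xy("IV")$x
  for (k in 2:10) {
    p <- partition_numeric(x4, k)
    expect_equal(p$k, 2)
    expect_equal(as.vector(tabulate(p$labels)), c(10, 1))
  }
  # a middle tie block straddling a boundary moves as one unit
  p <- partition_numeric(c(1, 2, 2, 3), 2)
  expect_equal(p$labels, c(1, 2, 2, 2))
  # sum of cluster sizes is n for valid partitions
  expect_equal(sum(tabulate(p$labels)), 4)
})

test_that("rank invariance: strictly increasing transforms preserve partitions", {
  set.seed(11)
  for (rep in 1:20) {
    v <- rnorm(60)
    k <- sample(2:10, 1)
    f <- sample(list(function(z) exp(z), function(z) z^3,
                     function(z) 5 * z - 2, function(z) atan(z)), 1)[[1]]
    expect_equal(partition_numeric(f(v), k)$labels,
                 partition_numeric(v, k)$labels)
  }
})

test_that("categorical partitions are the categories", {
  p <- partition_categorical(c("red", "green", "blue", "red"))
  expect_equal(p$labels, c(1L, 2L, 3L, 1L))
  expect_equal(p$k, 3)
  expect_null(partition_categorical(c("A", "A", "A")))
  # factors and characters agree
  expect_equal(partition_categorical(factor(c("b", "a", "b")))$k, 2)
})

test_that("generate_partitions yields one candidate per k and dedupes ties", {
  ps <- generate_partitions(1:10, 4)
  expect_length(ps, 3)
  expect_equal(vapply(ps, `[[`, 0L, "source_k"), 2:4)
  expect_identical(attr(ps, "variable_kind"), "numerical")

  # categorical: exactly one partition, independent of kmax
  ps_cat <- generate_partitions(c("a", "b", "c", "a", "b", "c"), 10)
  expect_length(ps_cat, 1)
  expect_identical(attr(ps_cat, "variable_kind"), "categorical")

  # heavy ties collapse every k to the same partition; duplicates are dropped
  ps_tied <- generate_partitions(anscombe_xy("IV")$x, 10)
  expect_length(ps_tied, 1)
  expect_equal(ps_tied[[1]]$source_k, 2)

  # constant variable: empty candidate set
  expect_length(generate_partitions(rep(1, 5), 10), 0)
  expect_error(generate_partitions(1:10, 1), ">= 2")
})

test_that("partitions are deterministic across repeated calls", {
  v <- rnorm(100)
  expect_identical(generate_partitions(v, 10), generate_partitions(v, 10))
})
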