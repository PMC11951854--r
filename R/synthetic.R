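## Run code under a temporary RNG state so generators are seed-deterministic
## without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

new_pattern <- function(x, y, name, params) {
  structure(list(x = x, y = y, pattern_name = name, params = params),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset> '%s', n = %d (x: %s, y: %s)\n",
              x$pattern_name, length(x$x),
              if (is.numeric(x$x)) "numerical" else "categorical",
              if (is.numeric(x$y)) "numerical" else "categorical"))
  invisible(x)
}

#' The Anscombe quartet
#'
#' The four canonical 11-point datasets of Anscombe (1973): identical means,
#' variances and Pearson correlation (0.82) but very different patterns —
#' noisy linear (I), quadratic (II), linear with one outlier (III), and a
#' near-constant x with one outlier (IV). Datasets I-III share the same x.
#' A classic check that a correlation coefficient responds to the pattern and
#' not just to summary statistics.
#'
#' @return Named list (`I`, `II`, `III`, `IV`) of `pattern_dataset` objects,
#'   each with numeric `x` and `y` of length 11.
#' @examples
#' a <- anscombe_quartet()
#' sapply(a, function(d) cor(d$x, d$y)) # all ~0.816
#' @export
anscombe_quartet <- function() {
  a <- datasets::anscombe
  sets <- lapply(1:4, function(i) {
    new_pattern(a[[paste0("x", i)]], a[[paste0("y", i)]],
                paste0("anscombe_", c("I", "II", "III", "IV")[i]),
                list(n = nrow(a)))
  })
  names(sets) <- c("I", "II", "III", "IV")
  sets
}

#' Simulated numerical relationship patterns
#'
#' Generators for the numerical variable-pair patterns used to characterize
#' not-only-linear dependence:
#' \describe{
#'   \item{random}{two independent standard normals — no relationship.}
#'   \item{non_coexistence}{one variable is high while the other is near zero
#'     and vice versa (e.g. mutually exclusive gene expression): with equal
#'     probability `x ~ U(1, 2), y ~ U(0, 0.1)` or the reverse.}
#'   \item{quadratic}{`x ~ U(-2, 2)`, `y = x^2 + e`, `e ~ N(0, noise^2)`;
#'     invisible to linear coefficients, needs >= 4 clusters on x.}
#'   \item{two_lines}{mixture of two linear components with slopes `slopes[1]`
#'     and `slopes[2]` (equal mixing), `x ~ U(-1, 1)`, plus `N(0, noise^2)`
#'     noise; Pearson and Spearman nearly cancel across the two components.}
#' }
#' Noise scales and slopes are exposed parameters; the defaults (noise 0.5
#' for quadratic, 0.15 and slopes `c(1, -1.3)` for two_lines) give the
#' qualitative behavior described for each pattern at `n = 100`.
#'
#' @param name one of `"random"`, `"non_coexistence"`, `"quadratic"`,
#'   `"two_lines"`.
#' @param n number of data points (default 100), at least 4.
#' @param seed integer seed; regeneration with identical parameters is
#'   bit-identical.
#' @param noise noise standard deviation (quadratic, two_lines).
#' @param slopes length-2 numeric, the two mixture slopes (two_lines only).
#' @return A `pattern_dataset` with numeric `x` and `y` and the generator
#'   parameters in `$params`.
#' @examples
#' d <- make_pattern("quadratic", n = 100, seed = 1)
#' ccc(d$x, d$y)
#' @export
make_pattern <- function(name = c("random", "non_coexistence", "quadratic",
                                  "two_lines"),
                         n = 100, seed = 1, noise = NULL, slopes = c(1, -1.3)) {
  name <- match.arg(name)
  n <- as.integer(n)
  if (n < 4) stop("'n' must be at least 4")
  with_seed(seed, {
    d <- switch(name,
      random = {
        list(x = rnorm(n), y = rnorm(n))
      },
      non_coexistence = {
        active <- runif(n) < 0.5
        hi_x <- runif(n, 1, 2); lo_x <- runif(n, 0, 0.1)
        hi_y <- runif(n, 1, 2); lo_y <- runif(n, 0, 0.1)
        list(x = ifelse(active, hi_x, lo_x), y = ifelse(active, lo_y, hi_y))
      },
      quadratic = {
        if (is.null(noise)) noise <- 0.5
        x <- runif(n, -2, 2)
        list(x = x, y = x^2 + rnorm(n, 0, noise))
      },
      two_lines = {
        if (is.null(noise)) noise <- 0.15
        x <- runif(n, -1, 1)
        g <- runif(n) < 0.5
        list(x = x, y = ifelse(g, slopes[1] * x, slopes[2] * x) + rnorm(n, 0, noise))
      }
    )
    new_pattern(d$x, d$y, name,
                list(n = n, seed = seed, noise = noise,
                     slopes = if (name == "two_lines") slopes else NULL))
  })
}

#' Simulated categorical relationship patterns
#'
#' Variable pairs involving nominal categories:
#' \describe{
#'   \item{two_cat_indep}{binary `w` (orange/blue) and three-level `z`
#'     (A/B/C), independent and uniform.}
#'   \item{two_cat_assoc}{`z` uniform over A/B/C; blue is over-represented
#'     within `z = A` (`P(blue|A) = p_assoc[1]`), orange within `z = B`
#'     (`P(orange|B) = p_assoc[2]`), and `w` is balanced within `z = C`.}
#'   \item{cat_num_indep}{`z` uniform over A/B/C, numerical `y ~ N(0, 1)`
#'     independent of `z`.}
#'   \item{cat_num_assoc}{`z` uniform over A/B/C; per category
#'     `y ~ N(0, 0.5^2)` for A, `N(1, 0.25^2)` for B, `N(1, 0.75^2)` for C —
#'     clusters of similar `y` match the category clusters of `z`.}
#' }
#'
#' @param name one of `"two_cat_indep"`, `"two_cat_assoc"`, `"cat_num_indep"`,
#'   `"cat_num_assoc"`.
#' @param n number of data points (default 100), at least 9.
#' @param seed integer seed.
#' @param p_assoc length-2 mixing weights for `two_cat_assoc` (defaults
#'   `c(0.8, 0.7)`).
#' @return A `pattern_dataset`; `x` is the categorical `z` (or `w`/`z` pair
#'   encoded as `x = w`, `y = z` for the two-categorical patterns), `y` is
#'   numerical for the cat_num patterns.
#' @examples
#' d <- make_categorical_pattern("cat_num_assoc", n = 100, seed = 1)
#' ccc(d$x, d$y) # around 0.3
#' @export
make_categorical_pattern <- function(name = c("two_cat_indep", "two_cat_assoc",
                                              "cat_num_indep", "cat_num_assoc"),
                                     n = 100, seed = 1, p_assoc = c(0.8, 0.7)) {
  name <- match.arg(name)
  n <- as.integer(n)
  if (n < 9) stop("'n' must be at least 9 (three categories represented)")
  with_seed(seed, {
    z <- sample(c("A", "B", "C"), n, replace = TRUE)
    d <- switch(name,
      two_cat_indep = {
        w <- sample(c("orange", "blue"), n, replace = TRUE)
        list(x = w, y = z)
      },
      two_cat_assoc = {
        p_blue <- ifelse(z == "A", p_assoc[1],
                         ifelse(z == "B", 1 - p_assoc[2], 0.5))
        w <- ifelse(runif(n) < p_blue, "blue", "orange")
        list(x = w, y = z)
      },
      cat_num_indep = {
        list(x = z, y = rnorm(n))
      },
      cat_num_assoc = {
        mu <- ifelse(z == "A", 0, 1)
        sigma <- c(A = 0.5, B = 0.25, C = 0.75)[z]
        list(x = z, y = rnorm(n, mu, sigma))
      }
    )
    new_pattern(d$x, d$y, name, list(n = n, seed = seed, p_assoc = p_assoc))
  })
}

#' Two-cluster substructure patterns
#'
#' Two equal-size spherical Gaussian clusters placed diagonally, horizontally,
#' or vertically. Diagonal placement makes the per-variable partitions match
#' (coefficient near 1, the same partition of samples is recovered from x and
#' from y); horizontal or vertical placement separates the clusters along one
#' variable only, the partitions cannot match, and the coefficient is near 0.
#' A probe for how clustered sample substructure drives the coefficient.
#'
#' @param orientation `"diagonal"`, `"horizontal"` or `"vertical"`.
#' @param n total number of points (default 500), even, at least 4.
#' @param seed integer seed.
#' @param separation distance between cluster centers in units of the cluster
#'   standard deviation (default 5: clearly separated).
#' @param spread cluster standard deviation (default 1).
#' @return A `pattern_dataset` with numeric `x`, `y` and the true cluster
#'   assignment in `params$cluster`.
#' @examples
#' ccc_xy <- function(d) ccc(d$x, d$y)
#' ccc_xy(make_substructure("diagonal", seed = 1))   # near 1
#' ccc_xy(make_substructure("horizontal", seed = 1)) # near 0
#' @export
make_substructure <- function(orientation = c("diagonal", "horizontal",
                                              "vertical"),
                              n = 500, seed = 1, separation = 5, spread = 1) {
  orientation <- match.arg(orientation)
  n <- as.integer(n)
  if (n < 4 || n %% 2 != 0) stop("'n' must be even and at least 4")
  with_seed(seed, {
    cl <- rep(0:1, each = n %/% 2)
    dx <- if (orientation != "vertical") separation * spread else 0
    dy <- if (orientation != "horizontal") separation * spread else 0
    x <- rnorm(n, 0, spread) + cl * dx
    y <- rnorm(n, 0, spread) + cl * dy
    new_pattern(x, y, paste0("substructure_", orientation),
                list(n = n, seed = seed, separation = separation,
                     spread = spread, cluster = cl + 1L))
  })
}

#' Pearson and Spearman reference correlations
#'
#' Textbook product-moment and rank correlations for numerical variable
#' pairs, reported alongside the clustermatch coefficient for comparison.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return List with elements `pearson` and `spearman`.
#' @examples
#' reference_coefficients(1:10, (1:10)^3) # pearson < 1, spearman = 1
#' @export
reference_coefficients <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("reference coefficients are defined for numerical variables only")
  }
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  list(pearson = stats::cor(x, y),
       spearman = stats::cor(x, y, method = "spearman"))
}

#' Export a pattern dataset as TSV
#'
#' Writes the two variables as columns `x`, `y` with a header, for CLI
#' round-trips and external plotting.
#'
#' @param pattern a `pattern_dataset`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pattern_tsv <- function(pattern, path) {
  stopifnot(inherits(pattern, "pattern_dataset"))
  data.table::fwrite(data.table::data.table(x = pattern$x, y = pattern$y),
                     path, sep = "\t")
  invisible(path)
}
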