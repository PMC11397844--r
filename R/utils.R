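#' @importFrom rlang .data :=
#' @importFrom stats median quantile sd var approx fft rnorm runif rbinom
#'   rlnorm predict pf pt wilcox.test t.test aov prcomp complete.cases
#'   binomial plogis glm.fit
#' @importFrom utils head tail
NULL

setNames <- stats::setNames

# Quartiles use type-7 (R default) throughout the catalog.
q1 <- function(x) unname(quantile(x, 0.25, na.rm = TRUE, names = FALSE))
q3 <- function(x) unname(quantile(x, 0.75, na.rm = TRUE, names = FALSE))
iqr_ <- function(x) q3(x) - q1(x)

#' Excess kurtosis (normal -> 0)
#' @param x numeric vector
#' @return scalar
#' @keywords internal
kurtosis_ <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

#' Adjusted Fisher-Pearson skewness
#' @param x numeric vector
#' @return scalar
#' @keywords internal
skewness_ <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x); s <- sd(x)
  if (s <= 0) return(NA_real_)
  (n / ((n - 1) * (n - 2))) * sum(((x - m) / s)^3)
}

# Eight-stat summary used across the motion catalog.
stats8 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(c(mean = NA_real_, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             iqr = NA_real_, sd = NA_real_, kurtosis = NA_real_, skewness = NA_real_))
  }
  c(mean = mean(x), median = median(x), q1 = q1(x), q3 = q3(x),
    iqr = iqr_(x), sd = if (length(x) > 1) sd(x) else 0,
    kurtosis = kurtosis_(x), skewness = skewness_(x))
}

# Total path length of a (possibly multivariate) trajectory: sum of
# Euclidean norms of successive differences. For 1-D input this is the sum
# of absolute successive differences.
path_length <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) return(0)
  d <- diff(x)
  sum(sqrt(rowSums(d^2)))
}

geometric_mean <- function(x, eps = 1e-300) exp(mean(log(pmax(x, eps))))

# Validate-and-recover a nominal sampling rate from a timestamp vector.
sampling_rate <- function(t) {
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  1 / median(dt)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  as.integer(seed %% .Machine$integer.max)
}

# Derive a stream-specific child seed so independent generators do not
# share a random sequence. Kept below 2^31.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
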