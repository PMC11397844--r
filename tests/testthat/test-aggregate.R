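mk_sessions <- function(df) {
  # minimal session-feature tibble with key columns
  dplyr::mutate(df,
                visit_index = dplyr::row_number() - 1L,
                visit_time = (dplyr::row_number() - 1L) * 14,
                .after = "environment")
}

test_that("participant averaging follows the scope and skips missing values", {
  sf <- mk_sessions(tibble::tibble(
    participant_id = c("A", "A", "B", "B"),
    group = c("PD", "PD", "HC", "HC"),
    environment = c("clinic", "home", "clinic", "home"),
    f.x = c(1, 3, 2, NA),
    f.y = c(NA, NA, 5, 7)))
  m <- build_matrix(sf)
  expect_equal(m$f.x[m$participant_id == "A"], 2)
  expect_equal(m$f.x[m$participant_id == "B"], 2)
  expect_equal(m$f.y[m$participant_id == "B"], 6)
  expect_true(is.na(m$f.y[m$participant_id == "A"]))

  m_home <- build_matrix(sf, scope = "home")
  # brute-force filter + mean oracle
  expect_equal(m_home$f.x[m_home$participant_id == "A"],
               mean(sf$f.x[sf$participant_id == "A" & sf$environment == "home"]))
  expect_equal(nrow(m_home), 2)

  # averaging shrinks session-level variance under subject random effects
  set.seed(1)
  subj <- rep(rnorm(20, sd = 2), each = 5)
  sf2 <- mk_sessions(tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:20), each = 5),
    group = rep(c("PD", "HC"), each = 50),
    environment = "home",
    f.z = subj + rnorm(100)))
  m2 <- build_matrix(sf2)
  expect_lt(mean(tapply(sf2$f.z, sf2$participant_id, var)), var(sf2$f.z))
  expect_lt(var(m2$f.z - subj[seq(1, 100, by = 5)]), 1)
})

test_that("selectivity analysis: power, null calibration, F = t^2 identity", {
  set.seed(2)
  n <- 60
  g <- rep(c("PD", "HC"), each = n / 2)
  shifted <- rnorm(n) + 3 * (g == "PD")
  m <- tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g,
                      f.shift = shifted)
  tab <- selectivity_analysis(m)
  expect_lt(tab$p_value[tab$feature == "f.shift"], 0.05)

  # 1000 independent null features: ~5% significant (binomial CI)
  null_m <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g),
    tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * 1000), n)),
                               paste0("f.null", 1:1000))))
  null_tab <- selectivity_analysis(null_m)
  prop <- attr(null_tab, "prop_significant")
  expect_lt(abs(prop - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  # F equals the squared pooled-variance t statistic and matches lm()
  y <- null_m$f.null1
  tt <- t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(tab_f <- null_tab$statistic[null_tab$feature == "f.null1"],
               unname(tt^2), tolerance = 1e-12)
  lm_f <- anova(lm(y ~ g))$`F value`[1]
  expect_equal(tab_f, lm_f, tolerance = 1e-12)
})

test_that("top-F feature selection honours counts, ties and planted signal", {
  set.seed(3)
  n <- 50
  g <- rep(c("PD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 200), n)
  x[, 1:10] <- x[, 1:10] + 2.5 * (g == "PD") # planted signal
  m <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g),
    tibble::as_tibble(setNames(as.data.frame(x), sprintf("f.%03d", 1:200))))
  keep <- select_features(m, n = 100)
  expect_length(keep, 100)
  expect_true(all(sprintf("f.%03d", 1:10) %in% keep))

  small <- m[, 1:52] # 50 features only
  expect_warning(keep_all <- select_features(small, n = 100), "retaining all")
  expect_length(keep_all, 50)
})

test_that("PCA reduction: variance ordering, rank deficiency, eigen oracle, no leakage", {
  set.seed(4)
  base <- matrix(rnorm(40 * 3), 40)
  x <- cbind(base, base %*% matrix(rnorm(3 * 17), 3)) # true rank 3
  x <- x + matrix(rnorm(40 * 20, sd = 1e-8), 40)
  proj <- reduce_features(x, n_components = 10)
  ev <- proj$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
  expect_lt(sum(ev[4:10]), 1e-6)

  # projection matches a direct eigendecomposition of the training
  # covariance of the standardized features
  xs <- scale(x)
  eig <- eigen(stats::cov(xs))
  p1 <- abs(as.numeric(predict(proj, x)[, 1]))
  p2 <- abs(as.numeric(xs %*% eig$vectors[, 1]))
  expect_equal(p1, p2, tolerance = 1e-6)

  # no leakage: training-side parameters identical whatever the test rows
  tr <- matrix(rnorm(30 * 8), 30)
  pr <- reduce_features(tr, n_components = 4)
  pr2 <- reduce_features(tr, n_components = 4)
  expect_identical(pr$rotation, pr2$rotation)
  te1 <- matrix(rnorm(10 * 8), 10)
  expect_equal(predict(pr, te1), predict(pr2, te1))
})

test_that("selection fitted on training rows ignores test labels (leak probe)", {
  set.seed(5)
  n <- 40
  g <- rep(c("PD", "HC"), n / 2)
  m <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g),
    tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * 30), n)),
                               sprintf("f.%02d", 1:30))))
  train <- m[1:32, ]
  keep1 <- select_features(train, n = 10)
  # permute labels outside the training rows: selection must not change
  m2 <- m
  m2$group[33:40] <- sample(m2$group[33:40])
  keep2 <- select_features(m2[1:32, ], n = 10)
  expect_identical(keep1, keep2)
})
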