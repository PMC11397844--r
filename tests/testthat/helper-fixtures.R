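# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small mixed cohort with a lightweight battery, used by aggregation,
# reliability and modeling tests.
small_cohort_features <- function() {
  fixture("small_cohort_features", function() {
    bat <- c("tremor", "finger_tapping", "vstm", "sdmt")
    spec <- cohort_spec(n_pd = 8, n_hc = 8, n_clinic_visits = 1,
                        n_home_visits = 2, battery = bat,
                        tremor_duration = 6, effect_scale = 1, seed = 101)
    coh <- generate_cohort(spec)
    extract_cohort(coh$sessions, battery = bat)
  })
}

# One complete full-battery synthetic session (all nine assessments at
# study-default signal scales).
full_session <- function() {
  fixture("full_session", function() {
    spec <- cohort_spec(n_pd = 1, n_hc = 1, n_clinic_visits = 1,
                        n_home_visits = 0, seed = 7)
    generate_cohort(spec)$sessions[[1]]
  })
}

# Brute-force 3-D convex hull surface area by facet enumeration: for every
# point triple, if all remaining points lie on one side of its plane the
# triangle is a hull facet.
brute_hull_area_3d <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  area <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- c(
      (p[j, 2] - p[i, 2]) * (p[k, 3] - p[i, 3]) -
        (p[j, 3] - p[i, 3]) * (p[k, 2] - p[i, 2]),
      (p[j, 3] - p[i, 3]) * (p[k, 1] - p[i, 1]) -
        (p[j, 1] - p[i, 1]) * (p[k, 3] - p[i, 3]),
      (p[j, 1] - p[i, 1]) * (p[k, 2] - p[i, 2]) -
        (p[j, 2] - p[i, 2]) * (p[k, 1] - p[i, 1]))
    if (sum(nrm^2) < 1e-20) next
    d <- p %*% nrm - sum(nrm * p[i, ])
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      area <- area + sqrt(sum(nrm^2)) / 2
    }
  }
  area
}
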