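test_that("despike removes an isolated spike and passes endpoints through", {
  expect_equal(despike(c(5, 50, 5)), c(5, 5, 5))
  mono <- c(1, 2, 3, 5, 8, 13)
  expect_equal(despike(mono), mono)
  expect_error(despike(c(1, 2)), "at least 3")
})

test_that("despike matches a brute-force sliding-median oracle", {
  set.seed(21)
  for (rep in 1:10) {
    x <- exp(rnorm(50))
    oracle <- x
    for (i in 2:49) oracle[i] <- sort(x[(i - 1):(i + 1)])[2]
    expect_equal(despike(x), oracle)
  }
})

test_that("despike is idempotent on isolated spikes over smooth profiles", {
  z <- seq_len(60)
  x <- 4e-4 * exp(-z / 30) + 2e-4
  x[c(7, 20, 41)] <- x[c(7, 20, 41)] * 10
  once <- despike(x)
  expect_equal(despike(once), once)
  expect_equal(once[c(7, 20, 41)], (4e-4 * exp(-c(7, 20, 41) / 30) + 2e-4),
               tolerance = 0.05)
})

fake_profiles <- function(deep_means, nz = 40) {
  z <- seq(50, 750, length.out = nz)
  do.call(rbind, lapply(seq_along(deep_means), function(i) {
    shape <- 1e-4 * exp(-z / 300)
    v <- shape + deep_means[i] - mean(shape[z >= 700 & z <= 750])
    data.frame(float_id = sprintf("F%d", i), time = "2020-06-01",
               lat = -30, lon = -120, depth_m = z, bbp700_m.1 = v)
  }))
}

test_that("deep alignment shifts profiles to the fleet median deep mean", {
  d <- fake_profiles(c(2e-4, 4e-4))
  a <- deep_align(d)
  dm <- vapply(split(a, a$float_id), function(p)
    mean(p$bbp700_m.1[p$depth_m >= 700 & p$depth_m <= 750]), 1.0)
  expect_equal(unname(dm), c(3e-4, 3e-4), tolerance = 1e-12)
  expect_equal(sort(unique(round(a$align_shift, 10))), c(-1e-4, 1e-4))
})

test_that("a single profile is unchanged by alignment", {
  d <- fake_profiles(2.5e-4)
  a <- deep_align(d)
  expect_equal(a$bbp700_m.1, d$bbp700_m.1, tolerance = 1e-15)
})

test_that("alignment preserves within-profile differences exactly", {
  d <- fake_profiles(c(1e-4, 3e-4, 8e-4))
  a <- deep_align(d)
  for (f in unique(d$float_id)) {
    expect_lt(max(abs(diff(a$bbp700_m.1[a$float_id == f]) -
                        diff(d$bbp700_m.1[d$float_id == f]))), 1e-18)
  }
})

test_that("profiles without deep samples are excluded and counted", {
  d <- fake_profiles(c(2e-4, 4e-4))
  shallow <- data.frame(float_id = "F9", time = "2020-06-01", lat = -30,
                        lon = -120, depth_m = seq(5, 200, 5),
                        bbp700_m.1 = 5e-4)
  a <- deep_align(rbind(d, shallow))
  expect_false("F9" %in% a$float_id)
  expect_equal(attr(a, "n_excluded"), 1L)
})

test_that("percentile trim drops 10% of a bin of distinct values, none of ties", {
  set.seed(5)
  z <- c(6, 10, 15)   # three surface depths
  d <- do.call(rbind, lapply(1:100, function(i)
    data.frame(float_id = sprintf("F%03d", i), time = "2021-03-02",
               lat = -30, lon = -120, depth_m = z,
               bbp700_m.1 = rep(i * 1e-5, 3))))
  w <- surface_weekly(d)
  expect_equal(w$n, 90)
  d$bbp700_m.1 <- 4e-4
  w2 <- surface_weekly(d)
  expect_equal(w2$n, 100)
  expect_equal(w2$value, 4e-4)
})

test_that("profiles with fewer than two surface samples are skipped", {
  z <- c(10, 100, 200)
  d <- data.frame(float_id = "F1", time = "2021-03-02", lat = -30,
                  lon = -120, depth_m = z, bbp700_m.1 = 1e-4)
  expect_equal(nrow(surface_weekly(d)), 0)
})

test_that("despiking suppresses injected spikes to the noise level", {
  # at interior spike positions the filter substitutes a neighbor value,
  # so the residual is a noise-scale difference: RMS below 2 noise SD and
  # a large reduction of the raw spike error
  stats <- vapply(1:20, function(s) {
    p <- argo_set_params(n_floats = 2, profiles_per_float = 3,
                         spike_rate = 0.02, spike_magnitude = 10,
                         float_offset_sd = 0, noise_cv = 0.05, seed = s)
    d <- gen_argo_profiles(p)
    key <- interaction(d$float_id, d$time, drop = TRUE)
    res <- raw <- c()
    for (ii in split(seq_len(nrow(d)), key)) {
      v <- despike(d$bbp700_m.1[ii])
      tr <- d$true_bbp700[ii]; sp <- which(d$is_spike[ii])
      sp <- sp[sp > 1 & sp < length(v)]
      if (!length(sp)) next
      res <- c(res, v[sp] - tr[sp])
      raw <- c(raw, d$bbp700_m.1[ii][sp] - tr[sp])
    }
    noise_sd <- p$noise_cv * p$surface_bbp
    c(rms = sqrt(mean(res^2)) / noise_sd,
      reduction = sqrt(mean(raw^2)) / sqrt(mean(res^2)))
  }, c(rms = 1.0, reduction = 1.0))
  expect_lt(median(stats["rms", ]), 2)
  expect_gt(median(stats["reduction", ]), 20)
})

test_that("deep alignment shrinks between-float offsets at least 5-fold", {
  shrink <- vapply(1:10, function(s) {
    p <- argo_set_params(n_floats = 8, profiles_per_float = 4,
                         spike_rate = 0, float_offset_sd = 1e-4,
                         noise_cv = 0.02, seed = s)
    d <- gen_argo_profiles(p)
    deep <- function(dd) vapply(split(dd, dd$float_id), function(pp)
      mean(pp$bbp700_m.1[pp$depth_m >= 700 & pp$depth_m <= 750]), 1.0)
    a <- deep_align(d)
    sd(deep(d)) / sd(deep(a))
  }, 1.0)
  expect_true(all(shrink >= 5))
})

test_that("a constructed year-level shift separates that year in the overlay", {
  p <- argo_set_params(n_floats = 6, profiles_per_float = 30,
                       years = c(2018, 2022), spike_rate = 0,
                       float_offset_sd = 0, noise_cv = 0.03, seed = 12)
  d <- gen_argo_profiles(p)
  shift <- 2e-4
  k <- format(as.Date(d$time), "%Y") == "2021" & d$depth_m <= 30
  d$bbp700_m.1[k] <- d$bbp700_m.1[k] + shift
  qc <- argo_qc_chain(d)
  w <- qc$weekly
  m2021 <- mean(w$value[w$year == 2021])
  mrest <- mean(w$value[w$year != 2021])
  expect_equal(m2021 - mrest, shift, tolerance = 0.3)
})
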