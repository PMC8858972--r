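test_that("TIC normalization scales to unit total and is idempotent", {
  s <- spot_spectrum(c(100, 200, 300), c(2, 3, 5))
  n1 <- tic_normalize(s)
  expect_equal(n1$intensity, c(0.2, 0.3, 0.5))
  expect_equal(tic_normalize(n1)$intensity, n1$intensity)
  expect_equal(n1$mz, s$mz)
  expect_error(tic_normalize(spot_spectrum(1:3, c(0, 0, 0))),
               "empty spectrum")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spot_spectrum(c(1, 1, 2), c(1, 1, 1)), "strictly increasing")
  expect_error(spot_spectrum(c(2, 1), c(1, 1)), "strictly increasing")
  expect_error(spot_spectrum(c(1, 2), c(1, -1)), "negative")
})

test_that("windowed peak area recovers a discretized Gaussian", {
  mz0 <- 1500
  sigma <- 0.003
  d <- 2e-4
  grid <- seq(mz0 - 6 * sigma, mz0 + 6 * sigma, by = d)
  area_true <- 2.5
  s <- spot_spectrum(grid, area_true * d * dnorm(grid, mz0, sigma))
  # window of +/- 4 sigma: tol_ppm such that mz0*tol >= 4*sigma
  tol_ppm <- 4 * sigma / mz0 * 1e6
  got <- extract_peak_area(s, mz0, tol_ppm)
  expect_equal(got, area_true, tolerance = 0.01)
})

test_that("peak area is local: empty windows give 0, outside points ignored", {
  s <- spot_spectrum(c(1000, 1500, 2000), c(1, 2, 3))
  expect_equal(extract_peak_area(s, 1200, 10), 0)
  s2 <- spot_spectrum(c(1000, 1500, 2000), c(9, 2, 7))
  expect_equal(extract_peak_area(s, 1500, 10), extract_peak_area(s2, 1500, 10))
})

test_that("spot quantification averages TIC-normalized pixel areas", {
  panel <- test_panel()
  mk <- function(ints) spot_spectrum(panel$theoretical_mz, ints,
                                     spot_id = "sp", channel = "IgG1")
  one <- quantify_spot(list(mk(c(2, 3, 5, 0, 0))), panel)
  expect_equal(unname(one), c(0.2, 0.3, 0.5, 0, 0))
  # mean of two pixels; second pixel scaled x10 must not dominate (TIC first)
  two <- quantify_spot(list(mk(c(2, 3, 5, 0, 0)), mk(10 * c(5, 3, 2, 0, 0))),
                       panel)
  expect_equal(unname(two), c(0.35, 0.3, 0.35, 0, 0))
  expect_error(quantify_spot(list(), panel), "empty pixel list")
  bad <- list(mk(c(1, 1, 1, 1, 1)),
              spot_spectrum(panel$theoretical_mz, rep(1, 5), spot_id = "other",
                            channel = "IgG1"))
  expect_error(quantify_spot(bad, panel), "multiple spots")
})

test_that("overlapping panel windows are reported by name", {
  p <- glycan_panel(c("G1.A2G0F", "G1.A2G1F"))
  # at a huge tolerance the two windows overlap
  s <- list(spot_spectrum(p$theoretical_mz, c(1, 1), "sp", "IgG1"))
  expect_warning(quantify_spot(s, p, tol_ppm = 1e5), "windows overlap")
})

test_that("relative percentiles close to 100 and handle degenerate input", {
  expect_equal(relative_percentile(c(2, 2, 4)), c(25, 25, 50))
  expect_equal(relative_percentile(7), 100)
  expect_warning(z <- relative_percentile(c(0, 0, 0)), "no signal")
  expect_equal(z, c(0, 0, 0))
  expect_error(relative_percentile(c(1, -1)), "negative")
})

test_that("quantification is invariant to uniform pixel rescaling", {
  panel <- test_panel()
  px <- generate_spot_spectra(test_profile(), panel, pixels = 5, snr = 30,
                              seed = 4, channel = "IgG1")
  scaled <- lapply(px, function(s) { s$intensity <- s$intensity * 37; s })
  expect_equal(quantify_spot(px, panel), quantify_spot(scaled, panel))
})

test_that("cohort assembly joins channels, labels and percentiles", {
  panel <- glycan_panel(c("G.A2G0F", "G.A2G1F", "G1.A2G0F", "G1.A2G1F"))
  mkpx <- function(ch, ints) {
    sub <- panel[panel$channel == ch, ]
    class(sub) <- c("glycan_panel", "data.frame")
    list(spot_spectrum(sub$theoretical_mz, ints, "sp", ch))
  }
  samples <- list(
    A = list(group = "group1", stage = "0",
             spots = list(G = mkpx("IgG", c(1, 3)), G1 = mkpx("IgG1", c(1, 1)))),
    B = list(group = "group3", stage = "4",
             spots = list(G = mkpx("IgG", c(2, 2)))))
  expect_message(tab <- build_cohort_table(samples, panel), "no spots")
  expect_s3_class(tab, "cohort_table")
  expect_equal(tab[tab$sample_id == "A", "G.A2G0F"], 25)
  expect_equal(tab[tab$sample_id == "A", "G1.A2G1F"], 50)
  expect_true(is.na(tab[tab$sample_id == "B", "G1.A2G0F"]))
  expect_error(build_cohort_table(stats::setNames(samples, c("A", "A")), panel),
               "unique sample IDs")
})

test_that("cohort and spot-dialect files round-trip", {
  sim <- generate_cohort(synthetic_config(glycans = 4, planted = NULL,
                                          decoys = NULL,
                                          group_sizes = c(3, 3, 3)),
                         seed = 2)
  tmp <- tempfile(fileext = ".tsv")
  write_cohort_table(sim$cohort, tmp)
  back <- read_cohort_table(tmp)
  expect_equal(cohort_features(back), cohort_features(sim$cohort))
  expect_equal(as.data.frame(back), as.data.frame(sim$cohort),
               tolerance = 1e-9)

  panel <- test_panel()
  px <- generate_spot_spectra(test_profile(), panel, pixels = 3, snr = 20,
                              seed = 9, spot_id = "w3", channel = "IgG1")
  f <- tempfile(fileext = ".tsv")
  write_spot_tsv(px, f)
  px2 <- read_spot_tsv(f)
  expect_equal(length(px2), 3)
  expect_equal(px2[[1]]$spot_id, "w3")
  expect_equal(px2[[1]]$channel, "IgG1")
  expect_equal(px2[[1]]$mz, px[[1]]$mz, tolerance = 1e-9)
})
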