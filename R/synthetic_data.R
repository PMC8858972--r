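# Baseline log-abundances of the default 11-glycan IgG panel. Chosen so the
# closed (percentile) profile resembles a typical serum IgG Fc profile:
# dominated by core-fucosylated bi-antennary glycans with 0-2 galactoses,
# minor bisected and sialylated species.
DEFAULT_BASELINE <- c(
  A2G0F = 2.6, A2G1F = 2.9, A2G2F = 2.2,
  A2G0 = 1.0, A2G1 = 1.2, A2G2 = 0.8,
  A2G2S1 = 1.6, A2G2S1F = 1.1,
  A2BG0F = 1.4, A2BG1F = 1.6, A2BG2F = 0.8
)

# The seven-feature fibrosis panel planted by default, with its timing class
# (which group transition shifts the feature) and the per-transition shift on
# the log-abundance scale. Directions: agalactosylated/bisected species rise
# with fibrosis, galactosylated species fall.
DEFAULT_PLANTED <- data.frame(
  feature = c("G.A2G2F", "G.A2BG0F", "G1.A2G1F", "G1.A2G2S1",
              "G2.A2G1F", "G2.A2G0F", "G3.A2BG1F"),
  timing  = c("both", "both", "early", "late", "early", "early", "late"),
  effect  = c(-0.8, 0.8, -0.8, 0.8, -0.8, 0.8, -0.8),
  stringsAsFactors = FALSE
)

# Decoy twins: near-duplicates of a planted feature (attenuated copy of its
# log-abundance plus extra noise) that exercise the Hoeffding-D
# pair-elimination path. The decoy replaces the named feature's independent
# draw.
DEFAULT_DECOYS <- data.frame(
  feature = c("G.A2BG2F", "G1.A2G1"),
  of      = c("G.A2BG0F", "G1.A2G1F"),
  attenuation = 0.7,
  noise_sd = 0.25,
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic cohort generator
#'
#' Defines a three-group cohort of compositional glycan profiles over five
#' antibody-capture channels, with designated features shifted between
#' groups on the log-abundance scale.
#'
#' @param group_sizes Samples per fibrosis group (no fibrosis, early to
#'   moderate, advanced/cirrhosis).
#' @param channels Channel prefixes to simulate.
#' @param glycans Character vector of Oxford names per channel, or an
#'   integer taken from [oxford_name_pool()]. Default: the 11-glycan IgG
#'   panel named in `DEFAULT_BASELINE`.
#' @param baseline Named log-abundance baseline; names must cover `glycans`.
#'   Glycans without a named baseline get the median baseline.
#' @param planted Data frame `feature, timing, effect` (timing one of
#'   `early`, `late`, `both`; effect = log shift per transition), or `NULL`
#'   for a global-null cohort.
#' @param decoys Data frame `feature, of, attenuation, noise_sd` of decoy
#'   twins, or `NULL` for none.
#' @param noise_sd Intra-sample log-abundance noise SD.
#' @param pixels,snr Defaults used when generating spot spectra.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(group_sizes = c(41, 28, 43),
                             channels = c("G", "G1", "G2", "G3", "G4"),
                             glycans = names(DEFAULT_BASELINE),
                             baseline = DEFAULT_BASELINE,
                             planted = DEFAULT_PLANTED,
                             decoys = DEFAULT_DECOYS,
                             noise_sd = 0.5,
                             pixels = 50, snr = 50) {
  if (is.numeric(glycans) && length(glycans) == 1L)
    glycans <- oxford_name_pool(glycans)
  stopifnot(length(group_sizes) == 3L, all(group_sizes >= 2L),
            all(channels %in% names(CHANNELS)), noise_sd > 0)
  for (g in glycans) parse_oxford(g)
  base <- baseline[glycans]
  names(base) <- glycans
  base[is.na(base)] <- stats::median(baseline)
  if (any(!is.finite(base)))
    stop("baseline log-abundances must be finite", call. = FALSE)
  features <- as.vector(t(outer(channels, glycans, paste, sep = ".")))
  if (!is.null(planted)) {
    stopifnot(all(c("feature", "timing", "effect") %in% names(planted)),
              all(planted$timing %in% c("early", "late", "both")))
    missing <- setdiff(planted$feature, features)
    if (length(missing))
      stop("planted features not in simulated panel: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(decoys)) {
    stopifnot(all(c("feature", "of") %in% names(decoys)))
    if (is.null(decoys$attenuation)) decoys$attenuation <- 0.7
    if (is.null(decoys$noise_sd)) decoys$noise_sd <- 0.25
    stopifnot(all(decoys$feature %in% features), all(decoys$of %in% features),
              !any(decoys$feature %in% if (is.null(planted)) character(0)
                                       else planted$feature))
  }
  structure(list(group_sizes = group_sizes, channels = channels,
                 glycans = glycans, baseline = base, planted = planted,
                 decoys = decoys, noise_sd = noise_sd,
                 pixels = pixels, snr = snr),
            class = "synthetic_config")
}

# per-group multiplier of the per-transition effect
timing_shift <- function(timing) {
  switch(timing,
         early = c(0, 1, 1),   # changes at group1 -> group2, then stable
         late  = c(0, 0, 1),   # changes only at group2 -> group3
         both  = c(0, 1, 2))   # changes at both transitions
}

# METAVIR stage composition within each group, proportioned as in the study
# cohort (healthy 38 / stage0 3; stage1 10 / stage2 18; stage3 6 / stage4 37)
stage_labels <- function(group_sizes) {
  mix <- list(c(healthy = 38, `0` = 3), c(`1` = 10, `2` = 18),
              c(`3` = 6, `4` = 37))
  unlist(lapply(1:3, function(g) {
    n <- group_sizes[g]; w <- mix[[g]]
    k <- round(n * w[1] / sum(w))
    rep(names(w), times = c(k, n - k))
  }), use.names = FALSE)
}

#' Generate a synthetic glycan cohort
#'
#' Draws logistic-normal compositional profiles per sample and channel:
#' log-abundance = baseline + group shift (planted features only) + Gaussian
#' noise, closed to percentiles summing to 100 within each channel. Decoy
#' twins are attenuated copies of their partner's log-abundance plus extra
#' noise. Deterministic given `seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `cohort` (a `cohort_table`) and `truth` (planted
#'   features, per-group expected mean percentiles, decoys, seed).
#' @export
generate_cohort <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_(seed, {
    n <- sum(cfg$group_sizes)
    group <- rep(paste0("group", 1:3), times = cfg$group_sizes)
    stage <- stage_labels(cfg$group_sizes)
    ids <- sprintf("S%03d", seq_len(n))
    ng <- length(cfg$glycans)
    gi <- rep(1:3, times = cfg$group_sizes)

    feat_cols <- list()
    for (ch in cfg$channels) {
      feats <- paste(ch, cfg$glycans, sep = ".")
      shift <- matrix(0, nrow = 3, ncol = ng, dimnames = list(NULL, feats))
      if (!is.null(cfg$planted)) {
        here <- cfg$planted[cfg$planted$feature %in% feats, , drop = FALSE]
        for (k in seq_len(nrow(here)))
          shift[, here$feature[k]] <-
            timing_shift(here$timing[k]) * here$effect[k]
      }
      loga <- matrix(rep(cfg$baseline, each = n), nrow = n) +
        shift[gi, , drop = FALSE] +
        matrix(stats::rnorm(n * ng, sd = cfg$noise_sd), nrow = n)
      colnames(loga) <- feats
      if (!is.null(cfg$decoys)) {
        here <- cfg$decoys[cfg$decoys$feature %in% feats, , drop = FALSE]
        for (k in seq_len(nrow(here))) {
          d <- here$feature[k]; p <- here$of[k]
          pg <- sub("^[^.]+\\.", "", p)
          dg <- sub("^[^.]+\\.", "", d)
          partner_dev <- loga[, p] - cfg$baseline[pg]
          loga[, d] <- cfg$baseline[dg] +
            here$attenuation[k] * partner_dev +
            stats::rnorm(n, sd = here$noise_sd[k])
        }
      }
      a <- exp(loga)
      feat_cols[[ch]] <- 100 * a / rowSums(a)
    }
    X <- do.call(cbind, feat_cols)
    cohort <- as_cohort_table(data.frame(
      sample_id = ids, group = group, stage = stage,
      X, check.names = FALSE, stringsAsFactors = FALSE))

    truth <- list(seed = seed, group_sizes = cfg$group_sizes,
                  planted = cfg$planted, decoys = cfg$decoys,
                  noise_sd = cfg$noise_sd,
                  expected = expected_percentiles(cfg))
    list(cohort = cohort, truth = truth)
  })
}

# Expected per-group mean percentile of each feature, from the closure of
# exp(baseline + shift). Lognormal noise contributes a common exp(sd^2/2)
# factor that cancels in the closure (decoy noise differs slightly; the
# expectation is therefore approximate for decoys).
expected_percentiles <- function(cfg) {
  out <- list()
  for (ch in cfg$channels) {
    feats <- paste(ch, cfg$glycans, sep = ".")
    m <- matrix(rep(cfg$baseline, each = 3), nrow = 3,
                dimnames = list(paste0("group", 1:3), feats))
    if (!is.null(cfg$planted)) {
      here <- cfg$planted[cfg$planted$feature %in% feats, , drop = FALSE]
      for (k in seq_len(nrow(here)))
        m[, here$feature[k]] <- m[, here$feature[k]] +
          timing_shift(here$timing[k]) * here$effect[k]
    }
    a <- exp(m)
    out[[ch]] <- 100 * a / rowSums(a)
  }
  do.call(cbind, out)
}

#' Generate synthetic spot spectra for one channel profile
#'
#' Produces centroided pixel spectra whose panel-glycan peak heights are
#' proportional to the given profile times a lognormal per-pixel brightness
#' factor, with multiplicative height noise of relative scale `1/snr`,
#' small mass jitter, and a uniform baseline of low-intensity noise
#' centroids. With `snr = Inf` the single-pixel spectrum reproduces the
#' profile exactly after quantification.
#'
#' @param profile Named nonnegative vector (one entry per panel label);
#'   any scale, only proportions matter.
#' @param panel A `glycan_panel` matching `names(profile)`.
#' @param pixels Number of pixel spectra.
#' @param snr Signal-to-noise ratio; `Inf` disables all noise.
#' @param seed Integer seed (`NULL` leaves the RNG stream alone).
#' @param spot_id,channel Metadata for the spectra.
#' @param mz_jitter_ppm SD of centroid mass error in ppm.
#' @param baseline_points Noise centroids per pixel (0 when `snr = Inf`).
#' @param mz_range m/z range of baseline noise.
#' @param pixel_sd SD of the lognormal per-pixel brightness factor.
#' @return List of `spot_spectrum`.
#' @export
generate_spot_spectra <- function(profile, panel, pixels = 50, snr = 50,
                                  seed = NULL, spot_id = "spot1",
                                  channel = NA_character_,
                                  mz_jitter_ppm = 1, baseline_points = 200,
                                  mz_range = c(800, 3000), pixel_sd = 0.2) {
  stopifnot(inherits(panel, "glycan_panel"), pixels >= 1L, snr > 0,
            length(profile) == nrow(panel), all(profile >= 0))
  if (!is.null(names(profile)))
    stopifnot(identical(names(profile), panel$label))
  with_seed_(seed, {
    ng <- nrow(panel)
    noiseless <- !is.finite(snr)
    lapply(seq_len(pixels), function(px) {
      fac <- if (noiseless) 1 else stats::rlnorm(1, 0, pixel_sd)
      hnoise <- if (noiseless) 0 else stats::rnorm(ng) / snr
      heights <- pmax(profile * fac * (1 + hnoise), 0)
      jitter <- if (noiseless) 0 else
        stats::rnorm(ng, sd = mz_jitter_ppm * 1e-6) * panel$theoretical_mz
      mz <- panel$theoretical_mz + jitter
      if (!noiseless && baseline_points > 0) {
        bmz <- stats::runif(baseline_points, mz_range[1], mz_range[2])
        bint <- abs(stats::rnorm(baseline_points)) * mean(heights) / snr
        mz <- c(mz, bmz); heights <- c(heights, bint)
      }
      o <- order(mz)
      mz <- mz[o]; heights <- heights[o]
      dup <- duplicated(mz)
      if (any(dup)) { heights <- tapply(heights, mz, sum); mz <- unique(mz) }
      spot_spectrum(mz, heights, spot_id = spot_id, channel = channel)
    })
  })
}

#' Write a synthetic truth record as JSON
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# evaluate code with a temporarily seeded RNG, restoring the caller's stream
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
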