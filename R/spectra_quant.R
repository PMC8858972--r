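#' Construct a spot spectrum
#'
#' One pixel's centroided spectrum, tagged with the spot (region) it was
#' acquired from and the capture channel of that spot.
#'
#' @param mz Strictly increasing numeric vector of m/z values.
#' @param intensity Nonnegative numeric vector, same length as `mz`.
#' @param spot_id Region label.
#' @param channel Capture antibody channel of the spot (e.g. `"IgG1"`).
#' @return An object of class `spot_spectrum`.
#' @export
spot_spectrum <- function(mz, intensity, spot_id = NA_character_,
                          channel = NA_character_) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (is.unsorted(mz, strictly = TRUE))
    stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 spot_id = spot_id, channel = channel),
            class = "spot_spectrum")
}

#' @export
print.spot_spectrum <- function(x, ...) {
  cat(sprintf("<spot_spectrum> spot=%s channel=%s, %d centroids, m/z %.2f-%.2f\n",
              x$spot_id, x$channel, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Total-ion-current normalization
#'
#' Scales a pixel spectrum so its summed intensity equals 1, removing
#' pixel-to-pixel variation in total signal. Idempotent.
#'
#' @param spec A `spot_spectrum`.
#' @return The spectrum with intensities summing to 1.
#' @export
tic_normalize <- function(spec) {
  stopifnot(inherits(spec, "spot_spectrum"))
  tic <- sum(spec$intensity)
  if (tic <= 0) stop("empty spectrum: total ion current is zero", call. = FALSE)
  spec$intensity <- spec$intensity / tic
  spec
}

#' Peak area within a ppm window around a theoretical m/z
#'
#' Sums centroid intensities falling in `mz0 * (1 +/- tol_ppm * 1e-6)`.
#' An empty window yields 0 (the glycan is simply absent from this pixel).
#'
#' @param spec A `spot_spectrum`.
#' @param mz0 Theoretical m/z of the monoisotopic peak.
#' @param tol_ppm Half-width of the window in parts per million.
#' @return Summed intensity (0 if no centroid falls in the window).
#' @export
extract_peak_area <- function(spec, mz0, tol_ppm = 10) {
  stopifnot(inherits(spec, "spot_spectrum"), tol_ppm > 0, mz0 > 0)
  tol <- tol_ppm * 1e-6
  lo <- mz0 * (1 - tol); hi <- mz0 * (1 + tol)
  inside <- spec$mz >= lo & spec$mz <= hi
  sum(spec$intensity[inside])
}

panel_windows <- function(panel, tol_ppm) {
  tol <- tol_ppm * 1e-6
  data.frame(label = panel$label,
             lo = panel$theoretical_mz * (1 - tol),
             hi = panel$theoretical_mz * (1 + tol))
}

warn_window_collisions <- function(panel, tol_ppm) {
  w <- panel_windows(panel, tol_ppm)
  if (nrow(w) < 2L) return(invisible(NULL))
  o <- order(w$lo)
  w <- w[o, ]
  overlap <- which(w$lo[-1] <= w$hi[-nrow(w)])
  for (k in overlap)
    warning(sprintf(
      "extraction windows overlap at %g ppm: '%s' and '%s' share m/z points",
      tol_ppm, w$label[k], w$label[k + 1]), call. = FALSE)
  invisible(NULL)
}

#' Quantify one spot against a glycan panel
#'
#' Each pixel is TIC-normalized, panel peak areas are extracted per pixel,
#' and the per-glycan areas are averaged over the spot's pixels (mean peak
#' intensity). If two panel windows overlap at the given tolerance both
#' receive the shared points and a warning names the collision.
#'
#' @param pixels List of `spot_spectrum` objects, all from the same spot.
#' @param panel A `glycan_panel` restricted to this spot's channel.
#' @param tol_ppm Extraction half-window in ppm.
#' @return Named numeric vector of mean peak areas, one per panel entry.
#' @export
quantify_spot <- function(pixels, panel, tol_ppm = 10) {
  if (length(pixels) == 0L) stop("empty pixel list", call. = FALSE)
  stopifnot(all(vapply(pixels, inherits, logical(1), "spot_spectrum")),
            inherits(panel, "glycan_panel"))
  sid <- unique(vapply(pixels, `[[`, character(1), "spot_id"))
  ch  <- unique(vapply(pixels, `[[`, character(1), "channel"))
  if (length(sid) > 1L) stop("pixels span multiple spots: ",
                             paste(sid, collapse = ", "), call. = FALSE)
  if (length(ch) > 1L) stop("pixels span multiple channels", call. = FALSE)
  warn_window_collisions(panel, tol_ppm)
  areas <- vapply(pixels, function(px) {
    px <- tic_normalize(px)
    vapply(panel$theoretical_mz, function(mz0)
      extract_peak_area(px, mz0, tol_ppm), numeric(1))
  }, numeric(nrow(panel)))
  areas <- matrix(areas, nrow = nrow(panel))
  out <- rowMeans(areas)
  names(out) <- panel$label
  out
}

#' Relative percentile of a raw glycan vector
#'
#' Expresses each glycan as a percentage of the summed panel signal within
#' its capture channel (the "relative percentile of the total glycan
#' profile"). An all-zero vector is returned unchanged with a warning.
#'
#' @param raw Nonnegative named vector of raw areas.
#' @return Vector of the same length summing to 100 (or all zero).
#' @export
relative_percentile <- function(raw) {
  stopifnot(is.numeric(raw))
  if (any(raw < 0)) stop("negative peak area", call. = FALSE)
  tot <- sum(raw)
  if (tot == 0) {
    warning("no signal in any panel window; returning zeros", call. = FALSE)
    return(raw)
  }
  raw * 100 / tot
}

#' Assemble a cohort table from per-sample spot sets
#'
#' For each sample and capture channel, the channel's spot pixels are
#' quantified against the channel's panel entries and converted to relative
#' percentiles; channels are concatenated into one row per sample. Channels
#' a sample lacks produce `NA` features with a message.
#'
#' @param samples Named list (names = sample IDs). Each element is a list
#'   with `group` (group label), optional `stage` (METAVIR stage) and
#'   `spots`, itself a named list mapping channel prefix (`"G"`, `"G1"`, ...)
#'   to a list of `spot_spectrum` pixels.
#' @param panel A `glycan_panel` with channel-prefixed labels.
#' @param tol_ppm Extraction half-window in ppm.
#' @return A `cohort_table`: data frame with `sample_id`, `group`, `stage`
#'   and one column per panel label holding relative percentiles.
#' @export
build_cohort_table <- function(samples, panel, tol_ppm = 10) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            inherits(panel, "glycan_panel"))
  ids <- names(samples)
  if (is.null(ids) || anyDuplicated(ids))
    stop("samples must be a named list with unique sample IDs", call. = FALSE)
  if (anyNA(panel$channel))
    stop("cohort panel requires channel-prefixed labels", call. = FALSE)
  prefixes <- names(CHANNELS)[match(panel$channel, CHANNELS)]
  rows <- lapply(ids, function(id) {
    s <- samples[[id]]
    feat <- rep(NA_real_, nrow(panel))
    names(feat) <- panel$label
    for (pre in unique(prefixes)) {
      sel <- prefixes == pre
      sub <- panel[sel, , drop = FALSE]
      class(sub) <- c("glycan_panel", "data.frame")
      if (is.null(s$spots[[pre]])) {
        message(sprintf("sample '%s': no spots for channel %s; features set NA",
                        id, CHANNELS[[pre]]))
        next
      }
      raw <- quantify_spot(s$spots[[pre]], sub, tol_ppm)
      feat[sel] <- relative_percentile(raw)
    }
    c(list(sample_id = id, group = s$group,
           stage = if (is.null(s$stage)) NA_character_ else s$stage),
      as.list(feat))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  as_cohort_table(out)
}

as_cohort_table <- function(df) {
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs", call. = FALSE)
  meta <- c("sample_id", "group", "stage")
  df <- df[, c(meta, setdiff(names(df), meta)), drop = FALSE]
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Feature columns of a cohort table
#' @param cohort A `cohort_table`.
#' @return Character vector of feature column names.
#' @export
cohort_features <- function(cohort) {
  setdiff(names(cohort), c("sample_id", "group", "stage"))
}

#' Feature matrix of a cohort table
#' @param cohort A `cohort_table`.
#' @param features Optional subset of feature names.
#' @return Numeric matrix, samples in rows.
#' @export
cohort_matrix <- function(cohort, features = NULL) {
  if (is.null(features)) features <- cohort_features(cohort)
  missing <- setdiff(features, names(cohort))
  if (length(missing))
    stop("features absent from cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(cohort[, features, drop = FALSE])
  rownames(m) <- cohort$sample_id
  m
}

#' Read / write a cohort table TSV
#'
#' Columns: `sample_id, group, stage, <prefix>.<glycan>...`. Feature column
#' names are validated against the Oxford parser on read.
#'
#' @param path File path.
#' @return `read_cohort_table` returns a `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- as_cohort_table(df)
  for (f in cohort_features(out)) parse_channel_feature(f)
  out
}

#' @rdname read_cohort_table
#' @param cohort A `cohort_table`.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spot spectrum from the simple tabular dialect
#'
#' One TSV per spot pixel set: columns `pixel, mz, intensity`; the spot ID
#' and channel are given in a header comment line
#' `# spot_id=<id> channel=<channel>` or passed explicitly.
#'
#' @param path File path.
#' @param spot_id,channel Override the header metadata.
#' @return List of `spot_spectrum`, one per pixel.
#' @export
read_spot_tsv <- function(path, spot_id = NULL, channel = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=\\S+", first))[[1]]
    meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    if (is.null(spot_id) && "spot_id" %in% names(meta)) spot_id <- meta[["spot_id"]]
    if (is.null(channel) && "channel" %in% names(meta)) channel <- meta[["channel"]]
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("pixel", "mz", "intensity") %in% names(tab)))
  lapply(split(tab, tab$pixel), function(px) {
    px <- px[order(px$mz), ]
    spot_spectrum(px$mz, px$intensity,
                  spot_id = spot_id %||% NA_character_,
                  channel = channel %||% NA_character_)
  })
}

#' Write spot pixels in the simple tabular dialect
#' @param pixels List of `spot_spectrum`.
#' @param path File path.
#' @export
write_spot_tsv <- function(pixels, path) {
  sid <- pixels[[1]]$spot_id; ch <- pixels[[1]]$channel
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# spot_id=%s channel=%s", sid, ch), con)
  tab <- do.call(rbind, lapply(seq_along(pixels), function(i)
    data.frame(pixel = i, mz = pixels[[i]]$mz,
               intensity = pixels[[i]]$intensity)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
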