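# Session aggregation and method-agreement statistics: per-minute box-plot
# numbers, 1-degree histograms, Pearson correlation with the qualitative
# bands used in rehabilitation research (Portney's cutpoints), and the mean
# absolute percentage error used for the 5% agreement check.

.ANGLE_CHANNELS <- c("ca_deg", "sa_deg", "alpha_deg", "beta_deg", "ka_deg")

#' Per-minute box-plot aggregates of an angle series
#'
#' Collapses a 1 Hz series into one row per started minute and channel:
#' sample count and the five box-plot numbers. Quartiles use linear
#' interpolation between order statistics (R's default quantile type 7);
#' missing samples are excluded from `n`, and minute/channel combinations
#' with no finite samples are omitted.
#'
#' @param series Data frame with `t_s` plus any of `ca_deg`, `sa_deg`,
#'   `alpha_deg`, `beta_deg`, `ka_deg`.
#' @param channels Channels to aggregate; default: all present.
#' @return Data frame with columns `minute_index`, `channel`, `n`, `min`,
#'   `q1`, `median`, `q3`, `max`.
#' @export
aggregate_minutes <- function(series,
                              channels = intersect(.ANGLE_CHANNELS,
                                                   names(series))) {
  stopifnot("t_s" %in% names(series), length(channels) > 0)
  minute <- floor(series$t_s / 60)
  rows <- list()
  for (ch in channels) {
    for (m in sort(unique(minute))) {
      v <- series[[ch]][minute == m]
      v <- v[is.finite(v)]
      if (length(v) == 0L) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        minute_index = m, channel = ch, n = length(v),
        min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(minute_index = integer(0), channel = character(0),
                      n = integer(0), min = numeric(0), q1 = numeric(0),
                      median = numeric(0), q3 = numeric(0), max = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of an angle channel with 1-degree bins
#'
#' @param series Data frame containing `channel`.
#' @param channel Column name to bin.
#' @param bin_deg Bin width in degrees.
#' @return Data frame with `bin_lo`, `bin_hi`, `count` for non-empty bins.
#' @export
angle_histogram <- function(series, channel, bin_deg = 1) {
  v <- series[[channel]]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  }
  lo <- floor(v / bin_deg) * bin_deg
  tab <- table(lo)
  data.frame(bin_lo = as.numeric(names(tab)),
             bin_hi = as.numeric(names(tab)) + bin_deg,
             count = as.integer(tab))
}

.portney_band <- function(r) {
  a <- abs(r)
  if (a >= 0.90) "very_high" else if (a >= 0.70) "high"
  else if (a >= 0.50) "moderate" else "low"
}

#' Pearson correlation with qualitative agreement band
#'
#' Standard Pearson r between two paired series, a two-tailed p-value from
#' the t distribution, the r-squared (as a percentage), and the qualitative
#' band assigned by |r| against the 0.90 / 0.70 / 0.50 cutpoints
#' (very high / high / moderate / low) conventional in rehabilitation
#' measurement research.
#'
#' @param x,y Paired numeric series of equal length `>= 3`, each with
#'   nonzero variance.
#' @return A `validation_stats` list with `r`, `r_band`, `p_two_tailed`,
#'   `r_squared_pct`, `n`.
#' @examples
#' pearson_with_band(1:10, 2 * (1:10) + 1)  # r = 1, very_high
#' @export
pearson_with_band <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, r_band = .portney_band(r),
                 p_two_tailed = ct$p.value,
                 r_squared_pct = 100 * r^2, n = length(x)),
            class = "validation_stats")
}

#' Mean absolute percentage error against a reference series
#'
#' `mean(|ref - cand| / |ref|)`, reported as a fraction (0.05 is the 5%
#' boundary below which agreement is considered excellent). Samples whose
#' reference value is zero are excluded with a warning, since their
#' percentage error is undefined.
#'
#' @param reference,candidate Paired numeric series of equal length.
#' @return MAPE as a fraction (`>= 0`).
#' @examples
#' mape(c(100, 100), c(95, 105))  # 0.05
#' @export
mape <- function(reference, candidate) {
  stopifnot(length(reference) == length(candidate))
  ok <- is.finite(reference) & is.finite(candidate)
  reference <- reference[ok]; candidate <- candidate[ok]
  nz <- reference != 0
  if (!all(nz)) {
    if (!any(nz)) stop("all reference values are zero; MAPE undefined",
                       call. = FALSE)
    warning(sum(!nz), " sample(s) with zero reference excluded from MAPE",
            call. = FALSE)
    reference <- reference[nz]; candidate <- candidate[nz]
  }
  mean(abs(reference - candidate) / abs(reference))
}

#' Compare a candidate series against a reference
#'
#' Convenience wrapper pairing [pearson_with_band()] and [mape()] on one
#' channel of two session CSV-style data frames.
#'
#' @param reference,candidate Data frames sharing `t_s` and `channel`.
#' @param channel Angle column to compare.
#' @return A `validation_stats` list additionally carrying `mape`.
#' @export
validate_series <- function(reference, candidate, channel) {
  m <- merge(reference[c("t_s", channel)], candidate[c("t_s", channel)],
             by = "t_s", suffixes = c("_ref", "_cand"))
  vs <- pearson_with_band(m[[paste0(channel, "_ref")]],
                          m[[paste0(channel, "_cand")]])
  vs$mape <- mape(m[[paste0(channel, "_ref")]],
                  m[[paste0(channel, "_cand")]])
  vs
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s band), p = %.3g, R^2 = %.1f%%, n = %d\n",
              x$r, x$r_band, x$p_two_tailed, x$r_squared_pct, x$n))
  if (!is.null(x$mape)) {
    cat(sprintf("MAPE = %.3f (%.1f%%)%s\n", x$mape, 100 * x$mape,
                if (x$mape <= 0.05) " -- within the 5% agreement bound"
                else ""))
  }
  invisible(x)
}

#' Export a machine-readable session report
#'
#' Writes the session's raw angle series (`angles.csv`), per-minute
#' box-plot table (`minutes.csv`), 1-degree histograms (`histogram.csv`),
#' and a versioned `report.json` holding the label summary, any
#' method-agreement statistics and the aggregation metadata (quartile
#' method, bin width). Optionally renders quick-look PNG plots of the
#' time series and per-minute boxes.
#'
#' @param series Non-empty angle series (camera- or sensor-side, or merged).
#' @param dir Output directory; created if needed.
#' @param criteria A [posture_criteria()] used for the label summary.
#' @param stats Optional `validation_stats` to embed in the report.
#' @param plots If `TRUE`, also write `series.png` per-channel traces.
#' @return Named character vector of written file paths, invisibly.
#' @export
export_report <- function(series, dir, criteria = posture_criteria(),
                          stats = NULL, plots = FALSE) {
  if (is.null(series) || nrow(series) == 0L) {
    stop("cannot report an empty session", call. = FALSE)
  }
  if (!dir.exists(dir)) {
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create report directory: ", dir, call. = FALSE)
    }
  }
  channels <- intersect(.ANGLE_CHANNELS, names(series))
  paths <- c(angles = file.path(dir, "angles.csv"),
             minutes = file.path(dir, "minutes.csv"),
             histogram = file.path(dir, "histogram.csv"),
             report = file.path(dir, "report.json"))
  utils::write.csv(series, paths[["angles"]], row.names = FALSE)
  minutes <- aggregate_minutes(series, channels)
  utils::write.csv(minutes, paths[["minutes"]], row.names = FALSE)
  hists <- do.call(rbind, lapply(channels, function(ch) {
    h <- angle_histogram(series, ch)
    if (nrow(h)) cbind(channel = ch, h) else NULL
  }))
  utils::write.csv(hists, paths[["histogram"]], row.names = FALSE)
  report <- list(
    schema_version = "1.0",
    n_samples = nrow(series),
    channels = as.list(channels),
    summary = summarize_session(series, criteria),
    criteria = unclass(criteria),
    stats = if (!is.null(stats)) unclass(stats),
    aggregation = list(quartile_method = "linear interpolation (type 7)",
                       histogram_bin_deg = 1, minute_s = 60)
  )
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (isTRUE(plots)) {
    p <- file.path(dir, "series.png")
    grDevices::png(p, width = 900, height = 300 * length(channels))
    graphics::par(mfrow = c(length(channels), 1), mar = c(4, 4, 2, 1))
    for (ch in channels) {
      graphics::plot(series$t_s, series[[ch]], type = "l", xlab = "time (s)",
                     ylab = ch, main = ch)
    }
    grDevices::dev.off()
    paths <- c(paths, plot = p)
  }
  invisible(paths)
}
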