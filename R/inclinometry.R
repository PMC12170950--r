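# Wearable-sensor side of the pipeline: parse the two accelerometer CSVs
# (upper back, T1/T2 -> alpha; mid back, T12/L1 -> beta), convert each
# sample to a tilt, pair the streams by timestamp and compose the kyphosis
# angle. Forward flexion of a sensor's X-axis is positive, so a kyphotic
# back yields positive alpha and beta.

#' Read one accelerometer stream
#'
#' Accepts the raw-acceleration dialect (columns `t_s, ax_g, ay_g, az_g`)
#' or, for devices that expose tilt directly, a pre-computed `tilt_deg`
#' column alongside `t_s`. Rows containing non-finite values are dropped
#' with a warning. No filtering or calibration is applied.
#'
#' @param path CSV path.
#' @param role `"upper_back"` (alpha, T1/T2) or `"mid_back"` (beta,
#'   T12/L1).
#' @return Data frame of valid samples, ordered in time, with attribute
#'   `sensor_role`.
#' @export
read_sensor_csv <- function(path, role = c("upper_back", "mid_back")) {
  role <- match.arg(role)
  df <- utils::read.csv(path)
  raw <- all(c("t_s", "ax_g", "ay_g", "az_g") %in% names(df))
  tilt <- all(c("t_s", "tilt_deg") %in% names(df))
  if (!raw && !tilt) {
    stop("sensor CSV must have columns t_s, ax_g, ay_g, az_g ",
         "(or t_s, tilt_deg): ", path, call. = FALSE)
  }
  cols <- if (raw) c("t_s", "ax_g", "ay_g", "az_g") else c("t_s", "tilt_deg")
  df <- df[cols]
  ok <- rowSums(!is.finite(as.matrix(df))) == 0
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite values dropped from ", path,
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  if (is.unsorted(df$t_s, strictly = TRUE)) {
    stop("sensor timestamps must be strictly increasing: ", path,
         call. = FALSE)
  }
  rownames(df) <- NULL
  attr(df, "sensor_role") <- role
  df
}

# tilt column for a stream in either dialect
.stream_tilt <- function(stream) {
  if ("tilt_deg" %in% names(stream)) return(stream$tilt_deg)
  tilt_from_acceleration(stream$ax_g, stream$ay_g, stream$az_g)
}

#' Pair the two sensor streams into a kyphosis series
#'
#' For every upper-back timestamp, the nearest mid-back sample within
#' `tolerance_s` is paired with it; alpha and beta are the per-sample
#' tilts and `ka_deg = alpha_deg + beta_deg`. Upper-back samples with no
#' mid-back partner become `partial` samples carrying alpha only. The two
#' wireless sensors carry independent clocks, hence nearest-neighbour
#' pairing rather than an assumption of aligned grids.
#'
#' @param upper,mid Streams from [read_sensor_csv()] (roles `upper_back`
#'   and `mid_back`).
#' @param tolerance_s Maximum timestamp mismatch accepted for a pair.
#' @return Data frame with columns `t_s`, `alpha_deg`, `beta_deg`,
#'   `ka_deg`, `quality` (`complete`/`partial`).
#' @export
pair_streams <- function(upper, mid, tolerance_s = 0.5) {
  if (nrow(upper) == 0L || nrow(mid) == 0L ||
      min(upper$t_s) > max(mid$t_s) + tolerance_s ||
      min(mid$t_s) > max(upper$t_s) + tolerance_s) {
    warning("sensor streams do not overlap in time; empty series",
            call. = FALSE)
    return(data.frame(t_s = numeric(0), alpha_deg = numeric(0),
                      beta_deg = numeric(0), ka_deg = numeric(0),
                      quality = character(0)))
  }
  alpha <- .stream_tilt(upper)
  beta_all <- .stream_tilt(mid)
  # nearest mid-back sample for each upper-back timestamp
  nearest <- vapply(upper$t_s, function(t0) {
    j <- which.min(abs(mid$t_s - t0))
    if (abs(mid$t_s[j] - t0) <= tolerance_s) j else NA_integer_
  }, integer(1))
  beta <- ifelse(is.na(nearest), NA_real_, beta_all[nearest])
  ka <- alpha + beta
  data.frame(t_s = upper$t_s, alpha_deg = alpha, beta_deg = beta,
             ka_deg = ka,
             quality = ifelse(is.na(beta), "partial", "complete"))
}

#' Write a kyphosis series to CSV
#'
#' @param series Output of [pair_streams()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_kyphosis_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
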