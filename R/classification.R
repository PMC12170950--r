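# Clinical labelling. Forward head posture is flagged when the
# craniovertebral angle drops below 48 degrees; a shoulder angle above 54
# degrees reflects the compensatory shoulder protraction that accompanies
# it; hyperkyphosis is flagged when the composed kyphosis angle exceeds 40
# degrees. All inequalities are strict, so boundary values classify as
# non-pathological.

#' Posture classification criteria
#'
#' @param ca_fhp_below Craniovertebral angle below which the head is
#'   labelled FHP (degrees; default 48).
#' @param sa_fhp_above Shoulder angle above which the corroborating
#'   shoulder flag is set (degrees; default 54).
#' @param ka_kyphosis_above Kyphosis angle above which the spine is
#'   labelled kyphotic (degrees; default 40).
#' @param fhp_mode `"ca_only"` (default): the craniovertebral angle alone
#'   decides the head label and the shoulder angle is reported as a
#'   corroborating flag. `"ca_and_sa"`: both criteria must hold for an FHP
#'   label (strict conjunction).
#' @return A `posture_criteria` list.
#' @export
posture_criteria <- function(ca_fhp_below = 48, sa_fhp_above = 54,
                             ka_kyphosis_above = 40,
                             fhp_mode = c("ca_only", "ca_and_sa")) {
  fhp_mode <- match.arg(fhp_mode)
  stopifnot(ca_fhp_below > 0, sa_fhp_above > 0, ka_kyphosis_above > 0)
  structure(list(ca_fhp_below = ca_fhp_below, sa_fhp_above = sa_fhp_above,
                 ka_kyphosis_above = ka_kyphosis_above, fhp_mode = fhp_mode),
            class = "posture_criteria")
}

#' Classify a single sample
#'
#' @param ca_deg,sa_deg,ka_deg Angles in degrees; `NA` for absent.
#' @param criteria A [posture_criteria()].
#' @return List with `head` (`"FHP"`, `"NHP"` or `"indeterminate"`),
#'   `spine` (`"kyphotic"`, `"normal"` or `"indeterminate"`) and
#'   `sa_flag` (logical: shoulder angle exceeds its threshold; `NA` when
#'   absent).
#' @examples
#' classify_sample(ca_deg = 40, sa_deg = 55)  # head FHP
#' classify_sample(ca_deg = 48)               # boundary: head NHP
#' @export
classify_sample <- function(ca_deg = NA, sa_deg = NA, ka_deg = NA,
                            criteria = posture_criteria()) {
  stopifnot(inherits(criteria, "posture_criteria"))
  sa_flag <- if (is.na(sa_deg)) NA else sa_deg > criteria$sa_fhp_above
  head <- if (criteria$fhp_mode == "ca_only") {
    if (is.na(ca_deg)) "indeterminate"
    else if (ca_deg < criteria$ca_fhp_below) "FHP" else "NHP"
  } else {
    if (is.na(ca_deg) || is.na(sa_deg)) "indeterminate"
    else if (ca_deg < criteria$ca_fhp_below && sa_deg > criteria$sa_fhp_above)
      "FHP" else "NHP"
  }
  spine <- if (is.na(ka_deg)) "indeterminate"
           else if (ka_deg > criteria$ka_kyphosis_above) "kyphotic"
           else "normal"
  list(head = head, spine = spine, sa_flag = sa_flag)
}

#' Classify every sample of a series
#'
#' Accepts either a camera-side series (`ca_deg`/`sa_deg` columns) or a
#' sensor-side series (`ka_deg` column), or a merged frame with both.
#'
#' @param series Data frame with a `t_s` column and any of `ca_deg`,
#'   `sa_deg`, `ka_deg`.
#' @param criteria A [posture_criteria()].
#' @return `series` with added `head`, `spine` and `sa_flag` columns.
#' @export
classify_series <- function(series, criteria = posture_criteria()) {
  get_col <- function(nm) {
    if (nm %in% names(series)) series[[nm]] else rep(NA_real_, nrow(series))
  }
  ca <- get_col("ca_deg"); sa <- get_col("sa_deg"); ka <- get_col("ka_deg")
  lab <- lapply(seq_len(nrow(series)), function(i) {
    classify_sample(ca[i], sa[i], ka[i], criteria)
  })
  series$head <- vapply(lab, `[[`, character(1), "head")
  series$spine <- vapply(lab, `[[`, character(1), "spine")
  series$sa_flag <- vapply(lab, `[[`, logical(1), "sa_flag")
  series
}

#' Summarise the posture labels of a session
#'
#' Fractions are computed over determinate samples only; counts cover all
#' labels including `indeterminate`. The longest uninterrupted run of FHP
#' samples is reported in samples (seconds, at the nominal 1 Hz rate).
#'
#' @param series Data frame as accepted by [classify_series()]; non-empty.
#' @param criteria A [posture_criteria()].
#' @return List with `n`, per-label `counts`, `fhp_fraction`,
#'   `kyphotic_fraction` (each `NA` when every sample is indeterminate for
#'   that channel) and `longest_fhp_run_s`.
#' @export
summarize_session <- function(series, criteria = posture_criteria()) {
  if (is.null(series) || nrow(series) == 0L) {
    stop("cannot summarise an empty session", call. = FALSE)
  }
  lab <- classify_series(series, criteria)
  frac <- function(x, positive) {
    det <- x != "indeterminate"
    if (!any(det)) NA_real_ else mean(x[det] == positive)
  }
  runs <- rle(lab$head == "FHP")
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(
    n = nrow(lab),
    counts = list(head = as.list(table(lab$head)),
                  spine = as.list(table(lab$spine))),
    fhp_fraction = frac(lab$head, "FHP"),
    kyphotic_fraction = frac(lab$spine, "kyphotic"),
    longest_fhp_run_s = as.integer(longest)
  )
}
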