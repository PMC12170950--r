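# Frame-to-angle pipeline: map detected marker IDs to anatomical landmarks
# and emit a 1 Hz craniovertebral/shoulder angle series. Each frame is
# processed independently -- no temporal smoothing or inter-frame tracking,
# so a lost marker in one frame never contaminates its neighbours.

#' Marker-ID to landmark assignment
#'
#' Which dictionary IDs are taped over which sagittal landmark. The default
#' numbering follows the assessment-station convention: 1 = ear (tragus),
#' 2 = lower neck (C7 spinous process), 3 = shoulder (acromion process).
#'
#' @param tragus_id,c7_id,acromion_id Distinct 0-based marker IDs.
#' @param dictionary_name Fiducial dictionary identifier.
#' @return A `landmark_map` list.
#' @export
landmark_map <- function(tragus_id = 1L, c7_id = 2L, acromion_id = 3L,
                         dictionary_name = "4x4_50") {
  ids <- c(tragus = tragus_id, c7 = c7_id, acromion = acromion_id)
  n <- length(fiducial_dictionary(dictionary_name))
  if (anyDuplicated(ids) || any(ids < 0) || any(ids >= n)) {
    stop("landmark IDs must be distinct and within the dictionary",
         call. = FALSE)
  }
  structure(list(tragus_id = as.integer(tragus_id),
                 c7_id = as.integer(c7_id),
                 acromion_id = as.integer(acromion_id),
                 dictionary_name = dictionary_name),
            class = "landmark_map")
}

#' Map one frame's detections to sagittal landmarks
#'
#' Each configured marker ID that appears exactly once is reduced to its
#' centroid and assigned to its landmark. An ID detected more than once in
#' the same frame is ambiguous: that landmark is marked absent and a
#' warning is raised, rather than guessing between the duplicates.
#'
#' @param detections List of detections from [detect_markers()].
#' @param map A [landmark_map()].
#' @param t Timestamp in seconds attached to the result.
#' @return List with `t` and `tragus`, `c7`, `acromion` -- each a `c(x, y)`
#'   centroid or `NULL` when absent.
#' @export
map_landmarks <- function(detections, map = landmark_map(), t = 0) {
  stopifnot(inherits(map, "landmark_map"))
  ids <- vapply(detections, function(d) as.integer(d$id), integer(1))
  pick <- function(id, name) {
    hits <- which(ids == id)
    if (length(hits) == 1L) return(marker_center(detections[[hits]]))
    if (length(hits) > 1L) {
      warning("marker id ", id, " (", name, ") detected ", length(hits),
              " times at t=", t, "; landmark dropped as ambiguous",
              call. = FALSE)
    }
    NULL
  }
  list(t = t,
       tragus = pick(map$tragus_id, "tragus"),
       c7 = pick(map$c7_id, "c7"),
       acromion = pick(map$acromion_id, "acromion"))
}

# Angles for one frame's landmarks under a shoulder-angle convention.
.landmarks_to_angles <- function(lm, sa_convention = "acromion_to_c7") {
  ca <- if (!is.null(lm$tragus) && !is.null(lm$c7)) {
    craniovertebral_angle(lm$c7, lm$tragus)
  } else NA_real_
  sa_target <- switch(sa_convention,
                      acromion_to_c7 = lm$c7,
                      acromion_to_tragus = lm$tragus,
                      stop("unknown sa_convention: ", sa_convention,
                           call. = FALSE))
  sa <- if (!is.null(lm$acromion) && !is.null(sa_target)) {
    shoulder_angle(lm$acromion, sa_target)
  } else NA_real_
  quality <- if (!is.na(ca) && !is.na(sa)) "complete"
             else if (!is.na(ca) || !is.na(sa)) "partial"
             else "empty"
  data.frame(t_s = lm$t, ca_deg = ca, sa_deg = sa, quality = quality)
}

#' Process a 1 Hz frame sequence into an angle series
#'
#' Runs detection, landmark mapping and the angle formulas on every frame.
#' One output sample is produced per input frame; missing markers yield NA
#' angles with a `partial`/`empty` quality flag and are never interpolated.
#'
#' @param frames A directory of numbered PNG frames, a character vector of
#'   image paths, or a list of in-memory grayscale matrices.
#' @param map A [landmark_map()].
#' @param t Timestamps in seconds, one per frame; defaults to
#'   `0, 1, 2, ...` (the nominal 1 Hz sampling grid).
#' @param sa_convention `"acromion_to_c7"` (default) measures the shoulder
#'   angle toward C7; `"acromion_to_tragus"` toward the tragus.
#' @param ... Passed to [detect_markers()].
#' @return Data frame with columns `t_s`, `ca_deg`, `sa_deg`, `quality`
#'   (`complete`/`partial`/`empty`); `nrow` equals the frame count.
#' @export
process_stream <- function(frames, map = landmark_map(), t = NULL,
                           sa_convention = "acromion_to_c7", ...) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    frames <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
  }
  n <- length(frames)
  if (is.null(t)) t <- seq_len(n) - 1
  stopifnot(length(t) == n, !is.unsorted(t, strictly = TRUE))
  empty <- data.frame(t_s = numeric(0), ca_deg = numeric(0),
                      sa_deg = numeric(0), quality = character(0))
  if (n == 0L) return(empty)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- if (is.list(frames)) frames[[i]] else frames[i]
    det <- detect_markers(fr, dictionary_name = map$dictionary_name, ...)
    lm <- map_landmarks(det, map, t = t[i])
    rows[[i]] <- .landmarks_to_angles(lm, sa_convention)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an angle series and its detector settings to disk
#'
#' Emits the long-format CSV (`t_s, ca_deg, sa_deg, quality`) plus a JSON
#' sidecar recording the landmark map and shoulder-angle convention, so a
#' series can always be re-interpreted later.
#'
#' @param series Output of [process_stream()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @param map,sa_convention Settings recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path, map = landmark_map(),
                               sa_convention = "acromion_to_c7") {
  utils::write.csv(series, path, row.names = FALSE)
  meta <- list(landmark_map = unclass(map), sa_convention = sa_convention,
               sample_hz = 1)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
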