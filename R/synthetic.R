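# Synthetic fixtures: frames with fiducial markers laid out at prescribed
# craniovertebral/shoulder geometry (the inverse of the angle formulas),
# accelerometer streams at prescribed tilt, and the two-phase seated
# protocol (forward-head-with-kyphosis, short transition, neutral posture)
# used to validate the measurement chain end to end.

# evaluate `code` under a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' A static posture set-point
#'
#' The four angles that fully determine one synthetic posture: the two
#' camera-side angles and the two sensor inclinations. [fhp_posture()] and
#' [nhp_posture()] give the goniometer set-points used in the validation
#' protocol: forward head posture with kyphosis (CA 40, SA 55, KA 45 split
#' as alpha 25 + beta 20) and neutral head posture with a normal thoracic
#' spine (CA 55, SA 50, KA 20 split as alpha 12.5 + beta 7.5).
#'
#' @param ca_deg,sa_deg Camera-side angles, each in `(0, 180)`.
#' @param alpha_deg,beta_deg Sensor inclinations, each in `(-90, 90)`.
#' @param label Free-text tag carried into ground-truth tables.
#' @return A `posture_spec` list; `ka_deg` is derived as
#'   `alpha_deg + beta_deg`.
#' @export
posture_spec <- function(ca_deg, sa_deg, alpha_deg, beta_deg, label = "") {
  stopifnot(ca_deg > 0, ca_deg < 180, sa_deg > 0, sa_deg < 180,
            abs(alpha_deg) < 90, abs(beta_deg) < 90)
  structure(list(ca_deg = ca_deg, sa_deg = sa_deg, alpha_deg = alpha_deg,
                 beta_deg = beta_deg,
                 ka_deg = kyphosis_angle(alpha_deg, beta_deg),
                 label = label),
            class = "posture_spec")
}

#' @rdname posture_spec
#' @export
fhp_posture <- function() {
  posture_spec(ca_deg = 40, sa_deg = 55, alpha_deg = 25, beta_deg = 20,
               label = "FHP_with_kyphosis")
}

#' @rdname posture_spec
#' @export
nhp_posture <- function() {
  posture_spec(ca_deg = 55, sa_deg = 50, alpha_deg = 12.5, beta_deg = 7.5,
               label = "NHP_normal_spine")
}

# marker centre positions (unrounded) realising a posture's CA/SA on the
# row-down canvas, anchored at the C7 position with fixed baseline lengths
.posture_landmarks <- function(spec, c7_xy, baseline_px,
                               sa_convention = "acromion_to_c7") {
  ca <- spec$ca_deg * pi / 180
  sa <- spec$sa_deg * pi / 180
  tragus <- c(c7_xy[1] + baseline_px * cos(ca),
              c7_xy[2] - baseline_px * sin(ca))
  anchor <- switch(sa_convention,
                   acromion_to_c7 = c7_xy,
                   acromion_to_tragus = tragus,
                   stop("unknown sa_convention: ", sa_convention,
                        call. = FALSE))
  acromion <- c(anchor[1] - baseline_px * cos(sa),
                anchor[2] + baseline_px * sin(sa))
  list(tragus = tragus, c7 = c7_xy, acromion = acromion)
}

# stamp a marker tag centred (as nearly as pixel rounding allows) at xy;
# returns the actual rendered centre
.stamp_tag <- function(canvas, tag, xy) {
  px <- nrow(tag)
  left <- round(xy[1] - (px - 1) / 2)
  top <- round(xy[2] - (px - 1) / 2)
  if (left < 1 || top < 1 || left + px - 1 > ncol(canvas) ||
      top + px - 1 > nrow(canvas)) {
    stop("layout error: marker at (", round(xy[1]), ", ", round(xy[2]),
         ") does not fit the canvas", call. = FALSE)
  }
  canvas[top:(top + px - 1), left:(left + px - 1)] <- tag
  list(canvas = canvas, center = c(x = left + (px - 1) / 2,
                                   y = top + (px - 1) / 2))
}

#' Render a synthetic sagittal frame at a prescribed posture
#'
#' Draws the three landmark markers on a white portrait canvas so that the
#' marker centroids realise exactly the requested craniovertebral and
#' shoulder angles (up to pixel rounding) at a fixed baseline segment
#' length. The inverse of the measurement geometry, used to exercise the
#' whole detect-and-measure chain against known ground truth.
#'
#' @param spec A [posture_spec()].
#' @param canvas `c(width, height)` in pixels; the default is the
#'   2048 x 1080-class portrait canvas of the reference webcam setup.
#' @param map A [landmark_map()] giving the IDs to render.
#' @param marker_px Rendered marker side in pixels.
#' @param baseline_px C7-tragus and shoulder-anchor segment lengths in
#'   pixels.
#' @param c7_xy C7 marker-centre position; default places the figure in the
#'   canvas middle.
#' @param sa_convention Shoulder-angle convention to realise (see
#'   [process_stream()]).
#' @return List with `image` (height x width matrix, white = 1) and
#'   `truth`: the rendered marker centres (`tragus`, `c7`, `acromion`) plus
#'   the requested `ca_deg`/`sa_deg`.
#' @export
render_posture_frame <- function(spec, canvas = c(1080, 2048),
                                 map = landmark_map(), marker_px = 40,
                                 baseline_px = 300, c7_xy = NULL,
                                 sa_convention = "acromion_to_c7") {
  width <- canvas[1]; height <- canvas[2]
  if (is.null(c7_xy)) c7_xy <- c(round(width * 0.45), round(height * 0.55))
  lm <- .posture_landmarks(spec, c7_xy, baseline_px, sa_convention)
  img <- matrix(1, nrow = height, ncol = width)
  centers <- list()
  ids <- c(tragus = map$tragus_id, c7 = map$c7_id, acromion = map$acromion_id)
  for (nm in names(ids)) {
    tag <- fiducial_tag(ids[[nm]], marker_px, map$dictionary_name)
    st <- .stamp_tag(img, tag, lm[[nm]])
    img <- st$canvas
    centers[[nm]] <- st$center
  }
  list(image = img,
       truth = c(centers, list(ca_deg = spec$ca_deg, sa_deg = spec$sa_deg)))
}

#' Simulate a 1 Hz accelerometer stream at a prescribed tilt
#'
#' Emits unit-norm acceleration vectors whose X-axis tilt equals the
#' requested angle plus optional zero-mean Gaussian perturbation (the
#' wearable's specified inclination accuracy is 0.2 degrees, the default
#' noise scale). The exact inverse of [tilt_from_acceleration()] when
#' `noise_sd_deg = 0`.
#'
#' @param angle_deg Target tilt in degrees, `|angle| < 90`; a scalar or a
#'   length-`n_s` trajectory.
#' @param n_s Number of one-second samples.
#' @param noise_sd_deg Standard deviation of the tilt perturbation.
#' @param seed Optional seed (global RNG state is preserved).
#' @param t0 Timestamp of the first sample.
#' @return Data frame with columns `t_s, ax_g, ay_g, az_g`.
#' @export
simulate_accel_stream <- function(angle_deg, n_s, noise_sd_deg = 0.2,
                                  seed = NULL, t0 = 0) {
  stopifnot(n_s >= 1)
  if (any(abs(angle_deg) >= 90)) {
    stop("invalid spec: tilt must satisfy |angle| < 90 degrees",
         call. = FALSE)
  }
  angle <- rep_len(angle_deg, n_s)
  noise <- if (noise_sd_deg == 0) numeric(n_s) else
    .with_seed(seed, stats::rnorm(n_s, 0, noise_sd_deg))
  tilt <- (angle + noise) * pi / 180
  data.frame(t_s = t0 + seq_len(n_s) - 1,
             ax_g = sin(tilt), ay_g = 0, az_g = -cos(tilt))
}

#' Two-phase protocol specification
#'
#' The validation protocol: the subject (a posable manikin in the reference
#' study) holds phase-1 posture for `phase1_s` seconds, is moved to the
#' phase-2 posture over a `transition_s`-second window, and holds it until
#' `total_s`. Angles interpolate linearly during the transition. Defaults
#' reproduce the published protocol: forward head posture with kyphosis for
#' 0-120 s, an approximately 5 s change, then neutral posture to 240 s,
#' sampled at 1 Hz.
#'
#' @param phase1,phase2 [posture_spec()]s.
#' @param phase1_s,transition_s,total_s Phase durations in seconds;
#'   `phase1_s + transition_s <= total_s`.
#' @param jitter_sd_deg Per-second Gaussian jitter on the true angles
#'   (posture wobble); 0 keeps each static phase exactly constant.
#' @param noise_sd_deg Sensor measurement noise applied on top of the true
#'   inclinations (degrees; default the wearable's 0.2-degree accuracy).
#' @param seed Single seed governing every stochastic element.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(phase1 = fhp_posture(), phase2 = nhp_posture(),
                          phase1_s = 120, transition_s = 5, total_s = 240,
                          jitter_sd_deg = 0, noise_sd_deg = 0.2, seed = 1L) {
  stopifnot(phase1_s >= 0, transition_s >= 0, total_s >= 1,
            phase1_s + transition_s <= total_s,
            jitter_sd_deg >= 0, noise_sd_deg >= 0)
  structure(list(phase1 = phase1, phase2 = phase2,
                 phase1_s = phase1_s, transition_s = transition_s,
                 total_s = total_s, jitter_sd_deg = jitter_sd_deg,
                 noise_sd_deg = noise_sd_deg, seed = as.integer(seed)),
            class = "protocol_spec")
}

# per-second true angles and phase labels for a protocol
.protocol_truth <- function(p) {
  t <- seq_len(p$total_s) - 1
  w <- pmin(1, pmax(0, if (p$transition_s > 0)
    (t - p$phase1_s) / p$transition_s else as.numeric(t >= p$phase1_s)))
  lerp <- function(field) (1 - w) * p$phase1[[field]] + w * p$phase2[[field]]
  phase <- ifelse(t < p$phase1_s, "phase1",
                  ifelse(t < p$phase1_s + p$transition_s, "transition",
                         "phase2"))
  data.frame(t_s = t, true_ca = lerp("ca_deg"), true_sa = lerp("sa_deg"),
             true_alpha = lerp("alpha_deg"), true_beta = lerp("beta_deg"),
             phase = phase)
}

#' Generate a full synthetic protocol bundle
#'
#' Produces every input the measurement pipeline consumes for one session:
#' a 1 Hz frame sequence rendered at the per-second true geometry, the two
#' accelerometer CSV streams, a ground-truth table, and a manifest
#' recording the seed and geometry. With a fixed seed the CSV outputs are
#' byte-identical across runs.
#'
#' @param p A [protocol_spec()].
#' @param outdir Output directory. When `NULL`, nothing is written and the
#'   bundle is returned in memory (without rendered frames unless
#'   `frames = "memory"`).
#' @param frames `"disk"` writes `frames/frame_NNNN.png` under `outdir`;
#'   `"memory"` returns the matrices (costly at full canvas size);
#'   `"none"` skips rendering.
#' @param canvas,map,marker_px,baseline_px,sa_convention Frame geometry,
#'   as in [render_posture_frame()].
#' @return List with `truth` (data frame, one row per second), `upper` and
#'   `mid` sensor data frames, `frames` (paths or matrices or `NULL`), and
#'   `paths` of any files written.
#' @export
generate_protocol <- function(p = protocol_spec(), outdir = NULL,
                              frames = if (is.null(outdir)) "none" else "disk",
                              canvas = c(1080, 2048), map = landmark_map(),
                              marker_px = 40, baseline_px = 300,
                              sa_convention = "acromion_to_c7") {
  frames <- match.arg(frames, c("disk", "memory", "none"))
  truth <- .protocol_truth(p)
  if (p$jitter_sd_deg > 0) {
    jit <- .with_seed(p$seed + 1L, matrix(
      stats::rnorm(4 * nrow(truth), 0, p$jitter_sd_deg), ncol = 4))
    truth$true_ca <- truth$true_ca + jit[, 1]
    truth$true_sa <- truth$true_sa + jit[, 2]
    truth$true_alpha <- truth$true_alpha + jit[, 3]
    truth$true_beta <- truth$true_beta + jit[, 4]
  }
  upper <- simulate_accel_stream(truth$true_alpha, nrow(truth),
                                 p$noise_sd_deg, seed = p$seed + 2L)
  mid <- simulate_accel_stream(truth$true_beta, nrow(truth),
                               p$noise_sd_deg, seed = p$seed + 3L)
  paths <- character(0)
  frame_out <- NULL
  if (frames != "none") {
    render_one <- function(i) {
      spec <- posture_spec(truth$true_ca[i], truth$true_sa[i],
                           truth$true_alpha[i], truth$true_beta[i])
      render_posture_frame(spec, canvas = canvas, map = map,
                           marker_px = marker_px, baseline_px = baseline_px,
                           sa_convention = sa_convention)$image
    }
    if (frames == "memory") {
      frame_out <- lapply(seq_len(nrow(truth)), render_one)
    } else {
      fdir <- file.path(outdir, "frames")
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      frame_out <- file.path(fdir, sprintf("frame_%04d.png", truth$t_s))
      for (i in seq_len(nrow(truth))) {
        png::writePNG(render_one(i), frame_out[i])
      }
    }
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
    paths <- c(upper = file.path(outdir, "upper_back.csv"),
               mid = file.path(outdir, "mid_back.csv"),
               truth = file.path(outdir, "ground_truth.csv"),
               manifest = file.path(outdir, "manifest.json"))
    utils::write.csv(upper, paths[["upper"]], row.names = FALSE)
    utils::write.csv(mid, paths[["mid"]], row.names = FALSE)
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
    manifest <- list(seed = p$seed, protocol = unclass(p),
                     canvas = canvas, marker_px = marker_px,
                     baseline_px = baseline_px,
                     sa_convention = sa_convention,
                     landmark_map = unclass(map))
    manifest$protocol$phase1 <- unclass(manifest$protocol$phase1)
    manifest$protocol$phase2 <- unclass(manifest$protocol$phase2)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  list(truth = truth, upper = upper, mid = mid, frames = frame_out,
       paths = paths)
}
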