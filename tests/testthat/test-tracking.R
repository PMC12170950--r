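test_that("a rendered marker is detected with its ID and a 1 px-accurate centroid", {
  img <- matrix(1, 400, 400)
  tag <- fiducial_tag(1L, 40)
  img[100:139, 180:219] <- tag          # centre at (199.5, 119.5)
  det <- detect_markers(img)
  expect_length(det, 1)
  expect_identical(det[[1]]$id, 1L)
  ctr <- marker_center(det[[1]])
  expect_lt(max(abs(ctr - c(199.5, 119.5))), 1)
})

test_that("a blank frame yields no detections", {
  expect_identical(detect_markers(matrix(1, 200, 200)), list())
})

test_that("all three landmark markers in one frame are detected and mapped", {
  f <- small_frame(fhp_posture())
  det <- detect_markers(f$image)
  expect_length(det, 3)
  expect_setequal(vapply(det, `[[`, integer(1), "id"), c(1L, 2L, 3L))
  lm <- map_landmarks(det, landmark_map(), t = 3)
  expect_identical(lm$t, 3)
  for (nm in c("tragus", "c7", "acromion")) {
    expect_lt(max(abs(lm[[nm]] - f$truth[[nm]])), 1)
  }
})

test_that("duplicate marker IDs drop that landmark as ambiguous", {
  corners <- rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9))
  mk <- function(id, dx = 0) list(id = id, corners = corners + dx)
  expect_warning(
    lm <- map_landmarks(list(mk(1L), mk(1L, 50), mk(2L, 100), mk(3L, 150)),
                        landmark_map(), t = 0),
    "ambiguous")
  expect_null(lm$tragus)
  expect_false(is.null(lm$c7))
  expect_false(is.null(lm$acromion))
})

test_that("partial landmark sets give partial samples without the missing angle", {
  corners <- rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9))
  det <- list(list(id = 1L, corners = corners + 200),
              list(id = 2L, corners = corners))
  lm <- map_landmarks(det, landmark_map(), t = 0)
  row <- posturekit:::.landmarks_to_angles(lm)
  expect_false(is.na(row$ca_deg))
  expect_true(is.na(row$sa_deg))
  expect_identical(row$quality, "partial")
})

test_that("process_stream emits one sample per frame and flags empty frames", {
  frames <- replicate(6, small_frame(nhp_posture())$image, simplify = FALSE)
  frames[[3]] <- matrix(1, 100, 100)  # markers lost in frame 3
  frames[[4]] <- matrix(1, 100, 100)
  s <- process_stream(frames)
  expect_identical(nrow(s), 6L)
  expect_identical(s$t_s, as.numeric(0:5))
  expect_identical(s$quality, c("complete", "complete", "empty", "empty",
                                "complete", "complete"))
  expect_true(all(is.na(s$ca_deg[3:4])))
  expect_identical(nrow(process_stream(list())), 0L)
})

test_that("detection is stateless: frame order does not change per-frame output", {
  f1 <- small_frame(fhp_posture())$image
  f2 <- small_frame(nhp_posture())$image
  a <- process_stream(list(f1, f2))
  b <- process_stream(list(f2, f1))
  expect_equal(a$ca_deg, rev(b$ca_deg))
  expect_equal(a$sa_deg, rev(b$sa_deg))
})

test_that("render-detect-measure recovers angles drawn in [10, 80] within 1 degree", {
  set.seed(21)
  for (i in 1:8) {
    ca <- runif(1, 10, 80)
    sa <- runif(1, 10, 80)
    f <- small_frame(posture_spec(ca, sa, 10, 10))
    s <- process_stream(list(f$image))
    expect_identical(s$quality, "complete")
    expect_lt(abs(s$ca_deg - ca), 1.0)
    expect_lt(abs(s$sa_deg - sa), 1.0)
  }
})

test_that("the acromion-to-tragus shoulder convention is honoured end to end", {
  spec <- posture_spec(40, 62, 10, 10)
  f <- small_frame(spec, sa_convention = "acromion_to_tragus")
  s <- process_stream(list(f$image), sa_convention = "acromion_to_tragus")
  expect_lt(abs(s$sa_deg - 62), 1.0)
})

test_that("angle series round-trips through CSV with its JSON sidecar", {
  s <- process_stream(list(small_frame(fhp_posture())$image))
  path <- file.path(withr::local_tempdir(), "angles.csv")
  write_angle_series(s, path)
  back <- utils::read.csv(path)
  expect_equal(back$ca_deg, s$ca_deg)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$landmark_map$c7_id, 2L)
  expect_identical(meta$sa_convention, "acromion_to_c7")
})
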