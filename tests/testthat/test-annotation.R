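toy_timeline <- function(extra = NULL) {
  iv <- rbind(
    data.frame(onset_ms = 0, offset_ms = 0, label = "session_start"),
    data.frame(onset_ms = 5000, offset_ms = 9000, label = "smile"),
    data.frame(onset_ms = 60000, offset_ms = 60000, label = "robot_movement"),
    extra
  )
  annotation_timeline(iv, session_id = "T1", participant_id = "ASD-P1",
                      group = "ASD")
}

test_that("timeline validation names offending rows", {
  expect_error(
    annotation_timeline(data.frame(onset_ms = 10, offset_ms = 5,
                                   label = "smile")),
    "offset < onset")
  expect_error(
    annotation_timeline(data.frame(onset_ms = -5, offset_ms = 5,
                                   label = "smile")),
    "negative")
  expect_error(
    annotation_timeline(data.frame(onset_ms = 0, offset_ms = 5,
                                   label = "grimace")),
    "grimace")
  expect_error(
    annotation_timeline(data.frame(onset_ms = c(0, 500), offset_ms = c(1000, 1500),
                                   label = "smile")),
    "overlapping")
})

test_that("timeline TSV round trip is lossless", {
  tl <- toy_timeline()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeline(tl, path)
  expect_identical(readLines(path)[1], "onset_ms\toffset_ms\tlabel\tcoder")
  back <- read_timeline(path, session_id = "T1", participant_id = "ASD-P1",
                        group = "ASD")
  expect_identical(back$intervals, tl$intervals)
  expect_identical(back$coder_id, tl$coder_id)
  # empty file with header is a valid empty timeline
  writeLines("onset_ms\toffset_ms\tlabel\tcoder", path)
  empty <- read_timeline(path)
  expect_identical(nrow(empty$intervals), 0L)
})

test_that("EMG/video synchronization follows the time tag", {
  tl <- toy_timeline()
  rec <- emg_recording(matrix(0:3999 * 1e-3, ncol = 4), 1000,
                       time_tag_sample = 0)
  expect_identical(synchronize(rec, tl), 0)
  rec2 <- emg_recording(matrix(rnorm(16000), ncol = 4), 1000,
                        time_tag_sample = 2000)
  tl2 <- annotation_timeline(
    data.frame(onset_ms = 500, offset_ms = 500, label = "session_start"))
  expect_identical(synchronize(rec2, tl2), -1500)
  # duplicated or missing session_start
  tl3 <- annotation_timeline(
    data.frame(onset_ms = c(0, 100), offset_ms = c(0, 100),
               label = "session_start"))
  expect_error(synchronize(rec2, tl3), "2 session_start")
  tl4 <- annotation_timeline(
    data.frame(onset_ms = 0, offset_ms = 100, label = "smile"))
  expect_error(synchronize(rec2, tl4), "no session_start")
})

test_that("smile fusion is exactly conservative and validates inputs", {
  video <- smile_track(0, 1000)
  unobs <- data.frame(onset_ms = 1000, offset_ms = 2000)
  emg <- smile_track(1200, 1800, source = "emg")
  fused <- fuse_smiles(video, emg, unobs)
  expect_equal(smile_total_s(fused), 1.6) # 1000 + 600 ms
  expect_equal(smile_total_s(fused),
               smile_total_s(video) + smile_total_s(emg))
  # emg empty -> fused equals video
  same <- fuse_smiles(video, smile_track(source = "emg"), unobs)
  expect_equal(as.data.frame(same), as.data.frame(video))
  # adjacency merge keeps total duration
  adj <- fuse_smiles(video, smile_track(1000, 1500, source = "emg"), unobs)
  expect_identical(nrow(adj), 1L)
  expect_equal(adj$onset_ms, 0)
  expect_equal(adj$offset_ms, 1500)
  # violations of the observability split
  expect_error(fuse_smiles(video, smile_track(2500, 3000, "emg"), unobs),
               "within the unobservable")
  expect_error(fuse_smiles(smile_track(900, 1100), smile_track(source = "emg"),
                           unobs),
               "disjoint")
})

test_that("fusion conservation holds across random tracks", {
  set.seed(77)
  for (rep in 1:20) {
    v_on <- sort(sample(0:50, 3)) * 1000
    video <- smile_track(v_on, v_on + 800)
    unobs <- data.frame(onset_ms = 60000, offset_ms = 90000)
    e_on <- 60000 + sort(sample(0:28, 2)) * 1000
    emg <- smile_track(e_on, e_on + c(700, 900), source = "emg")
    fused <- fuse_smiles(video, emg, unobs)
    expect_equal(smile_total_s(fused),
                 smile_total_s(video) + smile_total_s(emg),
                 tolerance = 1e-12)
  }
})

test_that("segment extraction returns the documented six windows", {
  extra <- rbind(
    data.frame(onset_ms = 300000, offset_ms = 320000, label = "prosocial_walk"),
    data.frame(onset_ms = 400000, offset_ms = 400000, label = "robot_fall_start"),
    data.frame(onset_ms = 403000, offset_ms = 407000, label = "smile"),
    data.frame(onset_ms = 410000, offset_ms = 418000, label = "prosocial_fall"),
    data.frame(onset_ms = 420000, offset_ms = 420000, label = "robot_adjusted")
  )
  tl <- toy_timeline(extra)
  segs <- extract_segments(tl, session_end_ms = 600000)
  expect_identical(segs$kind, c("a", "b", "c", "d", "e", "f"))
  expect_true(all(segs$present))
  b <- segs[segs$kind == "b", ]
  expect_equal(c(b$start_ms, b$end_ms), c(240000, 300000))
  # a-d, f are exactly one minute before clipping
  for (k in c("a", "b", "c", "d", "f")) {
    s <- segs[segs$kind == k, ]
    expect_equal(s$end_ms - s$start_ms, 60000, label = paste("window", k))
  }
  e <- segs[segs$kind == "e", ]
  expect_equal(c(e$start_ms, e$end_ms), c(403000, 407000))
  # alternative anchor for (d): one minute before the robot's fall
  segs2 <- extract_segments(tl, session_end_ms = 600000,
                            d_anchor = "robot_fall")
  d2 <- segs2[segs2$kind == "d", ]
  expect_equal(c(d2$start_ms, d2$end_ms), c(340000, 400000))
  expect_identical(d2$anchor, "robot_fall_start")
})

test_that("missing anchors yield absent windows, not errors", {
  tl <- toy_timeline(
    data.frame(onset_ms = 300000, offset_ms = 320000, label = "prosocial_walk"))
  segs <- extract_segments(tl, session_end_ms = 400000)
  expect_identical(segs$present[segs$kind %in% c("a", "b", "c")],
                   rep(TRUE, 3))
  expect_identical(segs$present[segs$kind %in% c("d", "e", "f")],
                   rep(FALSE, 3))
  # no smile during the fall: window (e) present with zero duration
  extra <- rbind(
    data.frame(onset_ms = 400000, offset_ms = 400000, label = "robot_fall_start"),
    data.frame(onset_ms = 420000, offset_ms = 420000, label = "robot_adjusted")
  )
  segs2 <- extract_segments(toy_timeline(extra), session_end_ms = 500000)
  e <- segs2[segs2$kind == "e", ]
  expect_true(e$present)
  expect_equal(e$end_ms - e$start_ms, 0)
})

test_that("smile duration in a window sums clipped intersections", {
  track <- smile_track(c(10000, 55000), c(20000, 70000))
  win <- list(start_ms = 0, end_ms = 60000, present = TRUE)
  expect_equal(smile_duration_in(track, win), 15) # 10 + 5 s
  full <- smile_track(0, 60000)
  expect_equal(smile_duration_in(full, win), 60)
  expect_equal(smile_duration_in(smile_track(), win), 0)
})

test_that("per-second pre-window coding applies the 500 ms overlap rule", {
  base <- data.frame(onset_ms = 0, offset_ms = 0, label = "session_start")
  onset <- 60000
  # smile covering the full window: all ten face seconds positive
  tl <- annotation_timeline(rbind(base,
    data.frame(onset_ms = 45000, offset_ms = 61000, label = "smile")))
  codes <- code_pre_window(tl, onset)
  expect_identical(sum(codes$face), 10L)
  expect_false(attr(codes, "clipped"))
  # 600 ms of smile inside second -3 -> exactly one positive second
  tl2 <- annotation_timeline(rbind(base,
    data.frame(onset_ms = onset - 3200, offset_ms = onset - 2400,
               label = "smile")))
  codes2 <- code_pre_window(tl2, onset)
  expect_identical(sum(codes2$face), 1L)
  expect_true(codes2$face[codes2$second == -3])
  # a 600 ms smile straddling two bins with < 500 ms in each codes nothing
  tl3 <- annotation_timeline(rbind(base,
    data.frame(onset_ms = onset - 3200, offset_ms = onset - 2600,
               label = "smile")))
  expect_identical(sum(code_pre_window(tl3, onset)$face), 0L)
  # no annotations at all: all-negative codes
  codes4 <- code_pre_window(annotation_timeline(base), onset)
  expect_identical(sum(codes4$head, codes4$face, codes4$movement), 0L)
  # early onset clips the window and flags it
  expect_true(attr(code_pre_window(annotation_timeline(base), 5000),
                   "clipped"))
})

test_that("case quadrant classification covers all four outcomes", {
  expect_identical(classify_case(list(S = 1, PB = 1)), "A")
  expect_identical(classify_case(list(S = 0, PB = 0)), "B")
  expect_identical(classify_case(list(S = 1, PB = 0)), "C")
  expect_identical(classify_case(list(S = 0, PB = 1)), "D")
  expect_error(classify_case(list(S = NA, PB = 1)), "S and PB")
})

test_that("two-coder ICC matches an independent aov decomposition", {
  set.seed(1)
  x <- rnorm(50)
  r <- cbind(x, x + rnorm(50, sd = 0.3))
  res <- icc_two_coders(r)
  d <- data.frame(y = c(r), item = factor(rep(1:50, 2)),
                  coder = factor(rep(1:2, each = 50)))
  ms <- anova(stats::aov(y ~ item + coder, d))
  msr <- ms["item", "Mean Sq"]; msc <- ms["coder", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 50)
  expect_equal(res$icc, oracle, tolerance = 1e-12)
  expect_equal(res$f_statistic, msr / mse, tolerance = 1e-12)
  expect_identical(res$df, c(49, 49))
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
})

test_that("ICC distinguishes absolute agreement from consistency", {
  set.seed(2)
  x <- rnorm(40)
  shifted <- cbind(x, x + 5) # large constant offset between coders
  agree <- icc_two_coders(shifted)$icc
  consist <- icc_two_coders(shifted, type = "consistency")$icc
  expect_lt(agree, consist)
  expect_gt(consist, 0.99)
  # identical columns: perfect agreement for any non-constant ratings
  expect_equal(icc_two_coders(cbind(x, x))$icc, 1)
  # independent noise: near-zero ICC
  set.seed(3)
  noise <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_two_coders(noise)$icc), 0.1)
  # degenerate input
  expect_error(icc_two_coders(matrix(1, 5, 2)), "zero variance")
})
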