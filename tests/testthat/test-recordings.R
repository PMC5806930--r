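# Session I/O (native container and EDF) and block extraction semantics.

make_small_session <- function(seed = 5, duration = 300) {
  cfg <- sim_config(2, 2, fs = 500, duration = duration, source_node = "1A",
                    source_gain = 2, seed = seed,
                    seizure_intervals = list(c(duration - 50, duration - 30)))
  ses <- simulate_session(cfg)
  ses$exclusion_intervals <- matrix(c(40, 50), 1)
  ses
}

test_that("native container round-trips a session exactly", {
  ses <- make_small_session()
  prefix <- file.path(withr::local_tempdir(), "ses")
  write_session(ses, prefix)
  back <- load_session(paste0(prefix, ".json"))
  expect_identical(unname(back$signal), unname(ses$signal))
  expect_equal(back$fs, ses$fs)
  expect_equal(back$seizure_intervals, ses$seizure_intervals)
  expect_equal(back$exclusion_intervals, ses$exclusion_intervals)
  expect_equal(back$eoi, ses$eoi)
  expect_equal(back$channel_labels, ses$channel_labels)
})

test_that("EDF round-trip preserves signals to quantization accuracy", {
  ses <- make_small_session(duration = 60)
  ses$seizure_intervals <- matrix(c(30, 50), 1)
  prefix <- file.path(withr::local_tempdir(), "ses")
  write_session(ses, prefix, format = "edf")
  back <- load_session(paste0(prefix, ".edf"), layout_spec = ses$grid)
  expect_equal(ncol(back$signal), 4)
  expect_equal(back$fs, 500)
  rng <- max(ses$signal) - min(ses$signal)
  expect_lt(max(abs(back$signal - ses$signal)), 4 * rng / 65535)
  expect_equal(back$seizure_intervals, ses$seizure_intervals)
})

test_that("EDF loading validates layout and annotations", {
  ses <- make_small_session(duration = 60)
  dir <- withr::local_tempdir()
  write_session(ses, file.path(dir, "a"), format = "edf")
  # missing annotation sidecar
  file.rename(file.path(dir, "a.annotations.json"), file.path(dir, "keep.json"))
  expect_error(load_session(file.path(dir, "a.edf"), ses$grid),
               "missing annotation file")
  file.rename(file.path(dir, "keep.json"), file.path(dir, "a.annotations.json"))
  # layout names a channel absent from the file
  expect_error(load_session(file.path(dir, "a.edf"), grid_layout(2, 3)),
               "absent from the EDF")
  # channels not in the layout are dropped with a warning
  expect_warning(back <- load_session(file.path(dir, "a.edf"), grid_layout(1, 2)),
                 "dropping channels")
  expect_equal(ncol(back$signal), 2)
  expect_error(load_session(file.path(dir, "nothere.json")), "no such file")
})

test_that("ictal blocks start at annotated seizure onsets", {
  cfg <- sim_config(2, 2, fs = 500, duration = 400,
                    seizure_intervals = list(c(100, 130), c(200, 230), c(300, 330)),
                    seed = 2)
  ses <- simulate_session(cfg)
  blocks <- extract_ictal_blocks(ses)
  expect_length(blocks, 3)
  expect_equal(vapply(blocks, function(b) b$start_time, 1.0), c(100, 200, 300))
  expect_true(all(vapply(blocks, function(b) b$label, "") == "ictal"))
  # 0-based half-open sample convention: t = 100 s at 500 Hz is samples
  # 50,000..54,999, i.e. R rows 50,001..55,000
  expect_identical(blocks[[1]]$data, ses$signal[50001:55000, ])
  expect_equal(nrow(blocks[[2]]$data), 10 * 500)
})

test_that("degenerate seizures are handled with warnings", {
  cfg <- sim_config(2, 2, fs = 500, duration = 100,
                    seizure_intervals = list(c(20, 24)), seed = 2)
  ses <- simulate_session(cfg)
  expect_warning(b <- extract_ictal_blocks(ses), "shorter than the block")
  expect_equal(nrow(b[[1]]$data), 5000)
  ses2 <- simulate_session(sim_config(2, 2, fs = 500, duration = 100,
                                      seizure_intervals = list(c(95, 99)),
                                      seed = 2))
  expect_warning(b2 <- extract_ictal_blocks(ses2), "too close to the recording end")
  expect_length(b2, 0)
})

test_that("rest blocks avoid seizures, guard bands and exclusions", {
  ses <- make_small_session(duration = 600)
  ses$seizure_intervals <- matrix(c(100, 160), 1)
  ses$exclusion_intervals <- matrix(c(300, 320), 1)
  set.seed(1)
  blocks <- sample_rest_blocks(ses, 1000, guard = 60)
  starts <- vapply(blocks, function(b) b$start_time, 1.0)
  # guard-band arithmetic: no start in (100 - 10 - 60, 160 + 60)
  expect_false(any(starts > 30 & starts < 220))
  expect_false(any(starts > 290 & starts < 320))
  expect_true(all(starts >= 0 & starts <= 590))
  expect_true(all(vapply(blocks, function(b) b$label, "") == "rest"))
})

test_that("rest sampling is reproducible and errors when infeasible", {
  ses <- make_small_session(duration = 600)
  s1 <- vapply(sample_rest_blocks(ses, 20, seed = 7), function(b) b$start_time, 1.0)
  s2 <- vapply(sample_rest_blocks(ses, 20, seed = 7), function(b) b$start_time, 1.0)
  expect_identical(s1, s2)
  ses2 <- make_small_session(duration = 300)
  ses2$seizure_intervals <- matrix(c(10, 280), 1)
  expect_error(sample_rest_blocks(ses2, 1, guard = 120), "admissible rest region")
})

test_that("rest start times are uniform over the admissible region", {
  # cheap session: coarse rate, tiny grid; only start times matter here
  sig <- matrix(rnorm(2 * 400 * 50), ncol = 2)
  ses <- recording_session(sig, fs = 50, grid = grid_layout(1, 2),
                           seizure_intervals = list(c(150, 170)))
  set.seed(42)
  blocks <- sample_rest_blocks(ses, 10000, guard = 20)
  starts <- vapply(blocks, function(b) b$start_time, 1.0)
  # admissible starts: [0, 120] and [190, 390]; map to one contiguous axis
  expect_false(any(starts > 120 & starts < 190))
  u <- ifelse(starts <= 120, starts, starts - 70)
  counts <- table(cut(u, breaks = seq(0, 320, length.out = 17),
                      include.lowest = TRUE))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
})
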