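test_that("trial CSV round-trips exactly and channels keep canonical order", {
  tf <- tempfile(fileext = ".csv")
  write_tiny_trial_csv(tf)
  tr <- load_trial(tf)
  expect_equal(dim(tr$samples), c(3L, 2L))
  expect_equal(tr$fs, 60, tolerance = 1e-9)
  expect_equal(tr$channels, c("hip_L_sagittal", "knee_L_sagittal"))

  # synthetic trial written and reloaded is bitwise identical
  g <- generate_gait(gait_gen_config(n_strides = 5, seed = 1))
  tf2 <- tempfile(fileext = ".csv")
  write_trial(g$trial, tf2)
  tr2 <- load_trial(tf2, fs = 60)
  expect_identical(unname(tr2$samples), unname(g$trial$samples))
  expect_identical(tr2$channels, g$trial$channels)

  # columns given out of canonical order are reordered on load
  df <- utils::read.csv(tf)
  utils::write.csv(df[c("time", "knee_L_sagittal", "hip_L_sagittal")],
                   tf, row.names = FALSE)
  tr3 <- load_trial(tf)
  expect_equal(tr3$channels, c("hip_L_sagittal", "knee_L_sagittal"))
})

test_that("loader rejects missing cells and unknown channel labels", {
  tf <- tempfile(fileext = ".csv")
  write_tiny_trial_csv(tf, values = c(10, NA, 12))
  expect_error(load_trial(tf), "hip_L_sagittal.*row 2")

  df <- data.frame(time = c(0, 1), elbow_L_sagittal = c(1, 2))
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(load_trial(tf), "unknown channel label.*hip")
  expect_error(load_trial(tempfile()), "not found")
})

test_that("contact CSV round-trips through load_contacts", {
  tf <- tempfile(fileext = ".csv")
  fc <- foot_contacts(c(1, 61, 121), foot = "L")
  write_contacts(fc, tf)
  fc2 <- load_contacts(tf, foot = "L")
  expect_identical(fc2$events, fc$events)
  expect_error(load_contacts(tf, foot = "R"), "no contacts")
})

test_that("stride segmentation follows half-open initial-contact windows", {
  tr <- kin_trial(matrix(rnorm(180 * 2), 180, 2), fs = 60,
                  channels = c("hip_L_sagittal", "knee_L_sagittal"))
  cyc <- segment_cycles(tr, foot_contacts(c(1, 61, 121), "L"))
  expect_length(cyc, 2)
  expect_equal(vapply(cyc, nrow, integer(1)), c(60L, 60L))
  expect_equal(cyc[[1]], tr$samples[1:60, ])
  expect_equal(cyc[[2]], tr$samples[61:120, ])

  expect_length(segment_cycles(tr, foot_contacts(c(1, 61), "L")), 1)
  expect_error(segment_cycles(tr, foot_contacts(5, "L")), "cannot segment")

  # cycles shorter than the minimum duration are dropped with a warning
  expect_warning(
    short <- segment_cycles(tr, foot_contacts(c(1, 5, 121), "L")),
    "dropped 1 cycle")
  expect_length(short, 1)
  expect_equal(attr(short, "dropped"), 1L)
})

test_that("segmented cycle lengths match the generator's stride record", {
  g <- generate_gait(gait_gen_config(n_strides = 50,
                                     stride_duration_cv = 0.05, seed = 42))
  cyc <- segment_cycles(g$trial, g$contacts)
  expect_length(cyc, 49)
  expect_equal(vapply(cyc, nrow, integer(1)),
               g$ground_truth$stride_frames[1:49])
})

test_that("time normalization preserves endpoints, lines and waveforms", {
  # identity grid: a 101-frame cycle is returned unchanged
  cyc <- matrix(rnorm(101 * 2), 101, 2)
  cs <- time_normalize(list(cyc))
  expect_equal(cs$cycles[1, , ], cyc, tolerance = 1e-12)

  # linear ramp: interpolation is exact for lines
  ramp <- matrix(seq(0, 10, length.out = 34), ncol = 1)
  csr <- time_normalize(list(ramp))
  expect_equal(csr$cycles[1, , 1], seq(0, 10, length.out = 101),
               tolerance = 1e-12)

  # sine at 60 frames/cycle lands within 1% of the analytic waveform
  ph <- (0:59) / 60
  sn <- matrix(sin(2 * pi * ph), ncol = 1)
  css <- time_normalize(list(sn))
  truth <- sin(2 * pi * seq(0, 59 / 60, length.out = 101))
  expect_lt(max(abs(css$cycles[1, , 1] - truth)), 0.01)

  # endpoints equal the raw cycle endpoints exactly
  g <- generate_gait(gait_gen_config(n_strides = 4, seed = 7))
  cycs <- segment_cycles(g$trial, g$contacts)
  csg <- time_normalize(cycs)
  for (i in seq_along(cycs)) {
    expect_identical(unname(csg$cycles[i, 1, ]), unname(cycs[[i]][1, ]))
    expect_identical(unname(csg$cycles[i, 101, ]),
                     unname(cycs[[i]][nrow(cycs[[i]]), ]))
  }
  expect_error(time_normalize(list(matrix(1, 1, 1))), "fewer than 2")
})

test_that("normalization is idempotent and tensors have the stated shape", {
  g <- generate_gait(gait_gen_config(n_strides = 10, seed = 3))
  cs <- time_normalize(segment_cycles(g$trial, g$contacts))
  expect_equal(dim(cs$cycles), c(9L, 101L, 18L))
  again <- time_normalize(lapply(seq_len(9), function(i) cs$cycles[i, , ]))
  expect_equal(again$cycles, cs$cycles, tolerance = 1e-12)
})

test_that("cycle sets survive the CSV + JSON bundle round trip", {
  g <- generate_gait(gait_gen_config(n_strides = 4, seed = 5))
  cs <- time_normalize(segment_cycles(g$trial, g$contacts))
  stem <- tempfile()
  write_cycle_set(cs, stem)
  cs2 <- read_cycle_set(stem)
  expect_equal(cs2$cycles, cs$cycles, tolerance = 1e-12)
  expect_identical(dimnames(cs2$cycles)[[3]], dimnames(cs$cycles)[[3]])
})
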