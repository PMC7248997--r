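test_that("label propagation covers +/- mo around a report and clips at boundaries", {
  s <- tiny_session(reports = data.frame(t = 300, rpe = 12))
  lab <- propagate_labels(s, mo = 180)
  expect_equal(range(lab$t), c(120, 480))
  expect_equal(nrow(lab), 2 * 180 + 1)
  expect_true(all(lab$label == "non_exerted"))
  expect_true(all(lab$marker_t == 300))
  # boundary clip
  s2 <- tiny_session(reports = data.frame(t = 60, rpe = 12))
  lab2 <- propagate_labels(s2, mo = 180)
  expect_equal(range(lab2$t), c(0, 240))
  # two same-label reports: union, no conflict warning
  s3 <- tiny_session(reports = data.frame(t = c(300, 500), rpe = c(12, 13)))
  expect_no_warning(lab3 <- propagate_labels(s3, mo = 180))
  expect_equal(range(lab3$t), c(120, 680))
  expect_equal(nrow(lab3), 561)
})

test_that("overlapping different-label ranges resolve to the nearest marker", {
  s <- tiny_session(reports = data.frame(t = c(300, 500), rpe = c(15, 16)))
  expect_warning(lab <- propagate_labels(s, mo = 180), "nearest")
  # midpoint 400 ties to the earlier marker
  expect_equal(lab$marker_t[lab$t == 400], 300)
  expect_equal(lab$label[lab$t == 399], "non_exerted")
  expect_equal(lab$label[lab$t == 401], "exerted")
  # each timestamp keeps exactly one label
  expect_equal(anyDuplicated(lab$t), 0)
})

test_that("per-runner z-normalization matches population moments and degenerates safely", {
  s <- session("z", "trained", time = 0:1, heart_rate = c(10, 20),
               cadence = c(160, 160), velocity = c(3, 3),
               reports = data.frame(t = 0, rpe = 10))
  z <- zscore_per_runner(s)
  expect_equal(z$values[, "heart_rate"], c(-1, 1))   # population sd = 5
  expect_equal(z$stats$sd[z$stats$channel == "heart_rate"], 5)
  # constant channels map to zero, not NaN
  expect_equal(z$values[, "cadence"], c(0, 0))
  # idempotence: re-standardizing standardized data is a no-op
  s2 <- tiny_session()
  z1 <- zscore_per_runner(s2)
  s3 <- s2; s3$heart_rate <- z1$values[, 1] * 10 + 100  # affine change
  z2 <- zscore_per_runner(s3)
  expect_equal(z2$values[, 1], z1$values[, 1], tolerance = 1e-12)
})

test_that("window extraction obeys the 2*mo + 2 - L counting law", {
  s <- tiny_session(reports = data.frame(t = 300, rpe = 12))
  ws <- extract_windows(s, augmentation_params(mo = 180, L = 60))
  expect_equal(nrow(ws$meta), 302)
  expect_equal(dim(ws$values), c(302, 60, 3))
  # window exactly as long as the labeled range -> a single window
  ws1 <- extract_windows(s, augmentation_params(mo = 180, L = 361))
  expect_equal(nrow(ws1$meta), 1)
  # property: random interior mo, L
  set.seed(42)
  for (i in 1:20) {
    mo <- sample(30:250, 1)
    L <- sample(10:(2 * mo), 1)
    wsi <- extract_windows(s, augmentation_params(mo = mo, L = L))
    expect_equal(nrow(wsi$meta), 2 * mo + 2 - L)
    # no window leaves the labeled range or the session
    expect_true(all(wsi$meta$window_start >= 300 - mo))
    expect_true(all(wsi$meta$window_start + L - 1 <= 300 + mo))
  }
})

test_that("windows never cross session boundaries nor mix labels", {
  co <- simulate_cohort(cohort_config(seed = 4))
  s <- co[[7]]  # an untrained runner, dense markers
  ws <- suppressWarnings(extract_windows(s, augmentation_params(), stride = 10))
  L <- 60
  expect_true(all(ws$meta$window_start >= min(s$time)))
  expect_true(all(ws$meta$window_start + L - 1 <= max(s$time)))
  lab <- suppressWarnings(propagate_labels(s, 180))
  lab_of <- stats::setNames(lab$label, lab$t)
  for (i in seq_len(min(25, nrow(ws$meta)))) {
    span <- as.character(ws$meta$window_start[i] + 0:(L - 1))
    marker_label <- unique(lab$label[lab$marker_t == ws$meta$marker_t[i]])
    expect_true(all(lab_of[span] == ws$meta$label[i], na.rm = FALSE))
    expect_equal(ws$meta$label[i], marker_label)
  }
  # sessions shorter than L warn and yield nothing
  short <- session("s", "trained", time = 0:10, heart_rate = rep(150, 11),
                   cadence = rep(160, 11), velocity = rep(3, 11),
                   reports = data.frame(t = 5, rpe = 12))
  expect_warning(empty <- extract_windows(short, augmentation_params(L = 60)),
                 "shorter")
  expect_equal(nrow(empty$meta), 0)
})

test_that("z-normalization makes DTW invariant to affine channel rescaling", {
  s <- tiny_session(reports = data.frame(t = 300, rpe = 12))
  ws <- extract_windows(s, augmentation_params(mo = 60, L = 30))
  s2 <- s
  s2$heart_rate <- 2.5 * s$heart_rate + 7   # scale + shift absorbed by stats
  ws2 <- extract_windows(s2, augmentation_params(mo = 60, L = 30))
  d1 <- dtw_distance(ws$values[1, , ], ws$values[10, , ])
  d2 <- dtw_distance(ws2$values[1, , ], ws2$values[10, , ])
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("window stride thins the window set deterministically", {
  s <- tiny_session(reports = data.frame(t = 300, rpe = 12))
  full <- extract_windows(s, augmentation_params())
  thin <- extract_windows(s, augmentation_params(), stride = 50)
  expect_equal(nrow(thin$meta), ceiling(302 / 50))
  expect_true(all(thin$meta$window_start %in% full$meta$window_start))
  expect_identical(thin, extract_windows(s, augmentation_params(), stride = 50))
})
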