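# Velocity heatmaps, event extraction, event summaries.

fake_disp <- function(v, missing = rep(FALSE, length(v))) {
  data.frame(sector = seq_along(v), dx_um = v, dy_um = 0, nx = 1, ny = 0,
             v_normal_um = v, method = "ray", missing = missing)
}

test_that("static boundary gives an identically zero heatmap", {
  hm <- build_velocity_heatmap(replicate(5, fake_disp(rep(0, 8)),
                                         simplify = FALSE), 5)
  expect_true(all(hm$raw == 0))
  expect_true(all(hm$norm == 0))
})

test_that("uniform step at the dataset maximum normalizes to V = 1", {
  hm <- build_velocity_heatmap(replicate(4, fake_disp(rep(0.5, 6)),
                                         simplify = FALSE), 5)
  expect_true(all(hm$norm == 1))
  # sign-preserving, odd normalization
  hm2 <- build_velocity_heatmap(replicate(4, fake_disp(rep(-0.5, 6)),
                                          simplify = FALSE), 5)
  expect_identical(hm2$norm, -hm$norm)
})

test_that("missing sectors are masked; an all-missing column errors", {
  d <- list(fake_disp(c(0.1, 0.2, 0, 0), missing = c(FALSE, TRUE, FALSE, FALSE)))
  hm <- build_velocity_heatmap(d, 5)
  expect_true(hm$missing[2, 1])
  expect_error(build_velocity_heatmap(
    list(fake_disp(rep(0.1, 4), missing = rep(TRUE, 4)))), "no tracked")
})

test_that("axis-aligned block is one protrusion event, duration from columns", {
  m <- matrix(0, 12, 20)
  m[3:6, 10:13] <- 1
  ev <- extract_events(fake_heatmap(m, frame_interval_s = 5), 0.3, 6)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "protrusion")
  expect_equal(ev$duration_s, 20)
  expect_equal(ev$angle_deg, 0)
  expect_false(ev$is_traveling_wave)
})

test_that("unit-slope diagonal streak has angle 45 and is a traveling wave", {
  m <- matrix(0, 14, 14)
  for (t in 3:10) m[t, t] <- -1      # retraction streak
  ev <- extract_events(fake_heatmap(m), 0.3, 6)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "retraction")
  expect_equal(ev$angle_deg, 45, tolerance = 1e-9)
  expect_true(ev$is_traveling_wave)
})

test_that("events wrap across the sector seam", {
  m <- matrix(0, 10, 12)
  m[c(1, 2, 9, 10), 4:8] <- 1       # block spanning rows 9,10,1,2
  ev <- extract_events(fake_heatmap(m), 0.3, 6)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$area_cells, 20L)
  # unwrapped moments: still an axis-aligned rectangle
  expect_equal(ev$angle_deg, 0, tolerance = 1e-9)
})

test_that("sign symmetry: negating the map swaps polarity only", {
  set.seed(5)
  m <- matrix(0, 12, 18)
  m[2:4, 3:9] <- 0.8
  m[8:10, 11:16] <- -0.6
  e1 <- extract_events(fake_heatmap(m), 0.3, 6)
  e2 <- extract_events(fake_heatmap(-m), 0.3, 6)
  expect_setequal(e1$duration_s, e2$duration_s)
  expect_setequal(e1$angle_deg, e2$angle_deg)
  expect_setequal(e1$polarity,
                  c(protrusion = "retraction", retraction = "protrusion")[e2$polarity])
})

test_that("raising the threshold never increases the count of separated
          unimodal events", {
  # (overlapping events merged at a low threshold can split as it rises;
  # monotonicity is guaranteed for non-merging events, see vignette)
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(0, 16, 40)
    n_ev <- sample(2:4, 1)
    rows <- sample(seq(2, 14, by = 4), n_ev)
    cols <- sample(seq(4, 36, by = 10), n_ev)
    for (i in seq_len(n_ev)) {
      peak <- runif(1, 0.5, 1) * sample(c(-1, 1), 1)
      for (dr in -1:1) for (dc in -3:3)
        m[rows[i] + dr, cols[i] + dc] <-
          peak * exp(-(dr^2 / 2 + dc^2 / 8))
    }
    hm <- fake_heatmap(m)
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
      nrow(extract_events(hm, th, 1)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("min_area drops small components", {
  m <- matrix(0, 10, 10)
  m[2:3, 2:3] <- 1      # 4 cells
  m[6:8, 5:9] <- 1      # 15 cells
  expect_equal(nrow(extract_events(fake_heatmap(m), 0.3, 6)), 1L)
  expect_equal(nrow(extract_events(fake_heatmap(m), 0.3, 1)), 2L)
})

test_that("non-finite values outside the missing mask are an error", {
  m <- matrix(0, 8, 8); m[3, 3] <- NaN
  expect_error(extract_events(fake_heatmap(m)), "non-finite")
})

test_that("summaries: rate arithmetic, strict >10 deg wave rule, empty case", {
  ev <- data.frame(duration_s = c(20, 30, 40), angle_deg = c(5, 15, 25),
                   is_traveling_wave = c(FALSE, TRUE, TRUE))
  s <- summarize_events(ev, movie_duration_s = 300)
  expect_equal(s$events_per_minute, 0.6)
  expect_equal(s$percent_traveling_waves, 200 / 3, tolerance = 1e-9)
  # angle exactly 10 is NOT a wave
  s10 <- summarize_events(data.frame(duration_s = 10, angle_deg = 10,
                                     is_traveling_wave = FALSE), 60)
  expect_equal(s10$percent_traveling_waves, 0)
  s0 <- summarize_events(ev[0, ], 300)
  expect_equal(s0$n_events, 0L)
  expect_equal(s0$events_per_minute, 0)
  expect_true(is.na(s0$mean_duration_s))
})

test_that("planted pulse is recovered through the full pixel pipeline", {
  fx <- smoke_analysis()
  ev <- fx$res$velocity_events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "protrusion")
  expect_equal(ev$duration_s, fx$sim$truth$events$duration_s,
               tolerance = fx$cfg$frame_interval_s / ev$duration_s)
  expect_lt(abs(ev$angle_deg - fx$sim$truth$events$angle_deg), 5)
})
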