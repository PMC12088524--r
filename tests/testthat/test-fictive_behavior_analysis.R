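# Event classification and summary statistics on constructed fixtures.

test_that("peak detection finds constructed bumps with onsets and offsets", {
  tm <- seq(0, 30000, by = 10)
  centres <- c(3000, 8000, 13000, 19000, 26000)
  v <- rowSums(sapply(centres, function(cc) bump(tm, cc, 500)))
  pk <- detect_peaks(v, tm, min_prominence = 0.3, min_separation = 500)
  expect_equal(nrow(pk), 5)
  expect_true(all(abs(pk$time - centres) <= 10))
  expect_true(all(pk$onset < pk$time & pk$time < pk$offset))
  # onset sits at the 20% rising crossing of a known shape:
  # (1 + cos(pi x))/2 = 0.2  =>  |x| = acos(-0.6)/pi
  x20 <- acos(-0.6) / pi * 500
  expect_equal(pk$time - pk$onset, rep(x20, 5), tolerance = 0.05)
  # flat trace -> no peaks; empty trace -> empty table
  expect_equal(nrow(detect_peaks(rep(1, 100), 1:100)), 0)
  expect_equal(nrow(detect_peaks(numeric(), numeric())), 0)
})

test_that("bumps closer than min_separation merge into the larger peak", {
  tm <- seq(0, 10000, by = 10)
  v <- bump(tm, 4000, 300, 0.7) + bump(tm, 4800, 300, 1)
  pk <- detect_peaks(v, tm, min_separation = 1500)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time, 4800, tolerance = 20)
})

test_that("progressive posterior-to-anterior peaks classify as a forwards wave", {
  # near-synchronous posterior onset (A8-A6), then progressive delay
  times <- list(A8 = 0, A7 = 0, A6 = 0, A5 = 100, A4 = 200, A3 = 400,
                A2 = 600, A1 = 800) |> lapply(function(x) x + 2000)
  tr <- bump_traces(times)
  ev <- classify_events(peak_table(tr))
  expect_equal(ev$kind, "forwards_wave")
  # strictly decreasing times from anterior seed -> backwards wave
  times_b <- lapply(setNames(as.list(seq(0, 2100, by = 300)),
                             paste0("A", 1:8)), function(x) x + 2000)
  ev_b <- classify_events(peak_table(bump_traces(times_b)))
  expect_equal(ev_b$kind, "backwards_wave")
})

test_that("posterior-confined synchronous peaks are a burst, not a wave", {
  tr <- bump_traces(list(A8 = 2000, A7 = 2100, A6 = 2050,
                         A5 = 30000, A4 = 30000, A3 = 30000, A2 = 30000,
                         A1 = 30000))
  # remove the dummy co-activation far away and keep only A8-A6 peaks
  pk <- peak_table(tr)
  pk <- pk[pk$time < 10000, ]
  ev <- classify_events(pk, channels = paste0("A", 8:1))
  expect_equal(ev$kind, "posterior_burst")
  # anterior mirror
  pk2 <- pk; pk2$segment <- c(A8 = "A1", A7 = "A2", A6 = "A2")[pk$segment]
  pk2 <- pk2[!duplicated(paste(pk2$segment, pk2$time)), ]
  ev2 <- classify_events(pk2, channels = paste0("A", 8:1))
  expect_equal(ev2$kind, "anterior_burst")
  # whole-chain synchrony is its own category
  tr3 <- bump_traces(setNames(as.list(rep(2000, 8)), paste0("A", 1:8)))
  ev3 <- classify_events(peak_table(tr3))
  expect_equal(ev3$kind, "synchronous_network_event")
  expect_equal(nrow(classify_events(peak_table(tr3[0, ]))), 0)
})

test_that("waves require the full chain of channels", {
  # peaks only in A8-A5: progressive but partial -> not a wave
  times <- list(A8 = 2000, A7 = 2000, A6 = 2050, A5 = 2600)
  tr <- bump_traces(times)
  pk <- peak_table(tr)
  ev <- classify_events(pk, channels = paste0("A", 8:1))
  expect_false(any(ev$kind %in% c("forwards_wave", "backwards_wave")))
  # the same peaks against the matching truncated chain are a wave
  ev2 <- classify_events(pk, channels = paste0("A", 8:5))
  expect_equal(ev2$kind, "forwards_wave")
  expect_error(classify_waves(pk, channels = paste0("A", 8:1)), "A4")
})

test_that("classification is invariant to channel ordering in the table", {
  set.seed(21)
  times <- list(A8 = c(2000, 9000), A7 = c(2050, 9050), A6 = c(2100, 9100),
                A5 = c(2400, 9500), A4 = c(2800, 10000))
  tr <- bump_traces(times)
  pk <- peak_table(tr)
  ev1 <- classify_events(pk, channels = paste0("A", 8:4))
  ev2 <- classify_events(pk[sample(nrow(pk)), ], channels = paste0("A", 8:4))
  expect_equal(ev1$kind, ev2$kind)
  expect_equal(ev1$t_first, ev2$t_first)
})

test_that("classifier agrees with the exhaustive rule-checking oracle", {
  channels <- paste0("A", 8:5)
  set.seed(33)
  n_checked <- 0
  for (rep in 1:40) {
    pk <- random_peak_table(n_peaks = sample(4:10, 1), channels = channels)
    ev <- classify_events(pk, channels = channels)
    waves <- ev[ev$kind %in% c("forwards_wave", "backwards_wave"), ]
    orc <- oracle_waves(pk, channels)
    if (is.null(orc)) {
      expect_equal(nrow(waves), 0)
    } else {
      expect_equal(nrow(waves), nrow(orc))
      expect_equal(waves$kind, orc$kind)
      n_checked <- n_checked + nrow(orc)
    }
  }
  expect_gt(n_checked, 5)   # the generator must exercise real waves
})

test_that("every peak belongs to at most one event", {
  set.seed(12)
  channels <- paste0("A", 8:5)
  for (rep in 1:10) {
    pk <- random_peak_table(n_peaks = 12, channels = channels)
    ev <- classify_events(pk, channels = channels)
    rows <- unlist(attr(ev, "peak_rows"))
    expect_lte(max(table(rows)), 1)
  }
})

test_that("head sweeps score suprathreshold left-right excursions", {
  tm <- seq(0, 60000, by = 10)
  right <- bump(tm, 10000, 1000) + bump(tm, 30000, 1000)
  left <- right + bump(tm, 20000, 800) # one left-only event
  hs <- detect_head_sweeps(left, right, tm, threshold = 0.3)
  expect_equal(hs$kind, "head_sweep_L")
  expect_equal(hs$t_first, 20000, tolerance = 20)
  # identical traces -> nothing
  expect_equal(nrow(detect_head_sweeps(right, right, tm)), 0)
  # alternating excursions -> alternating kinds
  l2 <- bump(tm, 10000, 800) + bump(tm, 40000, 800)
  r2 <- bump(tm, 25000, 800) + bump(tm, 55000, 800)
  hs2 <- detect_head_sweeps(l2, r2, tm, threshold = 0.3)
  expect_equal(hs2$kind, c("head_sweep_L", "head_sweep_R",
                           "head_sweep_L", "head_sweep_R"))
  expect_error(detect_head_sweeps(l2, r2[-1], tm[-1]), "grid")
})

test_that("wave metrics implement the 20%-rise / 80%-fall rule", {
  # two identical forwards waves 10 s apart with analytically placed
  # crossings: raised-cosine bumps, onset 20% and offset 20%-of-height
  half <- 500
  x20 <- acos(-0.6) / pi * half
  tr <- bump_traces(list(A8 = c(3000, 13000), A7 = c(3000, 13000),
                         A6 = c(3050, 13050), A5 = c(3600, 13600),
                         A4 = c(4200, 14200)), half_width = half)
  pk <- peak_table(tr)
  ev <- classify_events(pk, channels = paste0("A", 8:4))
  expect_equal(ev$kind, rep("forwards_wave", 2))
  wm <- wave_metrics(ev, pk, channels = paste0("A", 8:4))
  # duration: from A8 rise-20% (t0 - x20) to A4 fall-80% (t0+1200 + x20)
  expect_equal(wm$duration, rep(1200 + 2 * x20, 2), tolerance = 0.03)
  expect_equal(wm$interval, c(NA, 10000), tolerance = 1e-6)
  expect_equal(wm$frequency, c(NA, 0.1), tolerance = 1e-6)
})

test_that("overlap annotation distinguishes same and opposite programs", {
  ev <- data.frame(
    kind = c("forwards_wave", "forwards_wave", "backwards_wave",
             "forwards_wave"),
    start = c(0, 1000, 5000, 9000),
    end = c(2000, 3000, 6000, 10000))
  ov <- detect_overlap(ev)
  expect_true(all(ov$events$same_overlap[1:2]))
  expect_false(any(ov$events$opposite_overlap))
  expect_false(ov$events$same_overlap[4])
  ev2 <- data.frame(kind = c("forwards_wave", "backwards_wave"),
                    start = c(0, 1500), end = c(3000, 4000))
  expect_true(all(detect_overlap(ev2)$events$opposite_overlap))
  # fully quiescent separation -> no overlap at all
  ev3 <- data.frame(kind = c("forwards_wave", "forwards_wave"),
                    start = c(0, 5000), end = c(2000, 7000))
  expect_false(any(unlist(detect_overlap(ev3)$events[c("same_overlap",
                                                       "opposite_overlap")])))
})

test_that("transition matrices count ordered kind pairs", {
  m <- transition_matrix(c("F", "B", "F", "B"))
  expect_equal(m["F", "B"], 1)
  expect_equal(m["B", "F"], 1)
  m2 <- transition_matrix(c("F", "F", "F", "B"))
  expect_equal(m2["F", "F"], 2 / 3)
  expect_equal(m2["F", "B"], 1 / 3)
  set.seed(4)
  for (i in 1:5) {
    seq_k <- sample(letters[1:4], 30, replace = TRUE)
    m3 <- transition_matrix(seq_k)
    rs <- rowSums(m3)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }
  expect_equal(dim(transition_matrix("F")), c(0, 0))
})

test_that("asymmetry density integrates to one and tracks offsets", {
  set.seed(9)
  l <- rnorm(5000); r <- rnorm(5000)
  d0 <- asymmetry_kde(l, l)
  expect_lt(abs(d0$x[which.max(d0$y)]), 0.2)
  dc <- suppressWarnings(asymmetry_kde(l + 3, l))  # constant difference
  expect_equal(dc$x[which.max(dc$y)], 3, tolerance = 0.3)
  expect_equal(sum(dc$y) * mean(diff(dc$x)), 1, tolerance = 0.05)
  # bimodal mixture: modes within one bandwidth of component means
  diffs <- c(rnorm(4000, -4, 0.3), rnorm(4000, 4, 0.3))
  dm <- asymmetry_kde(diffs, rep(0, length(diffs)), bandwidth_factor = 1)
  peaks <- dm$x[which(diff(sign(diff(dm$y))) == -2) + 1]
  main <- peaks[dm$y[match(peaks, dm$x)] > 0.1 * max(dm$y)]
  expect_equal(sort(main), c(-4, 4), tolerance = dm$bw / 4 + 0.2)
})

test_that("linear fits report exact and analytic R-squared", {
  x <- 1:10
  expect_equal(linear_fit_r2(x, 2 * x + 1)$r_squared, 1)
  set.seed(2)
  y <- rnorm(500)
  expect_lt(linear_fit_r2(rnorm(500), y)$r_squared, 0.05)
  # known residual variance fixture
  e <- c(-1, 1, -1, 1, -1, 1)
  xx <- 1:6; yy <- 3 * xx + e
  f <- linear_fit_r2(xx, yy)
  ss_res <- sum(stats::residuals(stats::lm(yy ~ xx))^2)
  expect_equal(f$r_squared, 1 - ss_res / sum((yy - mean(yy))^2))
  expect_error(linear_fit_r2(rep(1, 5), 1:5), "variance")
  expect_error(linear_fit_r2(1:2, 1:2), "3")
})
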