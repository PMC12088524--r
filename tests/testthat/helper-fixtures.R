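# Shared fixtures and independent oracles used across the suite.

# smooth synthetic burst: raised-cosine bump of given half-width
bump <- function(time, centre, half_width, height = 1) {
  x <- (time - centre) / half_width
  ifelse(abs(x) < 1, height * (1 + cos(pi * x)) / 2, 0)
}

# multichannel trace table with one bump per (channel, time) pair
bump_traces <- function(times_by_channel, dt = 10, t_end = NULL,
                        half_width = 400, baseline = 0) {
  if (is.null(t_end)) t_end <- max(unlist(times_by_channel)) + 3 * half_width
  tm <- seq(0, t_end, by = dt)
  out <- data.frame(time = tm)
  for (ch in names(times_by_channel)) {
    v <- rep(baseline, length(tm))
    for (tc in times_by_channel[[ch]]) {
      v <- v + bump(tm, tc, half_width)
    }
    out[[ch]] <- v
  }
  out
}

# Exhaustive rule-checking wave classifier for tiny peak tables: tests every
# combination of one peak per channel as a candidate wave window and accepts
# non-conflicting candidates in order of initiating-peak time. Independent
# of the package's seed-and-trace implementation.
oracle_waves <- function(peaks, channels, sync_window = 500,
                         max_interseg_delay = 2000, tie_tol = 10) {
  post <- channels[seq_len(min(3, length(channels)))]
  ant <- channels[channels %in% c("T1", "T2", "T3", "A1", "A2")]
  if (!length(ant)) {
    ant <- channels[seq.int(max(1, length(channels) - 1), length(channels))]
  }
  by_ch <- lapply(channels, function(ch) which(peaks$segment == ch))
  names(by_ch) <- channels
  if (any(vapply(by_ch, length, 1L) == 0)) return(NULL)
  combos <- expand.grid(by_ch, KEEP.OUT.ATTRS = FALSE)
  ok_dir <- function(rows, scan, group) {
    tt <- peaks$time[rows[match(scan, channels)]]  # in scan order
    t_run <- tt[1]
    for (j in 2:length(tt)) {
      tol <- if (scan[j] %in% group) sync_window else tie_tol
      if (tt[j] < t_run - tol || tt[j] > t_run + max_interseg_delay) {
        return(FALSE)
      }
      t_run <- max(t_run, tt[j])
    }
    diff(range(tt)) > sync_window
  }
  # for each (direction, seed peak) keep the lexicographically earliest
  # valid assignment in scan order, matching the canonical tie-break
  collect <- function(kind, scan, group) {
    seed_ch <- scan[1]
    out <- list()
    valid <- combos[apply(combos, 1, function(rows)
      ok_dir(as.integer(rows), scan, group)), , drop = FALSE]
    if (!nrow(valid)) return(out)
    seed_col <- match(seed_ch, channels)
    for (seed in unique(valid[[seed_col]])) {
      v <- valid[valid[[seed_col]] == seed, , drop = FALSE]
      tmat <- sapply(scan, function(ch)
        peaks$time[v[[match(ch, channels)]]])
      tmat <- matrix(tmat, nrow = nrow(v))
      best <- do.call(order, as.data.frame(tmat))[1]
      out[[length(out) + 1L]] <- list(
        kind = kind, rows = sort(as.integer(v[best, ])),
        t0 = peaks$time[seed])
    }
    out
  }
  cands <- c(collect("forwards_wave", channels, post),
             collect("backwards_wave", rev(channels), ant))
  if (!length(cands)) return(NULL)
  used <- rep(FALSE, nrow(peaks))
  out <- NULL
  for (ci in order(vapply(cands, `[[`, 0, "t0"))) {
    rows <- cands[[ci]]$rows
    if (any(used[rows])) next
    used[rows] <- TRUE
    out <- rbind(out, data.frame(kind = cands[[ci]]$kind,
                                 t_first = min(peaks$time[rows]),
                                 t_last = max(peaks$time[rows])))
  }
  out[order(out$t_first), , drop = FALSE]
}

# random peak table over a small chain for property tests; implants zero,
# one or two jittered progressive waves among background peaks so that the
# generator exercises real wave windows
random_peak_table <- function(n_peaks, channels, t_max = 20000,
                              n_waves = sample(0:2, 1)) {
  ch <- sample(channels, n_peaks, replace = TRUE)
  tt <- round(stats::runif(n_peaks, 0, t_max))
  if (n_waves > 0) {
    for (w in seq_len(n_waves)) {
      t0 <- stats::runif(1, 0, t_max - 4000)
      delays <- cumsum(c(0, stats::runif(length(channels) - 1, 0, 900)))
      ch <- c(ch, channels)
      tt <- c(tt, round(t0 + delays))
    }
  }
  data.frame(channel = ch, segment = ch, side = NA, time = tt,
             amplitude = 1, onset = tt - 300, offset = tt + 300)
}

# default HO blueprint used repeatedly
ho_bp <- function() hemisegmental_oscillator()
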