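# Fictive-behaviour analysis: burst/peak detection on multichannel traces
# (model voltages or imaging dF/F), classification of metachronal waves,
# bursts and head sweeps, wave metrics, overlap annotation, transition
# matrices, bilateral-asymmetry density profiles, and simple fits.

# canonical posterior -> anterior ordering of segments
.SEGMENT_ORDER <- c(paste0("A", 8:1), paste0("T", 3:1))

# rank of a segment along the chain (posterior = low)
.seg_rank <- function(segment) match(segment, .SEGMENT_ORDER)

#' Detect activity peaks in a single trace
#'
#' Burst-style peak detection for slow, plateau-like activity: excursions
#' above a prominence threshold (a fraction of the channel's dynamic range
#' above baseline) are segmented; each excursion contributes one peak (its
#' maximum), and excursions separated by less than `min_separation` are
#' merged. Onset and offset are located where the signal crosses a
#' configurable fraction of the peak height above baseline on the rising and
#' falling phases.
#'
#' @param trace numeric vector, uniformly sampled.
#' @param time sample times, ms (same length as `trace`).
#' @param min_prominence threshold as a fraction of the channel range above
#'   baseline.
#' @param min_separation minimum separation between distinct peaks, ms.
#' @param onset_frac rising-phase crossing fraction of peak height
#'   (default 0.2, i.e. 20% of the rise).
#' @param offset_frac falling-phase fraction of the *fall* completed at the
#'   offset point (default 0.8: the signal has dropped to 20% of peak
#'   height).
#' @param baseline reference level; default the 10% quantile of the trace.
#' @param reference_range dynamic-range reference used for thresholding in
#'   place of this channel's own range (see [peak_table()]'s shared scale).
#' @return data.frame with columns `time`, `amplitude` (peak height above
#'   baseline), `onset`, `offset`; zero rows for a flat or empty trace.
#' @export
detect_peaks <- function(trace, time, min_prominence = 0.3,
                         min_separation = 500, onset_frac = 0.2,
                         offset_frac = 0.8,
                         baseline = stats::quantile(trace, 0.1, names = FALSE),
                         reference_range = NULL) {
  empty <- data.frame(time = numeric(), amplitude = numeric(),
                      onset = numeric(), offset = numeric())
  if (!length(trace)) return(empty)
  stopifnot(length(trace) == length(time))
  rng <- if (is.null(reference_range)) max(trace) - baseline else
    reference_range
  if (!is.finite(rng) || rng <= 0) return(empty)
  th <- baseline + min_prominence * rng
  above <- trace > th
  if (!any(above)) return(empty)
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  # merge excursions separated by less than min_separation
  if (length(starts) > 1) {
    keep_start <- c(TRUE, time[starts[-1]] - time[ends[-length(ends)]] >=
                      min_separation)
    grp <- cumsum(keep_start)
    starts <- starts[keep_start]
    ends <- vapply(split(ends, grp), max, numeric(1))
  }
  out <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(trace[idx])]
    h <- trace[pk] - baseline
    on_lvl <- baseline + onset_frac * h
    off_lvl <- baseline + (1 - offset_frac) * h
    # walk out from the peak to the crossing levels
    j <- pk; while (j > 1 && trace[j - 1] > on_lvl) j <- j - 1
    k <- pk; while (k < length(trace) && trace[k + 1] > off_lvl) k <- k + 1
    data.frame(time = time[pk], amplitude = h, onset = time[j],
               offset = time[k])
  })
  do.call(rbind, out)
}

#' Build a peak table from a multichannel trace data.frame
#'
#' @param traces data.frame with a `time` column and one column per channel;
#'   channel names encode segment (and optionally side) as "A4" or "A4.L".
#' @param shared_scale logical: threshold every channel against the largest
#'   channel's dynamic range instead of its own (recommended for model
#'   voltages, where a silent channel's numerical ripple must not count as
#'   peaks).
#' @param ... passed to [detect_peaks()].
#' @return data.frame with columns `channel`, `segment`, `side`, `time`,
#'   `amplitude`, `onset`, `offset`, time-ordered within channel.
#' @export
peak_table <- function(traces, shared_scale = TRUE, ...) {
  chans <- setdiff(names(traces), "time")
  ref <- if (shared_scale && length(chans) && nrow(traces)) {
    max(vapply(chans, function(ch) {
      v <- traces[[ch]]
      max(v) - stats::quantile(v, 0.1, names = FALSE)
    }, numeric(1)))
  } else NULL
  out <- lapply(chans, function(ch) {
    pk <- detect_peaks(traces[[ch]], traces$time, reference_range = ref, ...)
    if (!nrow(pk)) return(NULL)
    parts <- strsplit(ch, ".", fixed = TRUE)[[1]]
    cbind(data.frame(channel = ch, segment = parts[1],
                     side = if (length(parts) > 1) parts[2] else NA_character_),
          pk)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(channel = character(), segment = character(),
                      side = character(), time = numeric(),
                      amplitude = numeric(), onset = numeric(),
                      offset = numeric())
  }
  out
}

# initiating ("near-synchronous") groups: the three most posterior chain
# segments for forwards activity, and the anterior segments (T3..A1 region)
# for backwards activity.
.post_group <- function(chain) chain[seq_len(min(3, length(chain)))]
.ant_group <- function(chain) {
  g <- chain[chain %in% c("T1", "T2", "T3", "A1", "A2")]
  if (length(g)) g else chain[seq.int(max(1, length(chain) - 1), length(chain))]
}

# Trace one candidate wave from a seed peak: walk the scan order (posterior
# -> anterior for forwards, reversed for backwards), at each channel
# accepting a peak no earlier than the running time minus the applicable
# tolerance (sync_window inside the initiating group, tie_tol elsewhere) and
# no later than the running time plus max_interseg_delay. Depth-first with
# backtracking, preferring earlier peaks, so the result is the
# lexicographically earliest valid assignment whose peak-time span exceeds
# sync_window (a fully synchronous cluster is not a wave). Returns peak row
# indices or NULL.
.trace_wave <- function(pk, scan, group, seed_row, used, sync_window,
                        max_interseg_delay, tie_tol) {
  t_seed <- pk$time[seed_row]
  recurse <- function(depth, rows, t_run, t_min, t_max) {
    if (depth > length(scan)) {
      if (max(t_max, t_run) - min(t_min, t_run) > sync_window) return(rows)
      return(NULL)
    }
    ch <- scan[depth]
    tol <- if (ch %in% group) sync_window else tie_tol
    cand <- which(pk$segment == ch & !used &
                    pk$time >= t_run - tol &
                    pk$time <= t_run + max_interseg_delay)
    for (pick in cand[order(pk$time[cand])]) {
      tp <- pk$time[pick]
      res <- recurse(depth + 1, c(rows, pick), max(t_run, tp),
                     min(t_min, tp), max(t_max, tp))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recurse(2, seed_row, t_seed, t_seed, t_seed)
}

.mk_event <- function(pk, rows, kind) {
  data.frame(kind = kind, start = min(pk$onset[rows]),
             end = max(pk$offset[rows]), t_first = min(pk$time[rows]),
             t_last = max(pk$time[rows]), n_channels = length(rows))
}

#' Classify metachronal waves and bursts from a peak table
#'
#' Peaks are clustered in time across channels; a cluster covering the whole
#' chain with non-decreasing peak times from posterior to anterior (the
#' posterior initiating group may co-peak within `sync_window`) is a
#' forwards wave, the mirror order a backwards wave. Near-synchronous
#' clusters confined to the posterior (anterior) initiating group are
#' posterior (anterior) bursts; near-synchronous activity across the whole
#' chain is flagged as a synchronous network event. Waves and bursts are
#' mutually exclusive labels for the same peaks, and the result does not
#' depend on channel ordering in the input.
#'
#' @param peaks a [peak_table()] data.frame (one side, or side-averaged).
#' @param channels segments forming the chain, posterior first; default all
#'   segments present, in canonical order (A8 .. T1).
#' @param sync_window near-synchrony window, ms.
#' @param max_interseg_delay maximum consecutive intersegmental peak delay
#'   within a wave, ms.
#' @param tie_tol tolerance for equal peak times outside the initiating
#'   groups, ms.
#' @return data.frame of events: `kind`, `start`, `end`, `t_first`,
#'   `t_last`, `n_channels`.
#' @export
classify_events <- function(peaks, channels = NULL, sync_window = 500,
                            max_interseg_delay = 2000, tie_tol = 10) {
  if (!nrow(peaks)) {
    return(data.frame(kind = character(), start = numeric(), end = numeric(),
                      t_first = numeric(), t_last = numeric(),
                      n_channels = integer()))
  }
  if (is.null(channels)) {
    channels <- .SEGMENT_ORDER[.SEGMENT_ORDER %in% unique(peaks$segment)]
  }
  pk <- peaks[peaks$segment %in% channels, , drop = FALSE]
  if (!nrow(pk)) {
    return(data.frame(kind = character(), start = numeric(), end = numeric(),
                      t_first = numeric(), t_last = numeric(),
                      n_channels = integer()))
  }
  pk <- pk[order(pk$time), , drop = FALSE]
  rownames(pk) <- NULL
  n <- nrow(pk)
  used <- rep(FALSE, n)
  events <- list()
  ev_rows <- list()
  full <- length(channels)

  # candidate waves from both directions, accepted greedily in seed-time
  # order so each peak belongs to at most one event
  scans <- list(forwards_wave = list(scan = channels,
                                     group = .post_group(channels)),
                backwards_wave = list(scan = rev(channels),
                                      group = .ant_group(channels)))
  cands <- list()
  for (kind in names(scans)) {
    sc <- scans[[kind]]
    if (full < 2) break
    for (seed in which(pk$segment == sc$scan[1])) {
      rows <- .trace_wave(pk, sc$scan, sc$group, seed, used = rep(FALSE, n),
                          sync_window = sync_window,
                          max_interseg_delay = max_interseg_delay,
                          tie_tol = tie_tol)
      if (!is.null(rows) && diff(range(pk$time[rows])) > sync_window) {
        cands[[length(cands) + 1L]] <-
          list(kind = kind, rows = rows, t0 = pk$time[seed])
      }
    }
  }
  if (length(cands)) {
    for (ci in order(vapply(cands, `[[`, 0, "t0"))) {
      rows <- cands[[ci]]$rows
      if (any(used[rows])) next
      used[rows] <- TRUE
      events[[length(events) + 1L]] <- .mk_event(pk, rows, cands[[ci]]$kind)
      ev_rows[[length(events)]] <- rows
    }
  }

  # remaining peaks: near-synchronous clusters -> bursts / synchronous events
  rest <- which(!used)
  if (length(rest)) {
    grp <- cumsum(c(1, diff(pk$time[rest]) > sync_window))
    for (g in split(rest, grp)) {
      segs <- unique(pk$segment[g])
      span <- diff(range(pk$time[g]))
      kind <- if (span > sync_window || length(segs) < 2) "unclassified"
        else if (length(segs) == full) "synchronous_network_event"
        else if (all(segs %in% .post_group(channels))) "posterior_burst"
        else if (all(segs %in% .ant_group(channels))) "anterior_burst"
        else "unclassified"
      events[[length(events) + 1L]] <- .mk_event(pk, g, kind)
      ev_rows[[length(events)]] <- g
    }
  }
  out <- do.call(rbind, events)
  ord <- order(out$start, out$t_first)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peak_rows") <- ev_rows[ord]
  attr(out, "peaks_sorted") <- pk
  out
}

#' Classify waves only
#'
#' Convenience wrapper around [classify_events()] returning wave events.
#'
#' @inheritParams classify_events
#' @return the wave rows of [classify_events()].
#' @export
classify_waves <- function(peaks, channels = NULL, sync_window = 500,
                           max_interseg_delay = 2000) {
  if (!is.null(channels)) {
    have <- unique(peaks$segment)
    miss <- setdiff(channels, have)
    if (length(miss)) {
      stop("peak table lacks channel(s): ", paste(miss, collapse = ", "))
    }
  }
  ev <- classify_events(peaks, channels, sync_window, max_interseg_delay)
  sel <- ev$kind %in% c("forwards_wave", "backwards_wave")
  out <- ev[sel, , drop = FALSE]
  attr(out, "peak_rows") <- attr(ev, "peak_rows")[sel]
  attr(out, "peaks_sorted") <- attr(ev, "peaks_sorted")
  out
}

#' Classify bursts only
#'
#' @inheritParams classify_events
#' @return the burst rows of [classify_events()].
#' @export
classify_bursts <- function(peaks, channels = NULL, sync_window = 500) {
  ev <- classify_events(peaks, channels, sync_window)
  ev[ev$kind %in% c("posterior_burst", "anterior_burst"), , drop = FALSE]
}

#' Detect fictive head sweeps from bilateral traces
#'
#' Computes the left - right difference trace; excursions whose peak
#' magnitude exceeds `threshold` times the reference scale (percent dF/F for
#' imaging data; the larger channel's peak-to-peak range for voltages) are
#' scored as left (positive) or right (negative) head sweeps. Successive
#' sweeps of the same side within `refractory` are merged.
#'
#' @param left,right numeric traces on a shared time grid.
#' @param time sample times, ms.
#' @param threshold fraction of the reference scale (default 0.05, the 5%
#'   peak-difference criterion).
#' @param refractory merge window, ms.
#' @param reference reference scale; default the larger peak-to-peak range
#'   of the two traces.
#' @return data.frame of events: `kind` ("head_sweep_L"/"head_sweep_R"),
#'   `start`, `end`, `t_first` (peak time), `magnitude`.
#' @export
detect_head_sweeps <- function(left, right, time, threshold = 0.05,
                               refractory = 500,
                               reference = max(diff(range(left)),
                                               diff(range(right)))) {
  if (length(left) != length(right) || length(left) != length(time)) {
    stop("left, right and time must share one grid")
  }
  d <- left - right
  th <- threshold * reference
  out <- list()
  for (sgn in c(1, -1)) {
    x <- sgn * d
    above <- x > th
    if (!any(above)) next
    dd <- diff(c(FALSE, above, FALSE))
    starts <- which(dd == 1); ends <- which(dd == -1) - 1L
    if (length(starts) > 1) {
      keep <- c(TRUE, time[starts[-1]] - time[ends[-length(ends)]] >= refractory)
      grp <- cumsum(keep)
      starts <- starts[keep]
      ends <- vapply(split(ends, grp), max, numeric(1))
    }
    for (i in seq_along(starts)) {
      idx <- starts[i]:ends[i]
      pk <- idx[which.max(x[idx])]
      out[[length(out) + 1L]] <- data.frame(
        kind = if (sgn > 0) "head_sweep_L" else "head_sweep_R",
        start = time[starts[i]], end = time[ends[i]], t_first = time[pk],
        magnitude = d[pk])
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), start = numeric(), end = numeric(),
                      t_first = numeric(), magnitude = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

#' Wave duration, interval and frequency
#'
#' Duration runs from 20% of the rising phase of activity in the first
#' (initiating) segment of the chain to 80% of the falling phase in the last
#' segment. The event interval is the time between equivalent points
#' (initiating-segment onsets) of consecutive same-kind events, and
#' frequency is its inverse; both are absent (NA) for the first event of a
#' kind.
#'
#' @param events wave events from [classify_events()].
#' @param peaks the peak table the events were classified from.
#' @param channels chain segments, posterior first; default canonical order.
#' @return `events` with columns `duration` (ms), `interval` (ms),
#'   `frequency` (Hz) added.
#' @export
wave_metrics <- function(events, peaks, channels = NULL) {
  if (is.null(channels)) {
    channels <- .SEGMENT_ORDER[.SEGMENT_ORDER %in% unique(peaks$segment)]
  }
  ev <- events[events$kind %in% c("forwards_wave", "backwards_wave"), ,
               drop = FALSE]
  if (!nrow(ev)) {
    ev$duration <- ev$interval <- ev$frequency <- numeric(0)
    return(ev)
  }
  keep <- events$kind %in% c("forwards_wave", "backwards_wave")
  rows_attr <- attr(events, "peak_rows")
  pk_sorted <- attr(events, "peaks_sorted")
  dur <- onset_first <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    first_seg <- if (ev$kind[i] == "forwards_wave") channels[1] else
      channels[length(channels)]
    last_seg <- if (ev$kind[i] == "forwards_wave") channels[length(channels)] else
      channels[1]
    if (!is.null(rows_attr) && !is.null(pk_sorted)) {
      p_ev <- pk_sorted[rows_attr[[which(keep)[i]]], ]
    } else {
      inwin <- peaks$time >= ev$t_first[i] - 1e-9 &
        peaks$time <= ev$t_last[i] + 1e-9
      p_ev <- peaks[inwin, ]
    }
    p_first <- p_ev[p_ev$segment == first_seg, ]
    p_last <- p_ev[p_ev$segment == last_seg, ]
    onset_first[i] <- min(p_first$onset)
    dur[i] <- max(p_last$offset) - onset_first[i]
  }
  ev$duration <- dur
  ev$interval <- NA_real_
  for (k in unique(ev$kind)) {
    idx <- which(ev$kind == k)
    if (length(idx) > 1) {
      ev$interval[idx[-1]] <- diff(onset_first[idx])
    }
  }
  ev$frequency <- 1000 / ev$interval
  ev
}

#' Annotate temporal overlap between events
#'
#' Same-program overlap: two concurrent events of the same wave direction
#' (the second starts before the first ends). Opposite-program overlap: a
#' forwards and a backwards event (wave or the corresponding burst) whose
#' spans intersect. Returns per-event flags and total counts.
#'
#' @param events event data.frame with `kind`, `start`, `end`.
#' @return list with `events` (flags `same_overlap`, `opposite_overlap`
#'   added) and `counts`.
#' @export
detect_overlap <- function(events) {
  n <- nrow(events)
  same <- opp <- rep(FALSE, n)
  fwd_kinds <- c("forwards_wave", "posterior_burst")
  bwd_kinds <- c("backwards_wave", "anterior_burst")
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (events$start[j] >= events$end[i]) break
        overlap <- events$start[j] < events$end[i]
        if (!overlap) next
        if (events$kind[i] == events$kind[j] &&
            events$kind[i] %in% c(fwd_kinds[1], bwd_kinds[1])) {
          same[i] <- same[j] <- TRUE
        }
        if ((events$kind[i] %in% fwd_kinds && events$kind[j] %in% bwd_kinds) ||
            (events$kind[i] %in% bwd_kinds && events$kind[j] %in% fwd_kinds)) {
          opp[i] <- opp[j] <- TRUE
        }
      }
    }
  }
  events$same_overlap <- same
  events$opposite_overlap <- opp
  list(events = events,
       counts = c(same = sum(same) %/% 2 + sum(same) %% 2,
                  opposite = sum(opp) %/% 2 + sum(opp) %% 2))
}

#' Transition matrix of an event sequence
#'
#' Probability that each kind of motor program is followed by each other
#' kind, computed from the time-ordered sequence; each row with at least one
#' outgoing transition sums to 1.
#'
#' @param kinds character vector (or events data.frame with `kind`,
#'   `start`), in temporal order.
#' @return square matrix of transition probabilities (empty for < 2 events).
#' @export
transition_matrix <- function(kinds) {
  if (is.data.frame(kinds)) kinds <- kinds$kind[order(kinds$start)]
  if (length(kinds) < 2) return(matrix(numeric(), 0, 0))
  lev <- sort(unique(kinds))
  tab <- table(factor(kinds[-length(kinds)], lev), factor(kinds[-1], lev))
  m <- unclass(tab / pmax(rowSums(tab), 1))
  attr(m, "call") <- NULL
  m
}

#' Bilateral asymmetry density profile
#'
#' Gaussian kernel density estimate of all samples of the left - right
#' difference trace, with the rule-of-thumb bandwidth multiplied by
#' `bandwidth_factor` (default 4). The width of the profile reflects the
#' spectrum of asymmetries; its mode location reflects the side bias.
#'
#' @param left,right traces on a shared grid.
#' @param bandwidth_factor multiplier on the rule-of-thumb bandwidth.
#' @param n number of evaluation points.
#' @return a [stats::density] object (integrates to 1).
#' @export
asymmetry_kde <- function(left, right, bandwidth_factor = 4, n = 512) {
  if (length(left) != length(right)) stop("traces must share one grid")
  d <- left - right
  bw <- stats::bw.nrd0(d)
  if (bw <= 0) bw <- max(abs(d), 1e-6) * 0.01 + 1e-9
  stats::density(d, bw = bw * bandwidth_factor, n = n)
}

#' Ordinary least-squares fit with R^2
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need >= 3 paired points")
  }
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}
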