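# Stimulus protocols: tonic current, Poisson pulse trains (the single
# parameter is the mean stimulus interval, MSI), current ramps, and
# optogenetic unblock windows. Episodes are declarative; compilation onto the
# integration grid happens at simulation time and is deterministic given the
# protocol seed.

#' Tonic current episode
#'
#' @param cells character vector of target cell names.
#' @param start,stop window, ms.
#' @param amplitude injected current, nA.
#' @return a stimulus episode.
#' @export
tonic_current <- function(cells, start, stop, amplitude) {
  stopifnot(stop >= start)
  structure(list(kind = "tonic", cells = cells, start = start, stop = stop,
                 amplitude = amplitude), class = "stim_episode")
}

#' Poisson pulse-train episode
#'
#' Brief current pulses whose onset intervals are i.i.d. exponential with
#' mean `MSI`, the single parameter of the protocol; each target cell gets an
#' independent stream. Defaults correspond to the standard stochastic command
#' input: 100 ms, 0.01 nA pulses.
#'
#' @param cells character vector of target cell names.
#' @param MSI mean stimulus interval, ms (> 0).
#' @param window c(start, stop) in ms over which onsets are drawn.
#' @param width pulse width, ms.
#' @param amplitude pulse amplitude, nA. Overlapping pulses sum.
#' @return a stimulus episode.
#' @export
poisson_pulse_train <- function(cells, MSI, window, width = 100,
                                amplitude = 0.01) {
  if (!is.numeric(MSI) || MSI <= 0) stop("MSI must be positive")
  stopifnot(width > 0, length(window) == 2, window[2] >= window[1])
  structure(list(kind = "pulse_train", cells = cells, MSI = MSI,
                 window = window, width = width, amplitude = amplitude),
            class = "stim_episode")
}

#' Current-ramp episode
#'
#' Linearly increasing (or decreasing) injected current, zero at `start`.
#'
#' @param cells character vector of target cell names.
#' @param start,stop window, ms (stop > start).
#' @param slope ramp slope, nA per second.
#' @return a stimulus episode.
#' @export
ramp_stimulus <- function(cells, start, stop, slope) {
  stopifnot(stop > start)
  structure(list(kind = "ramp", cells = cells, start = start, stop = stop,
                 slope = slope), class = "stim_episode")
}

#' Optogenetic unblock window
#'
#' Marks the interval during which the opto channels of the target cells are
#' unblocked ("light on").
#'
#' @param cells character vector of target cell names (must carry an
#'   [opto_channel()] in the network spec).
#' @param start,stop window, ms.
#' @return a stimulus episode.
#' @export
opto_window <- function(cells, start, stop) {
  stopifnot(stop >= start)
  structure(list(kind = "opto", cells = cells, start = start, stop = stop),
            class = "stim_episode")
}

#' Assemble a stimulus protocol
#'
#' @param ... stimulus episodes ([tonic_current()], [poisson_pulse_train()],
#'   [ramp_stimulus()], [opto_window()]), or lists of episodes.
#' @param rng_seed integer seed governing all pulse-train sampling. Each
#'   (episode, cell) pair derives an independent stream from it, so one
#'   cell's train is unchanged by another's.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(..., rng_seed = 1L) {
  eps <- list(...)
  flat <- list()
  for (e in eps) {
    if (inherits(e, "stim_episode")) flat[[length(flat) + 1L]] <- e
    else if (is.list(e)) for (x in e) {
      stopifnot(inherits(x, "stim_episode"))
      flat[[length(flat) + 1L]] <- x
    }
    else stop("arguments must be stimulus episodes")
  }
  structure(list(episodes = flat, rng_seed = as.integer(rng_seed)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus_protocol: %d episode(s), seed %d\n",
              length(x$episodes), x$rng_seed))
  for (e in x$episodes) {
    cat(sprintf("  %-11s -> %s\n", e$kind, paste(e$cells, collapse = ",")))
  }
  invisible(x)
}

#' Sample Poisson pulse-onset times
#'
#' Onset intervals are i.i.d. exponential with mean `MSI`; sampling starts at
#' the window start and stops past the window end. Deterministic given the
#' seed.
#'
#' @param MSI mean stimulus interval, ms.
#' @param window c(start, stop), ms.
#' @param seed integer stream seed.
#' @return numeric vector of onset times in ms (possibly empty).
#' @export
poisson_pulse_times <- function(MSI, window, seed) {
  if (!is.numeric(MSI) || MSI <= 0) stop("MSI must be positive")
  D <- window[2] - window[1]
  if (D <= 0) return(numeric())
  n_guess <- max(16, ceiling(D / MSI + 6 * sqrt(D / MSI)))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  gaps <- stats::rexp(n_guess, rate = 1 / MSI)
  while (sum(gaps) < D) gaps <- c(gaps, stats::rexp(n_guess, rate = 1 / MSI))
  onsets <- window[1] + cumsum(gaps)
  onsets[onsets < window[2]]
}

# save/restore the global RNG state so protocol sampling is self-contained
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Per-(episode, cell) stream seed; stable under reordering of other cells.
.stream_seed <- function(rng_seed, episode_index, cell_index) {
  (as.double(rng_seed) * 7919 + cell_index * 104729 + episode_index * 31) %%
    2147483647
}

# Compile a protocol onto the integration grid of a built network.
# Returns the engine's stim/opto structures plus the sampled pulse times.
.compile_protocol <- function(protocol, network, duration, dt) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(network, "cpg_network"))
  n_steps <- round(duration / dt)
  nm <- network$cell_names
  cur <- list()   # per stimulated cell: numeric vector of per-step current
  pulse_times <- list()
  win_rows <- list()
  ensure <- function(cell) {
    if (is.null(cur[[cell]])) cur[[cell]] <<- numeric(n_steps)
  }
  tgrid_idx <- function(t0, t1) {
    # grid indices i (1-based) with t0 <= (i-1)*dt < t1
    i0 <- ceiling(t0 / dt) + 1L
    i1 <- ceiling(t1 / dt)
    if (i1 < i0) integer() else seq.int(max(1L, i0), min(n_steps, i1))
  }
  opto_nm <- names(network$spec$opto)
  for (ei in seq_along(protocol$episodes)) {
    e <- protocol$episodes[[ei]]
    unknown <- setdiff(e$cells, nm)
    if (length(unknown)) {
      stop("stimulus episode targets unknown cell(s): ",
           paste(unknown, collapse = ", "))
    }
    for (cell in e$cells) {
      ci <- match(cell, nm)
      if (e$kind == "tonic") {
        ensure(cell)
        idx <- tgrid_idx(e$start, e$stop)
        cur[[cell]][idx] <- cur[[cell]][idx] + e$amplitude
      } else if (e$kind == "ramp") {
        ensure(cell)
        idx <- tgrid_idx(e$start, e$stop)
        tt <- (idx - 1L) * dt
        cur[[cell]][idx] <- cur[[cell]][idx] + e$slope / 1000 * (tt - e$start)
      } else if (e$kind == "pulse_train") {
        ensure(cell)
        onsets <- poisson_pulse_times(
          e$MSI, e$window, .stream_seed(protocol$rng_seed, ei, ci))
        pulse_times[[cell]] <- c(pulse_times[[cell]], onsets)
        for (on in onsets) {
          idx <- tgrid_idx(on, on + e$width)
          cur[[cell]][idx] <- cur[[cell]][idx] + e$amplitude
        }
      } else if (e$kind == "opto") {
        if (!cell %in% opto_nm) {
          stop("opto window targets cell without an opto channel: ", cell)
        }
        win_rows[[length(win_rows) + 1L]] <-
          c(match(cell, opto_nm) - 1L, e$start, e$stop)
      }
    }
  }
  stim_cells <- names(cur)
  mat <- if (length(cur)) do.call(cbind, cur) else
    matrix(numeric(), nrow = n_steps, ncol = 0)
  windows <- if (length(win_rows)) do.call(rbind, win_rows) else
    matrix(numeric(), ncol = 3)
  list(stim = list(idx = as.integer(match(stim_cells, nm) - 1L), mat = mat,
                   cells = stim_cells),
       opto = c(network$opto, list(windows = windows)),
       pulse_times = pulse_times)
}
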