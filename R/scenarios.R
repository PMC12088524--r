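# Scenario layer: the standard in-silico experiments (HO frequency sweeps,
# segment-block sweeps, MSI-biased full-model runs, graded disinhibition),
# plus a config-driven runner with provenance logging and a parameter-grid
# sweep. Scenario files are plain-text YAML and reproduce bit-for-bit under
# a fixed seed.

#' Oscillation frequency of a rhythmic trace
#'
#' Frequency from upward mid-range crossings of the post-transient trace;
#' returns 0 for traces without sustained oscillation (swing below
#' `min_swing` or fewer than 3 cycles).
#'
#' @param trace numeric vector.
#' @param time sample times, ms.
#' @param min_swing minimum peak-to-peak amplitude to count as oscillating,
#'   mV.
#' @return frequency in Hz (0 if not oscillating).
#' @export
oscillation_frequency <- function(trace, time, min_swing = 8) {
  if (diff(range(trace)) < min_swing) return(0)
  th <- min(trace) + 0.5 * diff(range(trace))
  ups <- which(diff(trace > th) == 1)
  if (length(ups) < 3) return(0)
  1000 * (length(ups) - 1) / (time[ups[length(ups)]] - time[ups[1]])
}

# HO blueprint with scaled synaptic kinetics: transmitter clearance times k,
# maximum release rate divided by k (constant product, varying ratio).
.ho_with_kinetics <- function(k) {
  bp <- hemisegmental_oscillator()
  if (k == 1) return(bp)
  cn <- bp$spec$connections
  cn$params <- lapply(cn$params, function(p) {
    synapse_parameters(p$polarity, r_max = p$r_max / k, gain = p$gain,
                       tau_T_clr = p$tau_T_clr * k)
  })
  bp$spec <- network_spec(bp$spec$cells, cn)
  bp
}

#' Hemisegmental-oscillator frequency sweep
#'
#' Sweeps tonic command current into C_B (and optionally the synaptic
#' clearance-to-release kinetic ratio) and measures the steady oscillation
#' frequency of E_B. The default amplitude grid spans the oscillator's
#' tonic operating range; the default kinetic grid multiplies the
#' transmitter clearance time constant by k and divides the maximum release
#' rate by k for k over powers of two, spanning roughly three orders of
#' magnitude of the clearance/release ratio.
#'
#' @param amplitudes tonic current amplitudes, nA.
#' @param kinetic_factors kinetic scale factors k (1 = defaults).
#' @param duration simulated time per grid point, ms.
#' @param settle transient discarded before frequency measurement, ms.
#' @param dt integration step, ms.
#' @return data.frame with `amplitude`, `k`, `frequency` (Hz; 0 = no
#'   sustained oscillation).
#' @export
ho_frequency_sweep <- function(amplitudes = c(0.05, 0.06, 0.07, 0.08, 0.09,
                                              0.10, 0.11, 0.12, 0.13),
                               kinetic_factors = 1,
                               duration = 80000, settle = 15000, dt = 1) {
  out <- expand.grid(amplitude = amplitudes, k = kinetic_factors)
  out$frequency <- NA_real_
  for (i in seq_len(nrow(out))) {
    bp <- .ho_with_kinetics(out$k[i])
    prot <- stimulus_protocol(
      tonic_current("C_B", 2000, duration, out$amplitude[i]))
    r <- simulate_network(bp, prot, duration = duration, dt = dt,
                          record = "E_B")
    keep <- r$time > settle
    out$frequency[i] <- oscillation_frequency(r$V[keep, 1], r$time[keep])
  }
  out
}

#' Max/min frequency ratio over the oscillating part of a sweep
#'
#' @param sweep result of [ho_frequency_sweep()].
#' @return the fold range (max/min positive frequency); NA if fewer than two
#'   grid points oscillate.
#' @export
frequency_fold_range <- function(sweep) {
  f <- sweep$frequency[sweep$frequency > 0]
  if (length(f) < 2) return(NA_real_)
  max(f) / min(f)
}

#' Segment-block sweep on the abdominal chain
#'
#' Drives the chain tonically in one direction, applies a hyperpolarising
#' block to the wave-carrying excitor at each listed segment in turn
#' (plus an unblocked control run), and measures per-cycle wave duration
#' (initiating-segment 20% rise to last-intact-segment 80% fall) and cycle
#' period (initiating-segment onset to onset).
#'
#' @param mode "forwards" (block E_F, drive C_F) or "backwards".
#' @param blocks segments to block, e.g. `c("A5","A4","A3","A2","A1")`;
#'   `NA` entries mean no block.
#' @param duration simulated time per condition, ms.
#' @param amplitude tonic command amplitude, nA.
#' @param block_amplitude hyperpolarising block current, nA.
#' @param with_wave_detectors include the wave-detector motif.
#' @param dt integration step, ms.
#' @return data.frame with `block`, `intact` (number of unblocked segments),
#'   `duration` (ms), `period` (ms) per cycle.
#' @export
block_sweep <- function(mode = c("forwards", "backwards"),
                        blocks = NULL, duration = 120000, amplitude = 0.02,
                        block_amplitude = -0.1, with_wave_detectors = TRUE,
                        dt = 1) {
  mode <- match.arg(mode)
  if (is.null(blocks)) {
    blocks <- if (mode == "forwards") c(NA, "A5", "A4", "A3", "A2", "A1") else
      c(NA, "A4", "A5", "A6", "A7", "A8")
  }
  bp <- abdominal_chain(with_wave_detectors = with_wave_detectors)
  cls <- if (mode == "forwards") "E_F" else "E_B"
  cmd <- if (mode == "forwards") "C_F" else "C_B"
  chans <- paste0(cls, ".A", 8:1)
  out <- NULL
  for (b in blocks) {
    eps <- list(tonic_current(cmd, 2000, duration, amplitude))
    if (!is.na(b)) {
      eps <- c(eps, apply_segment_block(bp, b, mode, c(2000, duration),
                                        amplitude = block_amplitude))
    }
    prot <- do.call(stimulus_protocol, eps)
    r <- simulate_network(bp, prot, duration = duration, dt = dt,
                          record = chans)
    d <- data.frame(time = r$time, r$V)
    names(d) <- c("time", paste0("A", 8:1))
    intact <- if (is.na(b)) {
      if (mode == "forwards") paste0("A", 8:1) else paste0("A", 1:8)
    } else {
      k <- as.integer(sub("A", "", b))
      if (mode == "forwards") paste0("A", 8:(k + 1)) else paste0("A", 1:(k - 1))
    }
    pc <- .per_cycle_metrics(d[d$time > 4000, ], mode, intact)
    if (is.null(pc)) next
    out <- rbind(out, data.frame(block = ifelse(is.na(b), "none", b),
                                 intact = length(intact), pc))
  }
  out
}

# per-cycle wave duration and period from initiating / last-intact segment
# peak tables
.per_cycle_metrics <- function(d, mode, intact) {
  init <- if (mode == "forwards") "A8" else "A1"
  last <- intact[length(intact)]
  p_init <- detect_peaks(d[[init]], d$time)
  p_last <- detect_peaks(d[[last]], d$time)
  if (nrow(p_init) < 3) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(p_init) - 1)) {
    w <- p_last[p_last$onset >= p_init$onset[i] - 200 &
                  p_last$onset < p_init$onset[i + 1] - 200, ]
    if (!nrow(w)) next
    out <- rbind(out, data.frame(
      duration = max(w$offset) - p_init$onset[i],
      period = p_init$onset[i + 1] - p_init$onset[i]))
  }
  out
}

#' Classify fictive events from a full-model recording
#'
#' Side-averages the forwards- and backwards-excitor voltages per segment,
#' classifies waves and bursts on each program's channels, detects discrete
#' head sweeps from the left/right difference at a thoracic segment, and
#' removes anterior bursts that coincide with a head sweep (asymmetric
#' anterior activity is scored as the sweep). Wave/burst events from the
#' forwards program are taken from E_F channels and those of the backwards
#' program from E_B channels.
#'
#' @param rec a `cpg_recording` of a [full_model()] simulation containing
#'   the per-side excitor voltages.
#' @param segments chain segments (posterior first).
#' @param sweep_segment thoracic segment used for head-sweep detection.
#' @param sweep_threshold head-sweep threshold as a fraction of the
#'   reference scale; for voltage traces the default scores excursions
#'   exceeding half the larger channel's range.
#' @param sweep_refractory merge window for successive same-side sweeps, ms.
#' @param sync_window near-synchrony window for burst classification, ms.
#' @return list with `events` (combined, time-ordered), `counts` (per kind)
#'   and `rate_per_min` (total fictive events per minute).
#' @export
classify_fictive_program <- function(rec, segments = c(paste0("A", 8:1), "T3"),
                                     sweep_segment = "T3",
                                     sweep_threshold = 0.5,
                                     sweep_refractory = 1000,
                                     sync_window = 500) {
  stopifnot(inherits(rec, "cpg_recording"))
  avg <- function(cls, seg) {
    l <- paste0(cls, ".", seg, ".L"); r <- paste0(cls, ".", seg, ".R")
    if (all(c(l, r) %in% colnames(rec$V))) (rec$V[, l] + rec$V[, r]) / 2
    else rec$V[, paste0(cls, ".", seg)]
  }
  dF <- data.frame(time = rec$time,
                   stats::setNames(as.data.frame(sapply(segments, function(s)
                     avg("E_F", s))), segments), check.names = FALSE)
  dB <- data.frame(time = rec$time,
                   stats::setNames(as.data.frame(sapply(segments, function(s)
                     avg("E_B", s))), segments), check.names = FALSE)
  evF <- classify_events(peak_table(dF), sync_window = sync_window)
  evB <- classify_events(peak_table(dB), sync_window = sync_window)
  l <- paste0("E_B.", sweep_segment, ".L")
  r <- paste0("E_B.", sweep_segment, ".R")
  hs <- if (all(c(l, r) %in% colnames(rec$V))) {
    detect_head_sweeps(rec$V[, l], rec$V[, r], rec$time,
                       threshold = sweep_threshold,
                       refractory = sweep_refractory)
  } else {
    data.frame(kind = character(), start = numeric(), end = numeric(),
               t_first = numeric(), magnitude = numeric())
  }
  keepF <- evF[evF$kind %in% c("forwards_wave", "posterior_burst"), ]
  keepB <- evB[evB$kind %in% c("backwards_wave", "anterior_burst"), ]
  if (nrow(keepB) && nrow(hs)) {
    ab <- keepB$kind == "anterior_burst"
    drop <- ab & vapply(seq_len(nrow(keepB)), function(i)
      any(hs$start < keepB$end[i] & hs$end > keepB$start[i]), logical(1))
    keepB <- keepB[!drop, ]
  }
  cols <- c("kind", "start", "end", "t_first")
  ev <- rbind(keepF[, cols], keepB[, cols],
              if (nrow(hs)) hs[, cols] else NULL)
  ev <- ev[order(ev$start), ]
  rownames(ev) <- NULL
  mins <- diff(range(rec$time)) / 60000
  list(events = ev, counts = table(ev$kind),
       rate_per_min = nrow(ev) / mins)
}

#' MSI-biased full-model runs
#'
#' Runs the full bilateral model under Poisson command input with the given
#' MSI ratio conditions (posterior : (anterior-left : anterior-right),
#' expressed as percentages of `base_msi`: 50 halves the interval, i.e.
#' doubles the average drive), classifies all fictive events, and reports
#' the event rate per run.
#'
#' @param conditions named list of c(posterior, left, right) percentage
#'   triples.
#' @param seeds integer seeds (one run per seed per condition).
#' @param duration simulated time per run, ms.
#' @param base_msi base mean stimulus interval, ms.
#' @param pulse_amplitude,pulse_width Poisson pulse parameters (nA, ms).
#' @param ... passed to [classify_fictive_program()].
#' @return data.frame with one row per run: condition, seed, per-kind
#'   counts, events per minute.
#' @export
full_model_event_rates <- function(conditions = list(
                                     equal = c(100, 100, 100),
                                     forwards_bias = c(50, 100, 100),
                                     anterior_bias = c(100, 50, 100)),
                                   seeds = c(1, 2, 3),
                                   duration = 1800000,
                                   base_msi = 1000,
                                   pulse_amplitude = 0.01,
                                   pulse_width = 100, ...) {
  bp <- full_model()
  segs <- c(paste0("A", 8:1), "T3", "T2", "T1")
  rec_cells <- paste(rep(c("E_F", "E_B"), each = 2 * length(segs)),
                     rep(segs, times = 4),
                     rep(rep(c("L", "R"), each = length(segs)), times = 2),
                     sep = ".")
  out <- NULL
  for (cname in names(conditions)) {
    pct <- conditions[[cname]]
    msi <- base_msi * pct / 100
    for (seed in seeds) {
      prot <- stimulus_protocol(
        poisson_pulse_train(c("C_F.L", "C_F.R"), msi[1], c(2000, duration),
                            width = pulse_width, amplitude = pulse_amplitude),
        poisson_pulse_train("C_HL", msi[2], c(2000, duration),
                            width = pulse_width, amplitude = pulse_amplitude),
        poisson_pulse_train("C_HR", msi[3], c(2000, duration),
                            width = pulse_width, amplitude = pulse_amplitude),
        rng_seed = seed)
      r <- simulate_network(bp, prot, duration = duration, record = rec_cells)
      cls <- classify_fictive_program(r, ...)
      cnt <- cls$counts
      row <- data.frame(condition = cname, seed = seed,
                        forwards_waves = sum(cnt[grep("forwards", names(cnt))]),
                        backwards_waves = sum(cnt[grep("backwards", names(cnt))]),
                        posterior_bursts = sum(cnt[grep("posterior", names(cnt))]),
                        anterior_bursts = sum(cnt[grep("anterior", names(cnt))]),
                        head_sweeps = sum(cnt[grep("head", names(cnt))]),
                        events_per_min = cls$rate_per_min)
      out <- rbind(out, row)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Config-driven scenario runner

.builtin_circuits <- list(
  hemisegmental_oscillator = hemisegmental_oscillator,
  abdominal_chain = abdominal_chain,
  thoracic_circuit = thoracic_circuit,
  full_model = full_model)

# resolve cell selections in scenario configs ("inhibitory" keyword, exact
# names, or regular expressions starting with "^")
.resolve_cells <- function(sel, blueprint) {
  nm <- blueprint$spec$cells$name
  if (identical(sel, "inhibitory")) {
    return(nm[grepl("^(I\\.|I$|D_)", nm)])
  }
  out <- unlist(lapply(sel, function(s) {
    if (startsWith(s, "^")) grep(s, nm, value = TRUE) else s
  }))
  unknown <- setdiff(out, nm)
  if (length(unknown)) {
    stop("scenario stimulus: unknown cell(s): ", paste(unknown, collapse = ", "))
  }
  out
}

.scenario_protocol <- function(cfg, blueprint) {
  eps <- list()
  for (st in cfg$stimulus) {
    if (is.null(st$kind)) stop("scenario stimulus entry lacks 'kind'")
    cells <- .resolve_cells(st$cells, blueprint)
    ep <- switch(st$kind,
      tonic = tonic_current(cells, st$start, st$stop, st$amplitude),
      poisson = poisson_pulse_train(cells, st$MSI,
                                    c(st$window[1], st$window[2]),
                                    width = st$width %||% 100,
                                    amplitude = st$amplitude %||% 0.01),
      ramp = ramp_stimulus(cells, st$start, st$stop, st$slope),
      opto = opto_window(cells, st$start, st$stop),
      block = {
        frag <- apply_segment_block(blueprint, st$segment, st$mode,
                                    c(st$window[1], st$window[2]),
                                    amplitude = st$amplitude %||% -0.1)
        if (!length(frag)) NULL else frag[[1]]
      },
      stop("unknown stimulus kind: ", st$kind))
    if (!is.null(ep)) eps[[length(eps) + 1L]] <- ep
  }
  do.call(stimulus_protocol, c(eps, list(rng_seed = cfg$seed %||% 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario from a config
#'
#' Builds the circuit, compiles the stimulus, simulates, optionally runs the
#' fictive-behaviour analysis, and writes traces, events and a summary with
#' provenance (package version, config hash, seed) to the output directory.
#' Re-running an archived scenario file reproduces its outputs exactly.
#'
#' @param config path to a YAML scenario file, or an equivalent named list
#'   with fields `circuit`, `circuit_options`, `duration`, `dt`, `seed`,
#'   `stimulus` (list of episodes), `record`, `analysis`, `out_dir`,
#'   `record_every`.
#' @param out_dir overrides the config's output directory; `NULL` suppresses
#'   file output.
#' @return (invisibly) list with `recording`, `events` (or NULL), `summary`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("circuit", "duration")) {
    if (is.null(cfg[[f]])) stop("scenario config lacks required field: ", f)
  }
  ctor <- .builtin_circuits[[cfg$circuit]]
  if (is.null(ctor)) {
    stop("unknown circuit '", cfg$circuit, "'; available: ",
         paste(names(.builtin_circuits), collapse = ", "))
  }
  bp <- do.call(ctor, cfg$circuit_options %||% list())
  prot <- .scenario_protocol(cfg, bp)
  record <- if (is.null(cfg$record)) NULL else .resolve_cells(cfg$record, bp)
  rec <- simulate_network(bp, prot, duration = cfg$duration,
                          dt = cfg$dt %||% 1, record = record,
                          record_every = cfg$record_every %||% 1L)
  events <- NULL
  if (identical(cfg$analysis$type, "events")) {
    segs <- intersect(unique(bp$spec$cells$segment), c(paste0("A", 8:1)))
    chain <- c(paste0("A", 8:1), "T3")
    chain <- chain[chain %in% unique(bp$spec$cells$segment)]
    cls <- classify_fictive_program(
      rec, segments = chain,
      sweep_threshold = cfg$analysis$sweep_threshold %||% 0.5)
    events <- cls$events
  }
  cfg_norm <- cfg[order(names(cfg))]
  cfg_txt <- yaml::as.yaml(cfg_norm)
  tf <- tempfile(); writeLines(cfg_txt, tf)
  summary <- list(
    package_version = as.character(utils::packageVersion("larvaCPG")),
    config_hash = unname(tools::md5sum(tf)),
    seed = cfg$seed %||% 1L,
    n_cells = nrow(bp$spec$cells),
    n_connections = nrow(bp$spec$connections),
    duration_ms = cfg$duration,
    n_events = if (is.null(events)) NA_integer_ else nrow(events),
    events_per_min = if (is.null(events)) NA_real_ else
      nrow(events) / (cfg$duration / 60000),
    event_counts = if (is.null(events)) NULL else
      as.list(table(events$kind)))
  unlink(tf)
  out_dir <- out_dir %||% cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_recording(rec, file.path(out_dir, "traces.tsv"))
    if (!is.null(events)) {
      utils::write.table(events, file.path(out_dir, "events.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
    writeLines(cfg_txt, file.path(out_dir, "scenario.yaml"))
    atlas <- circuit_atlas(bp)
    utils::write.table(atlas$connections,
                       file.path(out_dir, "connections.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(recording = rec, events = events, summary = summary))
}

#' Run a scenario template over a parameter grid
#'
#' Each grid row overrides fields of the template config (names with `$`
#' descend into nested lists, e.g. `circuit_options$opto_g`); each row runs
#' once per seed. Deterministic given the grid and seed list.
#'
#' @param template scenario config (list or YAML path).
#' @param grid data.frame of overrides (possibly 0 columns for seed-only
#'   sweeps).
#' @param seeds integer vector of seeds.
#' @return data.frame with one row per (grid row, seed): the overrides, the
#'   seed, and the summary statistics of each run.
#' @export
batch_sweep <- function(template, grid = data.frame(row = 1), seeds = 1L) {
  cfg0 <- if (is.character(template)) yaml::read_yaml(template) else template
  out <- NULL
  for (i in seq_len(nrow(grid))) {
    cfg <- cfg0
    for (col in names(grid)) {
      if (col == "row") next
      path <- strsplit(col, "$", fixed = TRUE)[[1]]
      if (length(path) == 1) cfg[[path]] <- grid[[col]][i]
      else cfg[[path[1]]][[path[2]]] <- grid[[col]][i]
    }
    for (seed in seeds) {
      cfg$seed <- as.integer(seed)
      res <- run_scenario(cfg, out_dir = NULL)
      row <- cbind(grid[i, , drop = FALSE], seed = seed,
                   n_events = res$summary$n_events %||% NA,
                   events_per_min = res$summary$events_per_min %||% NA)
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Bundled scenario configurations
#'
#' Ready-made configs for the standard experiments: `"ho_tonic"` (tonic
#' command drive of the hemisegmental oscillator), `"chain_forwards"`
#' (tonic forwards waves in the abdominal chain), `"chain_stochastic"`
#' (Poisson drive of both abdominal commands), `"full_equal_bias"` (full
#' model under equal MSI), and `"disinhibition"` (full model with a
#' GtACR1-style chloride conductance in all inhibitory neurons, unblocked
#' mid-run).
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param duration simulated time, ms.
#' @return a scenario config list for [run_scenario()].
#' @export
bundled_scenario <- function(name = c("ho_tonic", "chain_forwards",
                                      "chain_stochastic", "full_equal_bias",
                                      "disinhibition"),
                             seed = 1L, duration = NULL) {
  name <- match.arg(name)
  switch(name,
    ho_tonic = list(
      circuit = "hemisegmental_oscillator",
      duration = duration %||% 80000, seed = seed,
      stimulus = list(list(kind = "tonic", cells = "C_B", start = 2000,
                           stop = duration %||% 80000, amplitude = 0.06)),
      record = c("E_F", "E_B", "I", "C_B"),
      analysis = list(type = "none")),
    chain_forwards = list(
      circuit = "abdominal_chain",
      duration = duration %||% 120000, seed = seed,
      stimulus = list(list(kind = "tonic", cells = "C_F", start = 2000,
                           stop = duration %||% 120000, amplitude = 0.02)),
      record = "^E_", analysis = list(type = "events")),
    chain_stochastic = list(
      circuit = "abdominal_chain",
      duration = duration %||% 300000, seed = seed,
      stimulus = list(
        list(kind = "poisson", cells = "C_F", MSI = 1000,
             window = c(2000, duration %||% 300000)),
        list(kind = "poisson", cells = "C_B", MSI = 1000,
             window = c(2000, duration %||% 300000))),
      record = "^E_", analysis = list(type = "events")),
    full_equal_bias = list(
      circuit = "full_model",
      duration = duration %||% 600000, seed = seed,
      stimulus = list(
        list(kind = "poisson", cells = c("C_F.L", "C_F.R"), MSI = 1000,
             window = c(2000, duration %||% 600000)),
        list(kind = "poisson", cells = "C_HL", MSI = 1000,
             window = c(2000, duration %||% 600000)),
        list(kind = "poisson", cells = "C_HR", MSI = 1000,
             window = c(2000, duration %||% 600000))),
      record = "^E_", analysis = list(type = "events")),
    disinhibition = list(
      circuit = "full_model",
      circuit_options = list(opto_g = 0.2),
      duration = duration %||% 180000, seed = seed,
      stimulus = list(
        list(kind = "poisson", cells = c("C_F.L", "C_F.R"), MSI = 1000,
             window = c(2000, duration %||% 180000)),
        list(kind = "poisson", cells = "C_HL", MSI = 1000,
             window = c(2000, duration %||% 180000)),
        list(kind = "poisson", cells = "C_HR", MSI = 1000,
             window = c(2000, duration %||% 180000)),
        list(kind = "opto", cells = "inhibitory", start = 60000,
             stop = 120000)),
      record = "^E_", analysis = list(type = "events")))
}

#' Serialise neuron or synapse parameters to a key-value config
#'
#' @param params a [neuron_parameters()] or [synapse_parameters()] object.
#' @param path output YAML file.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$.class <- class(params)[1]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read parameters written by [write_params()]
#'
#' @param path YAML file.
#' @return the reconstructed parameter object.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "neuron_parameters")) {
    x$area <- NULL
    do.call(neuron_parameters, x)
  } else if (identical(cls, "synapse_parameters")) {
    do.call(synapse_parameters, x)
  } else {
    stop("unrecognised parameter config")
  }
}
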