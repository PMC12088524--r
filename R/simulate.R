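# Whole-network integration: fixed-step exponential Euler at dt = 1 ms by
# default, recording membrane potentials (and optionally gating/calcium and
# synapse states) on a uniform grid. The compiled (C++) and reference (R)
# engines implement the identical staggered explicit scheme.

#' Simulate a network under a stimulus protocol
#'
#' Advances every neuron and synapse state in lockstep with the fixed-step
#' exponential-Euler scheme. Bit-reproducible given (spec, protocol, seed,
#' dt).
#'
#' @param network a [build_network()] result, a [network_spec()], or a
#'   circuit blueprint (see [hemisegmental_oscillator()]).
#' @param protocol a [stimulus_protocol()]; `NULL` for no stimulus.
#' @param duration simulated time, ms (> 0).
#' @param dt integration step, ms (default 1).
#' @param record cell names to record (default: all).
#' @param record_state logical: also record gate `m`, `Ca_i` per recorded
#'   cell and `T`, `m_syn` per recorded connection.
#' @param record_conns integer indices of connections to record when
#'   `record_state` is on (default: all).
#' @param record_every record every k-th step (storage decimation; the
#'   integration step is unchanged).
#' @param engine "cpp" (compiled, default) or "r" (pure-R reference, same
#'   scheme; for small cross-check runs).
#' @return an object of class `cpg_recording`: list with `time` (ms), `V`
#'   (matrix, one column per recorded cell), optional `m`, `Ca`, `T`,
#'   `m_syn`, the delivered stimulus (`stim`), sampled `pulse_times`, and
#'   `dt`.
#' @export
simulate_network <- function(network, protocol = NULL, duration, dt = 1,
                             record = NULL, record_state = FALSE,
                             record_conns = NULL, record_every = 1L,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(duration > 0, dt > 0)
  if (inherits(network, "circuit_blueprint")) network <- network$spec
  if (inherits(network, "network_spec")) network <- build_network(network)
  stopifnot(inherits(network, "cpg_network"))
  if (is.null(protocol)) protocol <- stimulus_protocol()
  if (is.null(record)) record <- network$cell_names
  rec_idx <- match(record, network$cell_names)
  if (anyNA(rec_idx)) {
    stop("unknown cell(s) in record: ",
         paste(record[is.na(rec_idx)], collapse = ", "))
  }
  if (is.null(record_conns)) record_conns <- seq_len(network$n_conns)
  comp <- .compile_protocol(protocol, network, duration, dt)

  if (network$n_cells == 0) {
    tm <- seq(0, duration, by = dt * record_every)
    return(structure(list(time = tm,
                          V = matrix(numeric(), nrow = length(tm), ncol = 0),
                          stim = comp$stim, pulse_times = comp$pulse_times,
                          dt = dt, record_every = record_every),
                     class = "cpg_recording"))
  }

  run <- if (engine == "cpp") .sim_engine_cpp else .sim_engine_r
  out <- run(network$cells, network$conns, comp$stim, comp$opto,
             duration, dt, as.integer(rec_idx - 1L),
             as.integer(record_conns - 1L), as.integer(record_every),
             record_state)
  colnames(out$V) <- record
  rec <- list(time = out$time, V = out$V, stim = comp$stim,
              pulse_times = comp$pulse_times, dt = dt,
              record_every = record_every)
  if (record_state) {
    colnames(out$m) <- colnames(out$Ca) <- record
    cn <- if (length(record_conns)) {
      paste0(network$conn_pre[record_conns], "->",
             network$conn_post[record_conns])
    } else character()
    colnames(out$T) <- colnames(out$m_syn) <- cn
    rec[c("m", "Ca", "T", "m_syn")] <- out[c("m", "Ca", "T", "m_syn")]
  }
  rec$final <- out[c("final_V", "final_m", "final_Ca", "final_T")]
  structure(rec, class = "cpg_recording")
}

#' @export
print.cpg_recording <- function(x, ...) {
  cat(sprintf("cpg_recording: %d samples x %d cells, dt %g ms (x%d), %.1f s\n",
              length(x$time), ncol(x$V), x$dt, x$record_every,
              max(x$time) / 1000))
  invisible(x)
}

#' @export
as.data.frame.cpg_recording <- function(x, ...) {
  data.frame(time = x$time, x$V, check.names = FALSE)
}

# Pure-R reference engine, same scheme as the compiled one; used by tests to
# cross-check the compiled path on small problems.
.sim_engine_r <- function(cells, conns, stim, opto, duration, dt,
                          record_cells, record_conns, record_every,
                          record_gates) {
  n_steps <- round(duration / dt)
  n_cells <- length(cells$V0)
  V <- cells$V0; m <- cells$m0; Ca <- cells$Ca0
  ECa <- cells$rtzf_mV * log(cells$Cae_nM / Ca)
  T_cleft <- conns$T0
  msyn <- numeric(length(T_cleft))
  pre <- conns$pre + 1L; post <- conns$post + 1L
  dec_m <- exp(-dt / cells$tau_m); dec_Ca <- exp(-dt / cells$tauCa)
  dec_T <- exp(-dt / conns$tauT)
  n_out <- n_steps %/% record_every + 1L
  rc <- record_cells + 1L; rs <- record_conns + 1L
  recV <- matrix(NA_real_, n_out, length(rc))
  recM <- recCa <- if (record_gates) recV else matrix(0, 0, 0)
  recT <- recMs <- if (record_gates) matrix(NA_real_, n_out, length(rs)) else
    matrix(0, 0, 0)
  rec_time <- numeric(n_out)
  ow <- opto$windows
  row_i <- 1L
  snap <- function(t) {
    rec_time[row_i] <<- t
    recV[row_i, ] <<- V[rc]
    if (record_gates) {
      recM[row_i, ] <<- m[rc]; recCa[row_i, ] <<- Ca[rc]
      if (length(rs)) { recT[row_i, ] <<- T_cleft[rs]; recMs[row_i, ] <<- msyn[rs] }
    }
    row_i <<- row_i + 1L
  }
  snap(0)
  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt
    if (length(pre)) {
      rate <- conns$rmax / (1 + exp((conns$Camid - Ca[pre]) / conns$Sr))
      T_inf <- rate * conns$tauT
      T_cleft <- T_inf + (T_cleft - T_inf) * dec_T
      msyn <- 2 / (1 + exp(-T_cleft / conns$Sbind)) - 1
      g <- conns$g_tot * msyn
      g_acc <- as.numeric(tapply(g, factor(post, levels = seq_len(n_cells)),
                                 sum, default = 0))
      gE_acc <- as.numeric(tapply(g * conns$Esyn,
                                  factor(post, levels = seq_len(n_cells)),
                                  sum, default = 0))
    } else {
      g_acc <- gE_acc <- numeric(n_cells)
    }
    if (nrow(ow)) {
      act <- which(t >= ow[, 2] & t < ow[, 3])
      for (w in act) {
        p <- ow[w, 1] + 1L
        j <- opto$idx[p] + 1L
        g_acc[j] <- g_acc[j] + opto$g_tot[p]
        gE_acc[j] <- gE_acc[j] + opto$g_tot[p] * opto$E[p]
      }
    }
    I_inj <- numeric(n_cells)
    if (length(stim$idx)) I_inj[stim$idx + 1L] <- stim$mat[i, ]
    m_inf <- 1 / (1 + exp((cells$Vmid - V) / cells$SCa))
    m <- m_inf + (m - m_inf) * dec_m
    gCa <- m * cells$gCa
    ICa <- gCa * (V - ECa) * 1000
    inflow <- cells$Beff * pmax(0, -ICa)
    Ca_inf <- cells$Camin + inflow * cells$tauCa
    Ca <- pmax(Ca_inf + (Ca - Ca_inf) * dec_Ca, cells$Camin)
    ECa <- cells$rtzf_mV * log(cells$Cae_nM / Ca)
    g_tot <- cells$gL + gCa + g_acc
    gE <- cells$gL * cells$EL + gCa * ECa + gE_acc
    V_inf <- (gE + I_inj / 1000) / g_tot
    V <- V_inf + (V - V_inf) * exp(-dt * g_tot / cells$C_tot)
    if (!all(is.finite(V))) {
      stop(sprintf("non-finite membrane potential at step %d (t = %g ms), cell index %d",
                   i, t, which(!is.finite(V))[1]))
    }
    if ((i %% record_every) == 0L) snap(i * dt)
  }
  list(time = rec_time, V = recV, m = recM, Ca = recCa, T = recT,
       m_syn = recMs, final_V = V, final_m = m, final_Ca = Ca,
       final_T = T_cleft)
}

#' Write a recording as delimited text
#'
#' One time column plus one column per recorded cell, tab-separated with a
#' header row.
#'
#' @param rec a `cpg_recording`.
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(as.data.frame(rec), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a delimited multichannel trace table
#'
#' Accepts the format written by [write_recording()] or any delimited table
#' with a time column and per-ROI columns.
#'
#' @param path input file path.
#' @param sep field separator (default tab).
#' @return data.frame with a `time` column.
#' @export
read_traces <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!"time" %in% names(df)) {
    stop("trace table must contain a 'time' column")
  }
  df
}
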