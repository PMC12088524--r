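# Event census helpers shared by the phenotype and acceptance tests.

# Classify both program channels of an abdominal-chain recording and count
# waves, same-direction wave concurrency (a wave's initiating peak falling
# before the previous same-kind wave's final peak), and opposite-program
# band concurrency between any forwards- and backwards-program events.
abdominal_census <- function(with_init, with_wave, msi = 1000, dur = 600000,
                             seed = 11) {
  bp <- abdominal_chain(with_initiation_detectors = with_init,
                        with_wave_detectors = with_wave)
  prot <- stimulus_protocol(
    poisson_pulse_train("C_F", msi, c(2000, dur)),
    poisson_pulse_train("C_B", msi, c(2000, dur)), rng_seed = seed)
  ef <- paste0("E_F.A", 8:1)
  eb <- paste0("E_B.A", 8:1)
  r <- simulate_network(bp, prot, duration = dur, record = c(ef, eb))
  dF <- data.frame(time = r$time, r$V[, ef])
  names(dF) <- c("time", paste0("A", 8:1))
  dB <- data.frame(time = r$time, r$V[, eb])
  names(dB) <- c("time", paste0("A", 8:1))
  evF <- classify_events(peak_table(dF))
  evB <- classify_events(peak_table(dB))
  fw <- evF[evF$kind == "forwards_wave", ]
  bw <- evB[evB$kind == "backwards_wave", ]
  cnt_same <- function(w) {
    if (nrow(w) < 2) 0 else sum(w$t_first[-1] < w$t_last[-nrow(w)])
  }
  opp <- 0
  if (nrow(evF) && nrow(evB)) {
    for (i in seq_len(nrow(evF))) {
      opp <- opp + sum(evB$start < evF$end[i] & evB$end > evF$start[i])
    }
  }
  list(forwards = nrow(fw), backwards = nrow(bw),
       same_concurrency = cnt_same(fw) + cnt_same(bw),
       opposite_concurrency = opp)
}

# Hemisegment burst rate (bursts per minute summed over recorded excitor
# channels) in a time window of a recording.
burst_rate <- function(rec, t0, t1) {
  keep <- rec$time >= t0 & rec$time < t1
  n <- sum(apply(rec$V[keep, , drop = FALSE], 2, function(v) {
    if (diff(range(v)) > 10) sum(diff(v > -45) == 1) else 0
  }))
  n / ((t1 - t0) / 60000)
}

# Standard equal-bias Poisson drive for the full model.
full_model_protocol <- function(dur, seed, msi = c(1000, 1000, 1000),
                                extra = list()) {
  eps <- c(list(
    poisson_pulse_train(c("C_F.L", "C_F.R"), msi[1], c(2000, dur)),
    poisson_pulse_train("C_HL", msi[2], c(2000, dur)),
    poisson_pulse_train("C_HR", msi[3], c(2000, dur))), extra)
  do.call(stimulus_protocol, c(eps, list(rng_seed = seed)))
}

full_model_record_set <- function() {
  segs <- c(paste0("A", 8:1), "T3", "T2", "T1")
  paste(rep(c("E_F", "E_B"), each = 2 * length(segs)), rep(segs, 4),
        rep(rep(c("L", "R"), each = length(segs)), 2), sep = ".")
}
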