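# Circuit library: parameterised constructors for the hemisegmental
# oscillator (HO), the 8-segment abdominal chain with command / initiation-
# detector / wave-detector motifs, the bilateral thoracic head-sweep circuit,
# and the full integrated bilateral model. Cell names are
# "<class>.<segment>.<side>" with segment/side omitted where not applicable
# (commands and detectors are extrasegmental).

.cell_name <- function(class, segment = NA, side = NA) {
  parts <- c(class, segment, side)
  paste(parts[!is.na(parts)], collapse = ".")
}

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$cells <- list(); env$conns <- list()
  env
}

.add_cell <- function(b, class, segment = NA, side = NA) {
  nm <- .cell_name(class, segment, side)
  b$cells[[nm]] <- data.frame(name = nm, class = class,
                              segment = if (is.na(segment)) NA_character_ else segment,
                              side = if (is.na(side)) NA_character_ else side,
                              stringsAsFactors = FALSE)
  nm
}

.connect <- function(b, pre, post, polarity, r_max = 80, gain = 1) {
  for (p in pre) for (q in post) {
    b$conns[[length(b$conns) + 1L]] <-
      data.frame(pre = p, post = q, polarity = polarity, r_max = r_max,
                 gain = gain, stringsAsFactors = FALSE)
  }
}

# Add the three HO cells of one hemisegment and their reciprocal E<->I
# connections; both excitors make identical connections to and from the
# shared inhibitor.
.add_ho <- function(b, segment = NA, side = NA) {
  ef <- .add_cell(b, "E_F", segment, side)
  eb <- .add_cell(b, "E_B", segment, side)
  inh <- .add_cell(b, "I", segment, side)
  .connect(b, ef, inh, "excitatory")
  .connect(b, inh, ef, "inhibitory")
  .connect(b, eb, inh, "excitatory")
  .connect(b, inh, eb, "inhibitory")
  list(E_F = ef, E_B = eb, I = inh)
}

.finish_blueprint <- function(b, motifs, options, opto_g,
                              neuron_params = neuron_parameters()) {
  cells <- do.call(rbind, unname(b$cells))
  conns <- if (length(b$conns)) do.call(rbind, b$conns) else
    data.frame(pre = character(), post = character())
  opto <- list()
  if (!is.null(opto_g)) {
    inh_cells <- cells$name[grepl("^(I\\.|I$|D_)", cells$name)]
    opto <- stats::setNames(
      rep(list(opto_channel(opto_g)), length(inh_cells)), inh_cells)
  }
  spec <- network_spec(cells, conns, neuron_params = neuron_params,
                       opto = opto)
  structure(list(spec = spec, motifs = motifs, options = options),
            class = "circuit_blueprint")
}

#' @export
print.circuit_blueprint <- function(x, ...) {
  cat(sprintf("circuit_blueprint: %d cells, %d connections; motifs: %s\n",
              nrow(x$spec$cells), nrow(x$spec$connections),
              if (length(x$motifs)) paste(x$motifs, collapse = ", ") else "none"))
  invisible(x)
}

#' Enumerate the cells and connections of a blueprint
#'
#' A plain-text circuit atlas for auditing motif ablations: every cell with
#' its class/segment/side, and every connection with polarity, release-rate
#' class and gain.
#'
#' @param blueprint a circuit blueprint.
#' @return list with data.frames `cells` and `connections`.
#' @export
circuit_atlas <- function(blueprint) {
  stopifnot(inherits(blueprint, "circuit_blueprint"))
  cn <- blueprint$spec$connections
  conns <- data.frame(pre = cn$pre, post = cn$post,
                      polarity = vapply(cn$params, `[[`, "", "polarity"),
                      r_max = vapply(cn$params, `[[`, 0, "r_max"),
                      gain = vapply(cn$params, `[[`, 0, "gain"))
  list(cells = blueprint$spec$cells, connections = conns)
}

#' Hemisegmental oscillator (HO)
#'
#' The core conditional oscillator: forwards excitor E_F, backwards excitor
#' E_B, and a single shared inhibitor I, with reciprocal graded connections
#' identical for both excitors, plus command neurons C_F and C_B driving the
#' respective excitor. Silent at rest; oscillates conditionally on command
#' drive.
#'
#' @param opto_g optogenetic chloride conductance density placed in the
#'   inhibitor, mS cm^-2 (`NULL` = no channel; 0 attaches a
#'   non-conducting channel).
#' @return a `circuit_blueprint` (5 cells, 6 connections).
#' @export
hemisegmental_oscillator <- function(opto_g = NULL) {
  b <- .new_builder()
  ho <- .add_ho(b)
  cf <- .add_cell(b, "C_F"); cb <- .add_cell(b, "C_B")
  .connect(b, cf, ho$E_F, "excitatory")
  .connect(b, cb, ho$E_B, "excitatory")
  .finish_blueprint(b, motifs = character(),
                    options = list(circuit = "hemisegmental_oscillator"),
                    opto_g = opto_g)
}

#' Abdominal chain model
#'
#' One HO per abdominal segment A1..An (A1 anterior), intersegmental
#' feed-forwards excitation carrying the metachronal wave (E_F anteriad onto
#' the next E_F and I; E_B posteriad likewise), command neurons C_F (driving
#' E_F in the three posterior segments) and C_B (driving E_B in the two
#' anterior segments), and optionally the initiation-detector and
#' wave-detector inhibitory motifs. All detector inhibitory outputs carry
#' gain 2.
#'
#' @param n_segments number of abdominal segments (>= 2, default 8).
#' @param with_initiation_detectors include D_IF / D_IB (command-driven
#'   inhibition of the opposite program's initiating excitors).
#' @param with_wave_detectors include D_WF / D_WB (chain-wide excitor input,
#'   inhibition of the initiating excitors at both chain ends).
#' @param opto_g optogenetic chloride conductance density for all inhibitory
#'   cells, mS cm^-2 (`NULL` = none).
#' @return a `circuit_blueprint`.
#' @export
abdominal_chain <- function(n_segments = 8, with_initiation_detectors = TRUE,
                            with_wave_detectors = TRUE, opto_g = NULL) {
  if (!is.numeric(n_segments) || n_segments < 2) {
    stop("n_segments must be >= 2")
  }
  b <- .new_builder()
  segs <- paste0("A", seq_len(n_segments))
  hos <- lapply(segs, function(s) .add_ho(b, segment = s))
  names(hos) <- segs
  .abdominal_wiring(b, hos, segs, with_initiation_detectors,
                    with_wave_detectors, side = NA,
                    cf = .add_cell(b, "C_F"), cb = .add_cell(b, "C_B"))
  motifs <- c(if (with_initiation_detectors) "initiation_detectors",
              if (with_wave_detectors) "wave_detectors")
  .finish_blueprint(b, motifs = motifs,
                    options = list(circuit = "abdominal_chain",
                                   n_segments = n_segments,
                                   with_initiation_detectors = with_initiation_detectors,
                                   with_wave_detectors = with_wave_detectors),
                    opto_g = opto_g)
}

# Shared abdominal wiring for the single-sided chain and each side of the
# full model. `cb` may be a character vector (the two head-sweep commands
# replace C_B in the full model and both drive D_IB).
.abdominal_wiring <- function(b, hos, segs, with_init, with_wave, side,
                              cf, cb, cb_targets_anterior = TRUE,
                              extra_wf_sources = character(),
                              extra_wb_sources = character()) {
  n <- length(segs)
  post3 <- segs[seq.int(max(1, n - 2), n)]   # posterior initiating segments
  ant2 <- segs[seq_len(min(2, n))]           # anterior initiating segments
  # intersegmental feed-forwards excitation
  for (k in seq.int(2, n)) {
    .connect(b, hos[[segs[k]]]$E_F, hos[[segs[k - 1]]]$E_F, "excitatory")
    .connect(b, hos[[segs[k]]]$E_F, hos[[segs[k - 1]]]$I, "excitatory")
  }
  for (k in seq_len(n - 1)) {
    .connect(b, hos[[segs[k]]]$E_B, hos[[segs[k + 1]]]$E_B, "excitatory")
    .connect(b, hos[[segs[k]]]$E_B, hos[[segs[k + 1]]]$I, "excitatory")
  }
  # command fan-out
  for (s in post3) .connect(b, cf, hos[[s]]$E_F, "excitatory")
  if (cb_targets_anterior) {
    for (s in ant2) .connect(b, cb, hos[[s]]$E_B, "excitatory")
  }
  if (with_init) {
    dif <- .add_cell(b, "D_IF", side = side)
    dib <- .add_cell(b, "D_IB", side = side)
    .connect(b, cf, dif, "excitatory")
    .connect(b, cb, dib, "excitatory")
    for (s in ant2) .connect(b, dif, hos[[s]]$E_B, "inhibitory", gain = 2)
    for (s in post3) .connect(b, dib, hos[[s]]$E_F, "inhibitory", gain = 2)
  }
  if (with_wave) {
    dwf <- .add_cell(b, "D_WF", side = side)
    dwb <- .add_cell(b, "D_WB", side = side)
    for (s in segs) .connect(b, hos[[s]]$E_F, dwf, "excitatory")
    for (s in segs) .connect(b, hos[[s]]$E_B, dwb, "excitatory")
    for (src in extra_wf_sources) .connect(b, src, dwf, "excitatory")
    for (src in extra_wb_sources) .connect(b, src, dwb, "excitatory")
    for (d in c(dwf, dwb)) {
      for (s in post3) .connect(b, d, hos[[s]]$E_F, "inhibitory", gain = 2)
      for (s in ant2) .connect(b, d, hos[[s]]$E_B, "inhibitory", gain = 2)
    }
  }
  invisible(b)
}

#' Thoracic head-sweep circuit
#'
#' Three bilateral pairs of HOs (T1-T3), head-sweep command neurons C_HL and
#' C_HR exciting the ipsilateral backwards excitors, intersegmental
#' connections in the posterior-to-anterior direction only, and optionally
#' the head-sweep detectors D_HL / D_HR: each excited by ipsilateral E_Bs and
#' inhibiting contralateral E_Bs in a half-centre motif (gain 2 on the
#' inhibitory outputs).
#'
#' @param with_head_sweep_detectors include D_HL / D_HR.
#' @param opto_g optogenetic chloride conductance density for inhibitory
#'   cells, mS cm^-2.
#' @return a `circuit_blueprint`.
#' @export
thoracic_circuit <- function(with_head_sweep_detectors = TRUE, opto_g = NULL) {
  b <- .new_builder()
  segs <- paste0("T", 1:3)
  hos <- list()
  for (sd in c("L", "R")) {
    for (s in segs) hos[[paste(s, sd)]] <- .add_ho(b, segment = s, side = sd)
  }
  chl <- .add_cell(b, "C_HL"); chr <- .add_cell(b, "C_HR")
  .thoracic_wiring(b, hos, segs, chl, chr, with_head_sweep_detectors)
  .finish_blueprint(
    b, motifs = if (with_head_sweep_detectors) "head_sweep_detectors" else character(),
    options = list(circuit = "thoracic_circuit",
                   with_head_sweep_detectors = with_head_sweep_detectors),
    opto_g = opto_g)
}

.thoracic_wiring <- function(b, hos, segs, chl, chr, with_hs) {
  cmd <- c(L = chl, R = chr)
  for (sd in c("L", "R")) {
    for (s in segs) .connect(b, cmd[[sd]], hos[[paste(s, sd)]]$E_B, "excitatory")
    # posterior-to-anterior connections only within the thorax
    for (k in seq.int(2, length(segs))) {
      .connect(b, hos[[paste(segs[k], sd)]]$E_F,
               hos[[paste(segs[k - 1], sd)]]$E_F, "excitatory")
      .connect(b, hos[[paste(segs[k], sd)]]$E_F,
               hos[[paste(segs[k - 1], sd)]]$I, "excitatory")
    }
  }
  if (with_hs) {
    dh <- c(L = .add_cell(b, "D_HL"), R = .add_cell(b, "D_HR"))
    for (sd in c("L", "R")) {
      contra <- setdiff(c("L", "R"), sd)
      for (s in segs) {
        .connect(b, hos[[paste(s, sd)]]$E_B, dh[[sd]], "excitatory")
        .connect(b, dh[[sd]], hos[[paste(s, contra)]]$E_B, "inhibitory",
                 gain = 2)
      }
    }
  }
  invisible(b)
}

#' Full integrated bilateral model
#'
#' Bilateral duplication of the abdominal chain (midline excitatory coupling
#' between counterpart excitors in each abdominal segment at the reduced
#' release rate r_max = 20), the thoracic head-sweep circuit attached at
#' T3-A1, a synaptic chiasm from E_B in each A1 to the contralateral A2 E_B,
#' thoracic excitors feeding the wave detectors, and the backwards command
#' replaced by the head-sweep commands C_HL / C_HR (which drive the
#' initiation detectors D_IB on both sides).
#'
#' @param with_initiation_detectors,with_wave_detectors,with_head_sweep_detectors
#'   motif toggles.
#' @param opto_g optogenetic chloride conductance density for all inhibitory
#'   cells, mS cm^-2.
#' @return a `circuit_blueprint`.
#' @export
full_model <- function(with_initiation_detectors = TRUE,
                       with_wave_detectors = TRUE,
                       with_head_sweep_detectors = TRUE,
                       opto_g = NULL) {
  b <- .new_builder()
  asegs <- paste0("A", 1:8)
  tsegs <- paste0("T", 1:3)
  hos <- list()
  for (sd in c("L", "R")) {
    for (s in c(tsegs, asegs)) {
      hos[[paste(s, sd)]] <- .add_ho(b, segment = s, side = sd)
    }
  }
  chl <- .add_cell(b, "C_HL"); chr <- .add_cell(b, "C_HR")
  cf <- c(L = .add_cell(b, "C_F", side = "L"),
          R = .add_cell(b, "C_F", side = "R"))
  for (sd in c("L", "R")) {
    ahos <- hos[paste(asegs, sd)]
    names(ahos) <- asegs
    thos <- hos[paste(tsegs, sd)]
    # abdominal wiring per side; C_B is replaced by the head-sweep commands,
    # so backwards waves enter via T3 rather than direct anterior drive
    .abdominal_wiring(
      b, ahos, asegs, with_initiation_detectors, with_wave_detectors,
      side = sd, cf = cf[[sd]], cb = c(chl, chr),
      cb_targets_anterior = FALSE,
      extra_wf_sources = vapply(thos, `[[`, "", "E_F"),
      extra_wb_sources = vapply(thos, `[[`, "", "E_B"))
    # thoracic-abdominal junction (T3 <-> A1)
    .connect(b, ahos$A1$E_F, hos[[paste("T3", sd)]]$E_F, "excitatory")
    .connect(b, ahos$A1$E_F, hos[[paste("T3", sd)]]$I, "excitatory")
    .connect(b, hos[[paste("T3", sd)]]$E_B, ahos$A1$E_B, "excitatory")
    .connect(b, hos[[paste("T3", sd)]]$E_B, ahos$A1$I, "excitatory")
  }
  .thoracic_wiring(b, hos, tsegs, chl, chr, with_head_sweep_detectors)
  # midline coupling between counterpart abdominal excitors (reduced r_max)
  for (s in asegs) {
    for (cl in c("E_F", "E_B")) {
      l <- hos[[paste(s, "L")]][[cl]]; r <- hos[[paste(s, "R")]][[cl]]
      .connect(b, l, r, "excitatory", r_max = 20)
      .connect(b, r, l, "excitatory", r_max = 20)
    }
  }
  # chiasm: A1 E_Bs excite the contralateral A2 E_Bs
  .connect(b, hos[["A1 L"]]$E_B, hos[["A2 R"]]$E_B, "excitatory", r_max = 20)
  .connect(b, hos[["A1 R"]]$E_B, hos[["A2 L"]]$E_B, "excitatory", r_max = 20)
  motifs <- c(if (with_initiation_detectors) "initiation_detectors",
              if (with_wave_detectors) "wave_detectors",
              if (with_head_sweep_detectors) "head_sweep_detectors")
  .finish_blueprint(
    b, motifs = motifs,
    options = list(circuit = "full_model",
                   with_initiation_detectors = with_initiation_detectors,
                   with_wave_detectors = with_wave_detectors,
                   with_head_sweep_detectors = with_head_sweep_detectors),
    opto_g = opto_g)
}

#' Segment-block intervention
#'
#' Builds the stimulus fragment that halts wave progression at a given
#' abdominal segment during a window: hyperpolarising current into the
#' segment's E_F (forwards block) and/or E_B (backwards block), or
#' depolarising current into its inhibitor(s) (mode "both"), effectively
#' reducing the number of intact segments.
#'
#' @param blueprint the circuit the block applies to (used for cell lookup
#'   and laterality).
#' @param segment segment name, e.g. "A4".
#' @param mode "forwards", "backwards", or "both".
#' @param window c(start, stop), ms; a zero-length window yields no episodes.
#' @param amplitude blocking current, nA (negative for excitor
#'   hyperpolarisation; its magnitude is used as a depolarising current on
#'   the inhibitor in mode "both").
#' @return list of stimulus episodes (possibly empty).
#' @export
apply_segment_block <- function(blueprint, segment,
                                mode = c("forwards", "backwards", "both"),
                                window, amplitude = -0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(blueprint, "circuit_blueprint"), length(window) == 2)
  cells <- blueprint$spec$cells
  if (!segment %in% cells$segment) {
    stop("unknown segment: ", segment)
  }
  if (window[2] <= window[1]) return(list())
  pick <- function(class) {
    cells$name[cells$class == class & cells$segment == segment &
                 !is.na(cells$segment)]
  }
  targets <- switch(mode,
    forwards = list(cells = pick("E_F"), amp = amplitude),
    backwards = list(cells = pick("E_B"), amp = amplitude),
    both = list(cells = pick("I"), amp = abs(amplitude)))
  list(tonic_current(targets$cells, window[1], window[2], targets$amp))
}
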