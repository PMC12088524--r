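# Network plumbing: a declarative spec (cells + typed directed connections)
# validated and compiled into the flat arrays the integrator consumes.

#' Construct a network specification
#'
#' A `network_spec` holds named cells (each with its neuron parameters and an
#' optional optogenetic channel) and directed, individually parameterised
#' graded synaptic connections between them.
#'
#' @param cells data.frame with columns `name` (unique character) and
#'   optionally `class`, `segment`, `side` metadata. Per-cell neuron
#'   parameters and opto channels are supplied via `neuron_params` / `opto`.
#' @param connections data.frame with columns `pre`, `post` (cell names) and
#'   optionally `polarity`, `r_max`, `gain` overrides; a full
#'   [synapse_parameters()] object per row may be given in list column
#'   `params`.
#' @param neuron_params a single [neuron_parameters()] object applied to every
#'   cell (all neurons in the model are physiologically identical), or a list
#'   of such objects named by cell.
#' @param opto named list (by cell name) of [opto_channel()] objects.
#' @param allow_self logical: permit self-connections (off by default).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(cells, connections,
                         neuron_params = neuron_parameters(),
                         opto = list(), allow_self = FALSE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  connections <- as.data.frame(connections, stringsAsFactors = FALSE)
  if (!"name" %in% names(cells)) stop("cells must have a 'name' column")
  dup <- cells$name[duplicated(cells$name)]
  if (length(dup)) {
    stop("duplicate cell name(s): ", paste(unique(dup), collapse = ", "))
  }
  if (nrow(connections)) {
    if (!all(c("pre", "post") %in% names(connections))) {
      stop("connections must have 'pre' and 'post' columns")
    }
    missing <- setdiff(unique(c(connections$pre, connections$post)),
                       cells$name)
    if (length(missing)) {
      stop("connection endpoint(s) name missing cell(s): ",
           paste(missing, collapse = ", "))
    }
    if (!allow_self && any(connections$pre == connections$post)) {
      stop("self-connection(s) on: ",
           paste(unique(connections$pre[connections$pre == connections$post]),
                 collapse = ", "))
    }
    if (!"params" %in% names(connections)) {
      pol <- if ("polarity" %in% names(connections)) connections$polarity
             else rep("excitatory", nrow(connections))
      rmx <- if ("r_max" %in% names(connections)) connections$r_max
             else rep(80, nrow(connections))
      gn <- if ("gain" %in% names(connections)) connections$gain
            else rep(1, nrow(connections))
      connections$params <- lapply(seq_len(nrow(connections)), function(i) {
        synapse_parameters(polarity = pol[i], r_max = rmx[i], gain = gn[i])
      })
    }
  } else {
    connections <- data.frame(pre = character(), post = character())
    connections$params <- list()
  }
  if (inherits(neuron_params, "neuron_parameters")) {
    neuron_params <- stats::setNames(
      rep(list(neuron_params), nrow(cells)), cells$name)
  }
  if (!all(cells$name %in% names(neuron_params))) {
    stop("neuron_params missing for some cells")
  }
  if (length(opto) && !all(names(opto) %in% cells$name)) {
    stop("opto channel(s) assigned to unknown cell(s)")
  }
  structure(list(cells = cells, connections = connections,
                 neuron_params = neuron_params[cells$name], opto = opto),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %d cells, %d connections\n",
              nrow(x$cells), nrow(x$connections)))
  if (nrow(x$cells)) {
    cls <- if ("class" %in% names(x$cells)) table(x$cells$class) else NULL
    if (!is.null(cls)) {
      cat("  cell classes:",
          paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
    }
  }
  if (length(x$opto)) {
    cat("  opto channels on:", paste(names(x$opto), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compile a network specification into a simulable network
#'
#' Validates the spec, assigns rest-consistent initial conditions, and
#' precomputes the whole-cell quantities the integrator uses. Deterministic
#' given the spec.
#'
#' @param spec a [network_spec()].
#' @return an object of class `cpg_network`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  nm <- spec$cells$name
  n <- length(nm)
  np <- spec$neuron_params
  fld <- function(f) vapply(np, function(p) p[[f]], numeric(1))
  area <- fld("area")
  cells <- list(
    gL = fld("g_leak") * area,
    EL = fld("V_leak_eq"),
    gCa = fld("g_Ca_max") * area,
    Vmid = fld("V_mid"), SCa = fld("S_Ca"), tau_m = fld("tau_m"),
    Beff = fld("B") * fld("B_scale"),
    tauCa = fld("tau_Ca_clr"), Camin = fld("Ca_i_min"),
    Cae_nM = fld("Ca_e") * .NM_PER_MM,
    rtzf_mV = 1000 * .GAS_CONSTANT * fld("temperature") /
      (.CA_VALENCE * .FARADAY),
    C_tot = fld("C_m") * area,
    area = area)
  init <- lapply(np, initial_neuron_state)
  cells$V0 <- vapply(init, `[[`, numeric(1), "V_m")
  cells$m0 <- vapply(init, `[[`, numeric(1), "m")
  cells$Ca0 <- vapply(init, `[[`, numeric(1), "Ca_i")

  cn <- spec$connections
  k <- nrow(cn)
  sp <- cn$params
  sfld <- function(f) if (k) vapply(sp, function(p) p[[f]], numeric(1)) else numeric()
  pre_i <- match(cn$pre, nm)
  post_i <- match(cn$post, nm)
  conns <- list(
    pre = as.integer(pre_i - 1L), post = as.integer(post_i - 1L),
    Esyn = sfld("V_syn_eq"), rmax = sfld("r_max") * sfld("r_unit"),
    Camid = sfld("Ca_i_mid"),
    Sr = sfld("S_r"), tauT = sfld("tau_T_clr"), Sbind = sfld("S_bind"),
    g_tot = sfld("gain") * sfld("g_syn_max") * area[post_i],
    T0 = rep(0, k))

  opto_nm <- names(spec$opto)
  opto <- list(
    idx = as.integer(match(opto_nm, nm) - 1L),
    g_tot = vapply(spec$opto, function(o) o$g_opto_Cl, numeric(1),
                   USE.NAMES = FALSE) *
      (if (length(opto_nm)) area[match(opto_nm, nm)] else numeric()),
    E = vapply(spec$opto, function(o) o$E_opto, numeric(1),
               USE.NAMES = FALSE))
  structure(list(spec = spec, cell_names = nm, conn_pre = cn$pre,
                 conn_post = cn$post, cells = cells, conns = conns,
                 opto = opto, n_cells = n, n_conns = k),
            class = "cpg_network")
}

#' @export
print.cpg_network <- function(x, ...) {
  cat(sprintf("cpg_network: %d cells, %d graded connections, %d opto channel(s)\n",
              x$n_cells, x$n_conns, length(x$opto$idx)))
  invisible(x)
}
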