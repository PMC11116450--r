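# Regulatory network model: signed graph -> continuous ODE system.
#
# Node activations live in [0, 1]. Each non-input node i is governed by
#   dx_i/dt = s(omega_i; h_i) - gamma_i * x_i
# where omega_i in [0, 1] aggregates the activations of i's regulators
# (normalized so omega = 1 under full activation and no inhibition) and
# s is a normalized sigmoid with s(0) = 0, s(0.5) = 0.5, s(1) = 1.
# Patient synovial-fluid analyte levels, min-max rescaled across the
# cohort to [0, 1], drive the input nodes (clamped by default; an
# initial-condition-only mode is also provided). Per-patient steady
# states of the output transcription-factor nodes are the downstream
# classifier features.

#' Construct and validate a network specification
#'
#' @param nodes data frame with columns \code{name}, \code{role}
#'   (\code{input}, \code{internal} or \code{output_tf}), \code{h}
#'   (sigmoid gain > 0) and \code{gamma} (decay rate > 0).
#' @param edges data frame with columns \code{source}, \code{sign}
#'   (\code{"+"} or \code{"-"}), \code{target} and \code{weight} (> 0).
#' @return object of class \code{network_spec} with precomputed
#'   per-node regulator lists.
#' @export
network_spec <- function(nodes, edges) {
  nodes <- as.data.frame(nodes); edges <- as.data.frame(edges)
  if (anyDuplicated(nodes$name)) stop_config("duplicate node name")
  if (!all(nodes$role %in% c("input", "internal", "output_tf")))
    stop_config("node role must be input/internal/output_tf")
  if (!all(nodes$h > 0) || !all(nodes$gamma > 0))
    stop_config("h and gamma must be positive")
  miss <- setdiff(c(edges$source, edges$target), nodes$name)
  if (length(miss)) stop_config("edge endpoint not declared: %s",
                                paste(miss, collapse = ", "))
  if (!all(edges$sign %in% c("+", "-"))) stop_config("edge sign must be + or -")
  if (!all(edges$weight > 0)) stop_config("edge weights must be positive")
  inputs <- nodes$name[nodes$role == "input"]
  bad <- intersect(inputs, edges$target)
  if (length(bad)) stop_config("input node has incoming edges: %s",
                               paste(bad, collapse = ", "))
  if (!any(nodes$role == "output_tf"))
    stop_config("network needs at least one output_tf node")
  regs <- lapply(nodes$name, function(nm) {
    e <- edges[edges$target == nm, , drop = FALSE]
    list(act = e$source[e$sign == "+"], act_w = e$weight[e$sign == "+"],
         inh = e$source[e$sign == "-"], inh_w = e$weight[e$sign == "-"])
  })
  names(regs) <- nodes$name
  structure(list(nodes = nodes, edges = edges, regulators = regs),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d nodes (%d input, %d output_tf), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "input"),
              sum(x$nodes$role == "output_tf"), nrow(x$edges)))
  invisible(x)
}

#' Parse a SIF-like signed interaction file
#'
#' Each line is \code{source<TAB>sign<TAB>target[<TAB>weight]} with sign
#' \code{+} or \code{-} and default weight 1. Roles, gains and decays may
#' be supplied in a sidecar YAML (\code{roles:} name -> role, optional
#' \code{h:}, \code{gamma:} maps); otherwise nodes without incoming edges
#' are inputs, nodes without outgoing edges are output TFs, and the rest
#' are internal. Defaults h = 10, gamma = 1.
#'
#' @param path SIF file path.
#' @param roles_path optional sidecar YAML path.
#' @param default_h,default_gamma defaults for unlisted nodes.
#' @return a \code{\link{network_spec}}.
#' @export
parse_network <- function(path, roles_path = NULL,
                          default_h = 10, default_gamma = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop_config("empty network file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    if (length(p) < 3 || length(p) > 4)
      stop_config("line %d of %s: expected 3 or 4 tab-separated fields", i, path)
    if (!p[2] %in% c("+", "-"))
      stop_config("line %d of %s: sign must be + or -, got '%s'", i, path, p[2])
    w <- if (length(p) == 4) suppressWarnings(as.numeric(p[4])) else 1
    if (is.na(w) || w <= 0)
      stop_config("line %d of %s: bad weight '%s'", i, path, p[4])
    data.frame(source = p[1], sign = p[2], target = p[3], weight = w,
               stringsAsFactors = FALSE)
  }))
  nm <- unique(c(edges$source, edges$target))
  role <- ifelse(!nm %in% edges$target, "input",
                 ifelse(!nm %in% edges$source, "output_tf", "internal"))
  h <- rep(default_h, length(nm)); gamma <- rep(default_gamma, length(nm))
  if (!is.null(roles_path)) {
    side <- yaml::read_yaml(roles_path)
    if (!is.null(side$roles)) {
      for (k in names(side$roles)) {
        if (!k %in% nm) stop_config("sidecar role for undeclared node '%s'", k)
        role[nm == k] <- side$roles[[k]]
      }
    }
    for (k in names(side$h %||% list())) h[nm == k] <- side$h[[k]]
    for (k in names(side$gamma %||% list())) gamma[nm == k] <- side$gamma[[k]]
  }
  network_spec(data.frame(name = nm, role = role, h = h, gamma = gamma,
                          stringsAsFactors = FALSE),
               edges)
}

#' Min-max rescale analyte levels to regulatory inputs
#'
#' Each mapped analyte is rescaled across the cohort as
#' (v - min)/(max - min) into [0, 1]; a constant analyte maps to 0.5 for
#' every subject (with a warning). Subjects with a missing value in any
#' mapped analyte are dropped.
#'
#' @param analyte_table data frame of analyte columns with subject ids as
#'   rownames (e.g. \code{cohort_features(ct, "analyte")}).
#' @param mapping named list/vector analyte column -> input node name.
#' @param spec optional \code{\link{network_spec}}; if given, every input
#'   node must be covered by the mapping.
#' @return list of regulatory inputs, each \code{list(patient_id, values)}
#'   with \code{values} a named vector over input nodes, all in [0, 1].
#' @export
rescale_inputs <- function(analyte_table, mapping, spec = NULL) {
  mapping <- unlist(mapping)
  miss <- setdiff(names(mapping), colnames(analyte_table))
  if (length(miss)) stop_config("mapped analyte absent from table: %s",
                                paste(miss, collapse = ", "))
  if (!is.null(spec)) {
    inputs <- spec$nodes$name[spec$nodes$role == "input"]
    un <- setdiff(inputs, mapping)
    if (length(un)) stop_config("input node not covered by mapping: %s",
                                paste(un, collapse = ", "))
  }
  tab <- analyte_table[, names(mapping), drop = FALSE]
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < 2) stop_config("need >= 2 subjects with complete mapped analytes")
  scaled <- vapply(seq_along(mapping), function(j) {
    v <- tab[[j]]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning(sprintf("analyte '%s' is constant; set to 0.5 for all subjects",
                      names(mapping)[j]))
      rep(0.5, length(v))
    } else (v - rng[1]) / (rng[2] - rng[1])
  }, numeric(nrow(tab)))
  colnames(scaled) <- unname(mapping)
  ids <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  lapply(seq_len(nrow(tab)), function(i)
    list(patient_id = ids[i], values = scaled[i, ]))
}

#' Normalized regulatory drive of a node
#'
#' omega = A (1 - I), where over the node's activators (weights alpha,
#' states x_a): A = [(1 + sum alpha)/sum alpha] * [sum alpha x_a /
#' (1 + sum alpha x_a)], A = 1 if the node has no activators; I is
#' defined identically over inhibitors, I = 0 without inhibitors. The
#' normalization makes omega = 1 under full activation with no
#' inhibition and omega = 0 under full inhibition.
#'
#' @param node node name (non-input).
#' @param state named numeric vector of activations in [0, 1] covering
#'   the node's regulators.
#' @param spec a \code{\link{network_spec}}.
#' @return omega in [0, 1].
#' @export
regulatory_input <- function(node, state, spec) {
  reg <- spec$regulators[[node]]
  if (is.null(reg)) stop_config("unknown node '%s'", node)
  if (spec$nodes$role[spec$nodes$name == node] == "input")
    stop_config("omega undefined for input node '%s'", node)
  part <- function(src, w) {
    if (!length(src)) return(NULL)
    sw <- sum(w)
    ((1 + sw) / sw) * (sum(w * state[src]) / (1 + sum(w * state[src])))
  }
  A <- part(reg$act, reg$act_w) %||% 1
  I <- part(reg$inh, reg$inh_w) %||% 0
  A * (1 - I)
}

#' Normalized sigmoid activation function
#'
#' s(omega; h) = [-e^{0.5 h} + e^{-h (omega - 0.5)}] /
#' [(1 - e^{0.5 h}) (1 + e^{-h (omega - 0.5)})]; strictly increasing with
#' s(0) = 0, s(0.5) = 0.5, s(1) = 1, steepness set by the gain h.
#'
#' @param omega regulatory drive in [0, 1].
#' @param h gain (> 0).
#' @return s in [0, 1].
#' @export
mendoza_sigmoid <- function(omega, h) {
  e1 <- exp(0.5 * h)
  e2 <- exp(-h * (omega - 0.5))
  (-e1 + e2) / ((1 - e1) * (1 + e2))
}

#' Synthesis-decay rate of a node
#'
#' dx/dt = s(omega; h) - gamma x.
#'
#' @param omega regulatory drive in [0, 1].
#' @param x current activation in [0, 1].
#' @param h sigmoid gain.
#' @param gamma decay rate.
#' @return the time derivative.
#' @export
node_rate <- function(omega, x, h, gamma) {
  mendoza_sigmoid(omega, h) - gamma * x
}

# Derivative closure over the free nodes; clamped nodes enter the state
# as constants. Free input nodes (initial-condition mode) have no
# regulators and simply decay.
rnm_derivs <- function(spec, free_nodes, clamped) {
  h <- stats::setNames(spec$nodes$h, spec$nodes$name)
  gamma <- stats::setNames(spec$nodes$gamma, spec$nodes$name)
  role <- stats::setNames(spec$nodes$role, spec$nodes$name)
  function(t, y, parms) {
    state <- c(y, clamped)
    dx <- vapply(free_nodes, function(nm) {
      if (role[nm] == "input") return(-gamma[nm] * state[nm])
      node_rate(regulatory_input(nm, state, spec), state[nm], h[nm], gamma[nm])
    }, numeric(1))
    list(dx)
  }
}

#' Integrate the network to steady state for one patient
#'
#' Input nodes are clamped at the patient's rescaled analyte levels
#' (default) or, with \code{inputs_as_ic = TRUE}, only initialized there
#' and left to decay. Remaining nodes are integrated with a
#' stiff-capable adaptive solver (\code{deSolve::lsodar}) until the
#' largest time derivative falls below \code{tol} or \code{t_max} is
#' reached. Activations are clipped to [0, 1] only to absorb solver
#' round-off.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param input regulatory input (\code{list(patient_id, values)}), values
#'   named by input node.
#' @param x0 initial activation for non-input nodes: a single value or a
#'   named vector (default 0.5, an unbiased mid state).
#' @param tol steady-state tolerance on max |dx/dt| (default 1e-6).
#' @param t_max maximum integration time (default 500).
#' @param inputs_as_ic if TRUE, inputs are free decaying states
#'   initialized at their rescaled values instead of being clamped.
#' @return object of class \code{steady_state}: \code{patient_id},
#'   \code{activations} (named, non-input nodes), \code{converged},
#'   \code{final_time}, \code{residual}.
#' @export
simulate_to_steady_state <- function(spec, input, x0 = 0.5, tol = 1e-6,
                                     t_max = 500, inputs_as_ic = FALSE) {
  input_nodes <- spec$nodes$name[spec$nodes$role == "input"]
  other <- setdiff(spec$nodes$name, input_nodes)
  miss <- setdiff(input_nodes, names(input$values))
  if (length(miss)) stop_config("input values missing for: %s",
                                paste(miss, collapse = ", "))
  iv <- input$values[input_nodes]
  if (any(iv < 0 | iv > 1)) stop_config("input activations must lie in [0, 1]")

  y0 <- if (length(x0) == 1) stats::setNames(rep(x0, length(other)), other)
        else x0[other]
  if (any(is.na(y0)) || any(y0 < 0 | y0 > 1))
    stop_config("x0 must cover all non-input nodes with values in [0, 1]")

  if (inputs_as_ic) {
    # inputs become free decaying states initialized at their values
    y0 <- c(y0, iv)
    deriv <- rnm_derivs(spec, names(y0),
                        clamped = stats::setNames(numeric(0), character(0)))
  } else {
    deriv <- rnm_derivs(spec, other, clamped = iv)
  }

  root <- function(t, y, parms) max(abs(unlist(deriv(t, y, parms)))) - tol
  sol <- deSolve::lsodar(y = y0, times = c(0, t_max), func = deriv,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-10, atol = 1e-12)
  if (anyNA(sol[nrow(sol), ]))
    stop("integration failed: solver returned NA state", call. = FALSE)
  tf <- sol[nrow(sol), 1]
  xf <- sol[nrow(sol), -1]
  residual <- max(abs(unlist(deriv(tf, xf, NULL))))
  if (any(xf < -1e-9 | xf > 1 + 1e-9))
    warning("trajectory left [0,1] beyond round-off")
  xf <- pmin(pmax(xf, 0), 1)
  # clamped mode reports the free (non-input) nodes; in the
  # initial-condition mode the inputs are dynamic states too
  keep_nodes <- if (inputs_as_ic) names(y0) else other
  structure(list(patient_id = input$patient_id,
                 activations = xf[keep_nodes],
                 converged = residual < tol,
                 final_time = tf,
                 residual = residual),
            class = "steady_state")
}

#' Simulate the network for a list of patients
#'
#' One steady state per patient; the returned table is restricted to the
#' output TF nodes. Non-converged patients are flagged in the
#' \code{converged} attribute, never dropped.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param inputs list of regulatory inputs (see
#'   \code{\link{rescale_inputs}}).
#' @param ... passed to \code{\link{simulate_to_steady_state}}.
#' @return a \code{\link{cohort_table}} of patient x TF activations
#'   (kind \code{tf}), with attributes \code{converged} (named logical)
#'   and \code{residuals}.
#' @export
batch_simulate <- function(spec, inputs, ...) {
  out_tf <- spec$nodes$name[spec$nodes$role == "output_tf"]
  states <- lapply(inputs, function(ri) simulate_to_steady_state(spec, ri, ...))
  dat <- data.frame(subject_id = vapply(states, `[[`, character(1), "patient_id"),
                    stringsAsFactors = FALSE)
  for (nm in out_tf)
    dat[[nm]] <- vapply(states, function(s) unname(s$activations[nm]), numeric(1))
  ct <- cohort_table(dat, stats::setNames(rep("tf", length(out_tf)), out_tf))
  attr(ct, "converged") <- stats::setNames(
    vapply(states, `[[`, logical(1), "converged"), dat$subject_id)
  attr(ct, "residuals") <- stats::setNames(
    vapply(states, `[[`, numeric(1), "residual"), dat$subject_id)
  if (!all(attr(ct, "converged")))
    warning(sprintf("%d patient(s) did not converge within t_max",
                    sum(!attr(ct, "converged"))))
  ct
}

#' Path to the bundled example chondrocyte-like network
#'
#' A small illustrative signed network with the 8 synovial-fluid input
#' nodes and 8 transcription-factor outputs used throughout the package
#' examples. Its topology is a plausible simplification (pro-inflammatory
#' inputs activate NF-kB/AP1 and repress FOXO/SOX9; IL-4 opposes them;
#' VEGF drives HIF2a/RUNX2); it does not claim fidelity to any published
#' chondrocyte model.
#'
#' @param what \code{"sif"}, \code{"roles"} or \code{"map"} (analyte ->
#'   input node mapping).
#' @return file path.
#' @export
example_network_path <- function(what = c("sif", "roles", "map")) {
  what <- match.arg(what)
  fn <- switch(what,
               sif = "chondrocyte_example.sif",
               roles = "chondrocyte_example_roles.yaml",
               map = "chondrocyte_example_map.yaml")
  system.file("extdata", fn, package = "oastratify", mustWork = TRUE)
}
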