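#' Describe one neuronal group
#'
#' A group is a homogeneous population: one cortical cell class in one
#' layer, firing with one Izhikevich phenotype and signalling through one
#' receptor class. Polarity is derived from the cell class: pyramidal and
#' spiny cells are excitatory, GABAergic cells inhibitory.
#'
#' @param name Unique group identifier, e.g. \code{"RS_p2"}.
#' @param cell_class One of \code{"pyramidal"}, \code{"spiny"},
#'   \code{"GABA_nb"}, \code{"GABA_b"}.
#' @param layer One of \code{"L1"}, \code{"L2"}, \code{"L2/3"}, \code{"L3"},
#'   \code{"L4"}, \code{"L5"}, \code{"L5/6"}, \code{"L6"}.
#' @param count Number of neurons (> 0).
#' @param spiking_type One of the labels of \code{\link{spiking_types}}.
#' @param receptor Receptor class the group's outgoing synapses act on:
#'   \code{"AMPA"}, \code{"NMDA"} or \code{"GABA"}.
#' @return One-row data frame with columns name, cell_class, layer, count,
#'   spiking_type, receptor, polarity.
#' @export
group_spec <- function(name, cell_class, layer, count, spiking_type, receptor) {
  polarity <- if (cell_class %in% c("pyramidal", "spiny")) "excitatory" else "inhibitory"
  data.frame(name = name, cell_class = cell_class, layer = layer,
             count = as.integer(count), spiking_type = spiking_type,
             receptor = receptor, polarity = polarity,
             stringsAsFactors = FALSE)
}

.cell_classes <- c("pyramidal", "spiny", "GABA_nb", "GABA_b")
.layers <- c("L1", "L2", "L2/3", "L3", "L4", "L5", "L5/6", "L6")
.receptors <- c("AMPA", "NMDA", "GABA")

#' Describe one group-to-group connection
#'
#' Each ordered pair of groups may carry one connection rule: every
#' (source neuron, target neuron) pair is wired independently with
#' probability \code{sparseness}, and each existing synapse adds
#' \code{weight} (mV) to the target's conductance variable for the source
#' group's receptor on every presynaptic spike. The sign of the effect is
#' carried by the receptor (GABA is subtractive), so weights are
#' non-negative.
#'
#' @param source,target Group names.
#' @param sparseness Connection probability in \[0, 1\].
#' @param weight Conductance increment per presynaptic spike, mV (>= 0).
#' @return One-row data frame.
#' @export
connection_spec <- function(source, target, sparseness = 0.1, weight = 10) {
  data.frame(source = source, target = target,
             sparseness = as.numeric(sparseness), weight = as.numeric(weight),
             stringsAsFactors = FALSE)
}

#' Assemble a network configuration
#'
#' Bundles the group table, connection table, noise specification, synapse
#' parameters, run settings, and the (default off) Hebbian plasticity block
#' into one validated object.
#'
#' @param groups Data frame of \code{\link{group_spec}} rows.
#' @param connections Data frame of \code{\link{connection_spec}} rows.
#' @param noise A \code{\link{noise_spec}}.
#' @param synapse A \code{\link{synapse_params}}.
#' @param plasticity A \code{\link{plasticity_spec}}.
#' @param duration Simulated time in ms (default 150).
#' @param dt Integration step in ms (default 0.5; the recording grid is
#'   always 1 ms).
#' @param seed Integer seed; all randomness (connectivity, initial
#'   conditions, noise, per-weight sweep runs) derives from it through
#'   named substreams.
#' @param expect_composition Optional named vector
#'   \code{c(excitatory = , inhibitory = )} of population fractions that
#'   \code{\link{validate_config}} additionally enforces.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(groups, connections, noise = noise_spec(),
                           synapse = synapse_params(),
                           plasticity = plasticity_spec(),
                           duration = 150, dt = 0.5, seed = 1L,
                           expect_composition = NULL) {
  cfg <- structure(
    list(groups = groups, connections = connections, noise = noise,
         synapse = synapse, plasticity = plasticity,
         run = list(duration = as.numeric(duration), dt = as.numeric(dt),
                    seed = as.integer(seed)),
         expect_composition = expect_composition),
    class = "network_config"
  )
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d groups, %d neurons (%d exc / %d inh), %d connections\n",
              nrow(x$groups), sum(x$groups$count),
              sum(x$groups$count[x$groups$polarity == "excitatory"]),
              sum(x$groups$count[x$groups$polarity == "inhibitory"]),
              nrow(x$connections)))
  cat(sprintf("  run: %g ms at dt = %g ms, seed %d\n",
              x$run$duration, x$run$dt, x$run$seed))
  invisible(x)
}

#' The default 17-group, 10,000-neuron cortical circuit
#'
#' Builds the layered cortical microcircuit used throughout the package:
#' 8 excitatory groups (pyramidal and spiny cells, 8000 neurons) and 9
#' inhibitory groups (GABAergic non-basket and basket cells, 2000 neurons),
#' each with its layer, count and firing phenotype; excitatory groups
#' signal through AMPA (layers 2/3 and 4) or NMDA (layer 5/6), inhibitory
#' groups through GABA. Every ordered pair of groups (including recurrent
#' self-connections) is wired at the given sparseness and weight, and
#' stochastic thalamic drive targets layers L2/3, L4 and L6.
#'
#' @param sparseness Connection probability for every group pair
#'   (default 0.1, the low end of the biologically motivated 0.1–0.2
#'   range).
#' @param weight Synaptic weight in mV applied to every connection
#'   (default 10).
#' @param duration,dt,seed Run settings, see \code{\link{network_config}}.
#' @return A \code{network_config}.
#' @export
#' @examples
#' cfg <- default_cortex_config()
#' sum(cfg$groups$count)
default_cortex_config <- function(sparseness = 0.1, weight = 10,
                                  duration = 150, dt = 0.5, seed = 1L) {
  groups <- rbind(
    group_spec("RS_p2",    "pyramidal", "L2/3", 2500, "RS", "AMPA"),
    group_spec("RS_p4",    "pyramidal", "L4",   1000, "RS", "AMPA"),
    group_spec("CH_p2",    "pyramidal", "L2/3",  500, "CH", "AMPA"),
    group_spec("IB_p5_1",  "pyramidal", "L5/6",  100, "IB", "NMDA"),
    group_spec("CH_p4",    "pyramidal", "L4",   1400, "CH", "AMPA"),
    group_spec("IB_p5_2",  "pyramidal", "L5/6",  500, "IB", "NMDA"),
    group_spec("RS_ss4_1", "spiny",     "L4",   1000, "RS", "AMPA"),
    group_spec("RS_ss4_2", "spiny",     "L2/3", 1000, "RS", "AMPA"),
    group_spec("LTS_nb1",  "GABA_nb",   "L1",    200, "LTS", "GABA"),
    group_spec("LTS_nb2",  "GABA_nb",   "L2",    400, "LTS", "GABA"),
    group_spec("LTS_nb4",  "GABA_nb",   "L4",    200, "LTS", "GABA"),
    group_spec("LTS_nb5",  "GABA_nb",   "L5",    100, "LTS", "GABA"),
    group_spec("LTS_nb6",  "GABA_nb",   "L6",    200, "LTS", "GABA"),
    group_spec("FS_b2",    "GABA_b",    "L2",    200, "FS", "GABA"),
    group_spec("FS_b4",    "GABA_b",    "L4",    400, "FS", "GABA"),
    group_spec("FS_b5",    "GABA_b",    "L5",    100, "FS", "GABA"),
    group_spec("FS_b6",    "GABA_b",    "L6",    200, "FS", "GABA")
  )
  pairs <- expand.grid(source = groups$name, target = groups$name,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  connections <- data.frame(source = pairs$source, target = pairs$target,
                            sparseness = sparseness, weight = weight,
                            stringsAsFactors = FALSE)
  network_config(groups, connections,
                 noise = noise_spec(),
                 duration = duration, dt = dt, seed = seed,
                 expect_composition = c(excitatory = 0.8, inhibitory = 0.2))
}

#' Validate a network configuration
#'
#' Checks every structural invariant of the configuration and returns the
#' violations found instead of throwing, so configurations can be linted.
#'
#' @param config A \code{network_config}.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
#' @examples
#' validate_config(default_cortex_config())
validate_config <- function(config) {
  v <- character(0)
  g <- config$groups
  if (anyDuplicated(g$name)) {
    v <- c(v, sprintf("groups: duplicated name(s): %s",
                      paste(unique(g$name[duplicated(g$name)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    if (!is.finite(r$count) || r$count <= 0) {
      v <- c(v, sprintf("group %s: count must be > 0 (got %s)", r$name, r$count))
    }
    if (!(r$cell_class %in% .cell_classes)) {
      v <- c(v, sprintf("group %s: unknown cell_class '%s'", r$name, r$cell_class))
    }
    if (!(r$layer %in% .layers)) {
      v <- c(v, sprintf("group %s: unknown layer '%s'", r$name, r$layer))
    }
    if (!(r$spiking_type %in% spiking_types())) {
      v <- c(v, sprintf("group %s: unknown spiking_type '%s'", r$name, r$spiking_type))
    }
    if (!(r$receptor %in% .receptors)) {
      v <- c(v, sprintf("group %s: unknown receptor '%s'", r$name, r$receptor))
    }
    exc <- r$cell_class %in% c("pyramidal", "spiny")
    if (exc != (r$polarity == "excitatory")) {
      v <- c(v, sprintf("group %s: polarity '%s' inconsistent with cell_class '%s'",
                        r$name, r$polarity, r$cell_class))
    }
    if (exc && r$receptor == "GABA") {
      v <- c(v, sprintf("group %s: excitatory group cannot use GABA receptor", r$name))
    }
    if (!exc && r$receptor != "GABA") {
      v <- c(v, sprintf("group %s: inhibitory group must use GABA receptor", r$name))
    }
  }
  cn <- config$connections
  for (i in seq_len(nrow(cn))) {
    r <- cn[i, ]
    if (!(r$source %in% g$name)) {
      v <- c(v, sprintf("connection %d: unknown source group '%s'", i, r$source))
    }
    if (!(r$target %in% g$name)) {
      v <- c(v, sprintf("connection %d: unknown target group '%s'", i, r$target))
    }
    if (!is.finite(r$sparseness) || r$sparseness < 0 || r$sparseness > 1) {
      v <- c(v, sprintf("connection %d (%s -> %s): sparseness %s outside [0, 1]",
                        i, r$source, r$target, r$sparseness))
    }
    if (!is.finite(r$weight) || r$weight < 0) {
      v <- c(v, sprintf("connection %d (%s -> %s): weight %s must be >= 0",
                        i, r$source, r$target, r$weight))
    }
  }
  if (!is.null(config$run)) {
    if (config$run$dt <= 0 || config$run$dt > 1) {
      v <- c(v, sprintf("run: dt %s outside (0, 1] ms", config$run$dt))
    }
    if (config$run$duration <= 0) {
      v <- c(v, "run: duration must be > 0")
    }
  }
  if (!is.null(config$expect_composition)) {
    total <- sum(g$count)
    frac_exc <- sum(g$count[g$polarity == "excitatory"]) / total
    want <- config$expect_composition[["excitatory"]]
    if (abs(frac_exc - want) > 1e-12) {
      v <- c(v, sprintf("composition: excitatory fraction %.4f differs from expected %.2f",
                        frac_exc, want))
    }
  }
  v
}

# Index bookkeeping: global 0-based contiguous neuron ids, groups in config
# order. Returns per-group offset/count plus per-neuron lookup vectors.
group_index <- function(config) {
  g <- config$groups
  count <- g$count
  offset <- cumsum(c(0L, count))[seq_len(nrow(g))]
  n <- sum(count)
  list(
    name = g$name, offset = offset, count = count, n = n,
    group_of = rep.int(seq_len(nrow(g)), count),
    polarity = g$polarity, receptor = g$receptor, layer = g$layer,
    spiking_type = g$spiking_type
  )
}

#' Sample the synaptic adjacency of a configured network
#'
#' Realises the connection rules as an explicit synapse list: for each
#' group-to-group connection, every (source, target) neuron pair is wired
#' independently with the connection's sparseness; autapses (a neuron onto
#' itself) are excluded in recurrent connections. The result also carries
#' one sparse weight matrix per receptor class, used by the engine for
#' spike propagation. Deterministic given the seed.
#'
#' @param config A valid \code{network_config}.
#' @param seed Integer seed (default: the connectivity substream of the
#'   config's run seed).
#' @return An object of class \code{adjacency}: list with \code{n} (total
#'   neurons), \code{index} (group index table), \code{edges} (data frame
#'   \code{source, target, weight, receptor} with 0-based neuron ids) and
#'   \code{W} (named list of source-by-target \code{dgCMatrix} weight
#'   matrices, one per receptor).
#' @export
#' @examples
#' cfg <- make_fixture(2, 10, seed = 7)
#' adj <- build_adjacency(cfg)
#' nrow(adj$edges)
build_adjacency <- function(config, seed = NULL) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid_config: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  if (is.null(seed)) seed <- substream_seed(config$run$seed, "connectivity")
  idx <- group_index(config)
  cn <- config$connections
  gi <- match(cn$source, idx$name)
  ti <- match(cn$target, idx$name)

  src_list <- vector("list", nrow(cn))
  tgt_list <- vector("list", nrow(cn))
  for (k in seq_len(nrow(cn))) {
    set.seed(substream_seed(seed, "conn", k))
    ns <- idx$count[gi[k]]
    nt <- idx$count[ti[k]]
    recurrent <- gi[k] == ti[k]
    n_pairs <- if (recurrent) ns * (nt - 1) else ns * nt
    p <- cn$sparseness[k]
    if (n_pairs <= 0 || p <= 0) next
    m <- stats::rbinom(1L, n_pairs, p)
    if (m == 0) next
    cell <- sample.int(n_pairs, m)
    si <- (cell - 1L) %% ns + 1L
    if (recurrent) {
      jr <- (cell - 1L) %/% ns + 1L     # 1..(n-1), diagonal skipped
      tj <- jr + (jr >= si)
    } else {
      tj <- (cell - 1L) %/% ns + 1L
    }
    src_list[[k]] <- idx$offset[gi[k]] + si   # 0-based global + 1-based local
    tgt_list[[k]] <- idx$offset[ti[k]] + tj
  }
  conn_len <- lengths(src_list)
  src <- unlist(src_list, use.names = FALSE)
  tgt <- unlist(tgt_list, use.names = FALSE)
  if (is.null(src)) src <- integer(0)
  if (is.null(tgt)) tgt <- integer(0)
  wt <- rep.int(cn$weight, conn_len)
  receptor <- rep.int(config$groups$receptor[gi], conn_len)

  W <- lapply(.receptors, function(r) {
    sel <- receptor == r
    Matrix::sparseMatrix(i = src[sel], j = tgt[sel], x = wt[sel],
                         dims = c(idx$n, idx$n))
  })
  names(W) <- .receptors

  structure(
    list(n = idx$n, index = idx,
         edges = data.frame(source = src - 1L, target = tgt - 1L,
                            weight = wt, receptor = receptor,
                            stringsAsFactors = FALSE),
         W = W, seed = seed),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d neurons, %d synapses (AMPA %d, NMDA %d, GABA %d)\n",
              x$n, nrow(x$edges),
              sum(x$edges$receptor == "AMPA"),
              sum(x$edges$receptor == "NMDA"),
              sum(x$edges$receptor == "GABA")))
  invisible(x)
}

#' Write an adjacency edge list to CSV
#'
#' Columns \code{source_id,target_id,weight_mV,receptor}; neuron ids are
#' global 0-based indices in config group order.
#'
#' @param adj An \code{adjacency}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  df <- adj$edges
  names(df) <- c("source_id", "target_id", "weight_mV", "receptor")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scale a configuration's population down (or up)
#'
#' Multiplies every group count by \code{factor} (rounded, floored at 1
#' neuron), preserving composition ratios, connectivity rules and all other
#' settings. Used for reduced replications of the full circuit.
#'
#' @param config A \code{network_config}.
#' @param factor Positive scaling factor, e.g. 0.1 for a tenth-size
#'   network.
#' @return The scaled \code{network_config}.
#' @export
#' @examples
#' sum(scale_config(default_cortex_config(), 0.1)$groups$count)
scale_config <- function(config, factor) {
  stopifnot(is.numeric(factor), factor > 0)
  config$groups$count <- pmax(1L, as.integer(round(config$groups$count * factor)))
  # exact fractions no longer guaranteed after rounding
  config$expect_composition <- NULL
  config
}
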