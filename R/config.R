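# Configuration file I/O, the miniature test fixture, and run manifests.

.top_keys <- c("groups", "connections", "noise", "synapse", "plasticity",
               "run", "expect_composition")
.group_keys <- c("name", "cell_class", "layer", "count", "spiking_type",
                 "receptor")
.conn_keys <- c("source", "target", "sparseness", "weight")

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0) {
    stop(sprintf("config_schema: unknown key(s) in %s: %s",
                 where, paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load a network configuration from YAML
#'
#' Parses, applies defaults, and fully validates a configuration file.
#' \code{groups} is a list of group blocks; \code{connections} is either an
#' explicit list of connection blocks or the shorthand
#' \code{\{rule: all_pairs, sparseness: , weight: \}} wiring every ordered
#' group pair. Unknown keys anywhere are rejected with the offending field
#' named; structural violations are reported via
#' \code{\link{validate_config}}.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{network_config}.
#' @export
#' @examples
#' path <- system.file("extdata", "cortex_default.yaml", package = "izhnet")
#' cfg <- load_config(path)
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, .top_keys, "top level")
  if (is.null(raw$groups)) stop("config_schema: missing 'groups'", call. = FALSE)

  groups <- do.call(rbind, lapply(seq_along(raw$groups), function(i) {
    gb <- raw$groups[[i]]
    check_keys(gb, .group_keys, sprintf("groups[%d]", i))
    missing <- setdiff(.group_keys, names(gb))
    if (length(missing) > 0) {
      stop(sprintf("config_schema: groups[%d] missing field(s): %s",
                   i, paste(missing, collapse = ", ")), call. = FALSE)
    }
    group_spec(gb$name, gb$cell_class, gb$layer, gb$count,
               gb$spiking_type, gb$receptor)
  }))

  cn <- raw$connections
  if (is.null(cn)) {
    connections <- data.frame(source = character(0), target = character(0),
                              sparseness = numeric(0), weight = numeric(0))
  } else if (!is.null(cn$rule)) {
    check_keys(cn, c("rule", "sparseness", "weight"), "connections")
    if (cn$rule != "all_pairs") {
      stop("config_schema: connections.rule must be 'all_pairs'", call. = FALSE)
    }
    pairs <- expand.grid(source = groups$name, target = groups$name,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    connections <- data.frame(source = pairs$source, target = pairs$target,
                              sparseness = cn$sparseness %||% 0.1,
                              weight = cn$weight %||% 10,
                              stringsAsFactors = FALSE)
  } else {
    connections <- do.call(rbind, lapply(seq_along(cn), function(i) {
      cb <- cn[[i]]
      check_keys(cb, .conn_keys, sprintf("connections[%d]", i))
      connection_spec(cb$source, cb$target,
                      cb$sparseness %||% 0.1, cb$weight %||% 10)
    }))
  }

  nb <- raw$noise %||% list()
  check_keys(nb, c("target_layers", "sigma_exc", "sigma_inh", "bias"), "noise")
  noise <- noise_spec(
    target_layers = unlist(nb$target_layers) %||% c("L2/3", "L4", "L6"),
    sigma_exc = nb$sigma_exc %||% 5,
    sigma_inh = nb$sigma_inh %||% 2,
    bias = nb$bias %||% 0
  )

  sb <- raw$synapse %||% list()
  check_keys(sb, c("tau_ampa", "tau_nmda", "tau_gaba", "coupling",
                   "e_exc", "e_inh", "g_init_max", "scale", "gain"), "synapse")
  synapse <- synapse_params(
    tau_ampa = sb$tau_ampa %||% 5, tau_nmda = sb$tau_nmda %||% 150,
    tau_gaba = sb$tau_gaba %||% 10, coupling = sb$coupling %||% "current",
    e_exc = sb$e_exc %||% 0, e_inh = sb$e_inh %||% -70,
    g_init_max = sb$g_init_max %||% 1, scale = sb$scale %||% "indegree",
    gain = sb$gain %||% 1.5
  )

  pb <- raw$plasticity %||% list()
  check_keys(pb, c("enabled", "eta", "epoch_ms"), "plasticity")
  plasticity <- plasticity_spec(
    enabled = isTRUE(pb$enabled), eta = pb$eta %||% 0.01,
    epoch_ms = pb$epoch_ms %||% 50
  )

  rb <- raw$run %||% list()
  check_keys(rb, c("duration", "dt", "seed"), "run")

  comp <- NULL
  if (!is.null(raw$expect_composition)) {
    check_keys(raw$expect_composition, c("excitatory", "inhibitory"),
               "expect_composition")
    comp <- c(excitatory = raw$expect_composition$excitatory,
              inhibitory = raw$expect_composition$inhibitory)
  }

  cfg <- network_config(groups, connections, noise = noise, synapse = synapse,
                        plasticity = plasticity,
                        duration = rb$duration %||% 150,
                        dt = rb$dt %||% 0.5, seed = rb$seed %||% 1L,
                        expect_composition = comp)
  viol <- validate_config(cfg)
  if (length(viol) > 0) {
    stop("config_invalid: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  cfg
}

#' Save a network configuration to YAML
#'
#' Writes the fully expanded configuration (explicit connection list) so
#' that \code{save_config} then \code{\link{load_config}} round-trips to an
#' equal configuration.
#'
#' @param config A \code{network_config}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  g <- config$groups
  out <- list(
    groups = lapply(seq_len(nrow(g)), function(i) {
      as.list(g[i, .group_keys])
    }),
    connections = lapply(seq_len(nrow(config$connections)), function(i) {
      as.list(config$connections[i, .conn_keys])
    }),
    noise = unclass(config$noise),
    synapse = list(
      tau_ampa = unname(config$synapse$tau[["AMPA"]]),
      tau_nmda = unname(config$synapse$tau[["NMDA"]]),
      tau_gaba = unname(config$synapse$tau[["GABA"]]),
      coupling = config$synapse$coupling,
      e_exc = config$synapse$e_exc, e_inh = config$synapse$e_inh,
      g_init_max = config$synapse$g_init_max,
      scale = config$synapse$scale, gain = config$synapse$gain
    ),
    plasticity = unclass(config$plasticity),
    run = config$run
  )
  if (!is.null(config$expect_composition)) {
    out$expect_composition <- as.list(config$expect_composition)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Miniature network fixture
#'
#' A small two-phenotype circuit for fast tests and examples: excitatory
#' regular-spiking pyramidal groups (AMPA, layer L2/3) alternate with
#' inhibitory fast-spiking basket groups (GABA, layer L4) — both layers sit
#' in the default thalamic noise target set — wired all-to-all-pairs at
#' sparseness 0.5 and weight 5 mV.
#'
#' @param n_groups Number of groups (>= 2; alternating polarity, starting
#'   excitatory).
#' @param neurons_per_group Neurons per group (>= 2).
#' @param seed Integer seed stored in the config.
#' @param duration,dt Run settings (defaults 150 ms, 0.5 ms).
#' @return A validated \code{network_config}.
#' @export
#' @examples
#' make_fixture(2, 10, seed = 1)
make_fixture <- function(n_groups = 2, neurons_per_group = 10, seed = 1L,
                         duration = 150, dt = 0.5) {
  stopifnot(n_groups >= 2, neurons_per_group >= 2)
  groups <- do.call(rbind, lapply(seq_len(n_groups), function(i) {
    if (i %% 2 == 1) {
      group_spec(sprintf("RS_e%d", i), "pyramidal", "L2/3",
                 neurons_per_group, "RS", "AMPA")
    } else {
      group_spec(sprintf("FS_i%d", i), "GABA_b", "L4",
                 neurons_per_group, "FS", "GABA")
    }
  }))
  pairs <- expand.grid(source = groups$name, target = groups$name,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  connections <- data.frame(source = pairs$source, target = pairs$target,
                            sparseness = 0.5, weight = 5,
                            stringsAsFactors = FALSE)
  network_config(groups, connections, duration = duration, dt = dt,
                 seed = seed)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration hash
#' (stable under key reordering), the seed, the package version, a
#' timestamp, and the output files produced.
#'
#' @param out_dir Directory the run wrote to.
#' @param config The \code{network_config} used.
#' @param seed The seed used.
#' @param files Character vector of output files.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed, files) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = as.integer(seed),
    package = "izhnet",
    version = as.character(utils::packageVersion("izhnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
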