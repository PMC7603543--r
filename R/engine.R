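#' Simulate a configured cortical network
#'
#' Advances the whole network state through time with a fixed-step scheme.
#' Each integration step: (1) the input current of every neuron is
#' assembled as thalamic noise plus synaptic drive from the conductances;
#' (2) all neurons take one Izhikevich step with reset; (3) conductances
#' decay; (4) this step's spikes are delivered to their targets, so a spike
#' influences targets from the next step onward (an implicit one-step
#' synaptic delay). Observables are recorded on a 1 ms grid regardless of
#' \code{dt}.
#'
#' Initial conditions: \code{v} starts at the group's reset potential plus
#' uniform jitter on \[0, 5) mV to break symmetry, \code{u = b v};
#' conductances start uniform on \[0, 1). Everything is deterministic given
#' the seed.
#'
#' @param config A valid \code{network_config}.
#' @param seed Integer seed; defaults to the config's run seed.
#' @param record_v If \code{TRUE} (default) keep the full membrane-potential
#'   matrix (neurons x ms), the substrate of the synchrony measure. Samples
#'   in a millisecond during which the neuron spiked are clamped to 30 mV
#'   so spikes have uniform height.
#' @param adjacency Optional pre-built \code{\link{build_adjacency}} result
#'   to reuse; by default it is sampled from the config.
#' @param verbose Log progress to stderr every 10 simulated ms.
#' @return An object of class \code{recording_set}: \code{raster} (data
#'   frame \code{t_ms, neuron_id, group}; ids 0-based), \code{traces}
#'   (named list, one data frame \code{t_ms, v_mV, u, g_ampa, g_nmda,
#'   g_gaba} per probe neuron — the first neuron of each group),
#'   \code{rates} (data frame \code{t_ms, group, count} of spikes per group
#'   per 1 ms bin), \code{v} (the trace matrix or \code{NULL}), plus run
#'   metadata.
#' @export
#' @examples
#' cfg <- make_fixture(2, 20, seed = 3)
#' rec <- run_network(cfg)
#' nrow(rec$raster)
run_network <- function(config, seed = NULL, record_v = TRUE,
                        adjacency = NULL, verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid_config: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  if (is.null(seed)) seed <- config$run$seed
  dt <- config$run$dt
  duration <- config$run$duration
  sub_per_ms <- round(1 / dt)
  if (abs(sub_per_ms * dt - 1) > 1e-9) {
    stop("bad_dt: dt must divide the 1 ms recording grid", call. = FALSE)
  }
  n_ms <- round(duration)
  n_steps <- n_ms * sub_per_ms

  if (is.null(adjacency)) {
    adjacency <- build_adjacency(config, substream_seed(seed, "connectivity"))
  }
  idx <- adjacency$index
  n <- idx$n

  # per-neuron phenotype parameters
  ptab <- do.call(rbind, lapply(idx$spiking_type, function(tt) {
    p <- phenotype_parameters(tt)
    c(p$a, p$b, p$c, p$d)
  }))
  pars <- list(a = ptab[idx$group_of, 1], b = ptab[idx$group_of, 2],
               c = ptab[idx$group_of, 3], d = ptab[idx$group_of, 4])

  set.seed(substream_seed(seed, "init"))
  v <- pars$c + stats::runif(n, 0, 5)
  u <- pars$b * v
  g <- init_synaptic_state(n, config$synapse, substream_seed(seed, "synapse_init"))
  sigma <- noise_sigma_vector(config$noise, idx)
  noise_seed <- substream_seed(seed, "noise_stream")

  # per-neuron gain on the recurrent drive (see synapse_params 'scale')
  syn_gain <- (config$synapse$gain %||% 1.5) *
    if ((config$synapse$scale %||% "indegree") == "indegree") {
      1 / pmax(1L, tabulate(adjacency$edges$target + 1L, nbins = n))
    } else {
      1
    }

  probe_ids <- idx$offset + 1L        # first neuron of each group (1-based)
  n_groups <- length(idx$name)
  trace_cols <- c("t_ms", "v_mV", "u", "g_ampa", "g_nmda", "g_gaba")
  probe_buf <- array(NA_real_, dim = c(n_ms, length(trace_cols), n_groups))
  rate_buf <- matrix(0L, nrow = n_ms, ncol = n_groups)
  v_buf <- if (record_v) matrix(NA_real_, nrow = n, ncol = n_ms) else NULL

  raster_t <- vector("list", n_ms)
  raster_id <- vector("list", n_ms)
  spiked_in_ms <- logical(n)

  plast <- config$plasticity
  epoch_counts <- if (isTRUE(plast$enabled)) integer(n) else NULL

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    I <- noise_current(config$noise, sigma, step, noise_seed) +
      syn_gain * synaptic_current(g, config$synapse, v)
    st <- izh_step(v, u, I, pars, dt)
    v <- st$v
    u <- st$u
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop(sprintf(
        "numerical_explosion: neuron %d (group %s) became non-finite at t = %g ms",
        bad - 1L, idx$name[idx$group_of[bad]], t_now), call. = FALSE)
    }
    g <- decay_step(g, config$synapse$tau, dt)
    spiked <- st$spiked
    if (any(spiked)) {
      g <- apply_spikes(g, adjacency, spiked)
      spiked_in_ms <- spiked_in_ms | spiked
      ms_bin <- ceiling(t_now - 1e-9)
      ids <- which(spiked)
      raster_t[[ms_bin]] <- c(raster_t[[ms_bin]], rep.int(t_now, length(ids)))
      raster_id[[ms_bin]] <- c(raster_id[[ms_bin]], ids)
      cnt <- tabulate(idx$group_of[ids], nbins = n_groups)
      rate_buf[ms_bin, ] <- rate_buf[ms_bin, ] + cnt
      if (!is.null(epoch_counts)) {
        epoch_counts[ids] <- epoch_counts[ids] + 1L
      }
    }
    if (step %% sub_per_ms == 0L) {
      ms <- step %/% sub_per_ms
      v_rec <- ifelse(spiked_in_ms, 30, v)
      if (record_v) v_buf[, ms] <- v_rec
      probe_buf[ms, 1, ] <- ms
      probe_buf[ms, 2, ] <- v_rec[probe_ids]
      probe_buf[ms, 3, ] <- u[probe_ids]
      probe_buf[ms, 4, ] <- g$AMPA[probe_ids]
      probe_buf[ms, 5, ] <- g$NMDA[probe_ids]
      probe_buf[ms, 6, ] <- g$GABA[probe_ids]
      spiked_in_ms[] <- FALSE
      if (verbose && ms %% 10 == 0) {
        message(sprintf("[izhnet] t = %d / %d ms", ms, n_ms))
      }
      if (!is.null(epoch_counts) && ms %% plast$epoch_ms == 0L) {
        adjacency <- apply_plasticity(adjacency, epoch_counts, plast$eta)
        epoch_counts[] <- 0L
      }
    }
  }

  raster <- data.frame(
    t_ms = unlist(raster_t) %||% numeric(0),
    neuron_id = (unlist(raster_id) %||% integer(0)) - 1L,
    stringsAsFactors = FALSE
  )
  raster$group <- if (nrow(raster) > 0) idx$name[idx$group_of[raster$neuron_id + 1L]] else character(0)

  traces <- lapply(seq_len(n_groups), function(k) {
    df <- as.data.frame(probe_buf[, , k, drop = TRUE])
    names(df) <- trace_cols
    df
  })
  names(traces) <- idx$name

  rates <- data.frame(
    t_ms = rep(seq_len(n_ms), times = n_groups),
    group = rep(idx$name, each = n_ms),
    count = as.integer(rate_buf),
    stringsAsFactors = FALSE
  )

  structure(
    list(raster = raster, traces = traces, rates = rates, v = v_buf,
         groups = idx$name, group_of = idx$group_of,
         duration = n_ms, dt = dt, seed = seed,
         config_hash = config_hash(config)),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d ms, %d spike events, %d groups%s\n",
              x$duration, nrow(x$raster), length(x$groups),
              if (is.null(x$v)) "" else sprintf(", v matrix %d x %d",
                                                nrow(x$v), ncol(x$v))))
  invisible(x)
}

#' Extract the membrane-trace matrix of one group
#'
#' @param rec A \code{recording_set} produced with \code{record_v = TRUE}.
#' @param group Group name.
#' @return Numeric matrix, neurons of the group x ms samples.
#' @export
group_traces <- function(rec, group) {
  if (is.null(rec$v)) stop("recording has no membrane matrix (record_v = FALSE)",
                           call. = FALSE)
  k <- match(group, rec$groups)
  if (is.na(k)) stop("unknown group '", group, "'", call. = FALSE)
  rec$v[rec$group_of == k, , drop = FALSE]
}

#' Write a recording set to CSV files
#'
#' Writes \code{raster.csv} (\code{t_ms,neuron_id,group}),
#' \code{rates.csv} (\code{t_ms,group,count}) and one
#' \code{trace_<group>.csv} per probe neuron
#' (\code{t_ms,v_mV,u,g_ampa,g_nmda,g_gaba}) into \code{out_dir}.
#' The files round-trip losslessly through \code{\link{read_recordings}}.
#'
#' @param rec A \code{recording_set}.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_recordings <- function(rec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir,
                                 call. = FALSE)
  files <- character(0)
  p <- file.path(out_dir, "raster.csv")
  utils::write.csv(format_num_df(rec$raster), p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)
  p <- file.path(out_dir, "rates.csv")
  utils::write.csv(rec$rates, p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)
  for (gname in names(rec$traces)) {
    p <- file.path(out_dir, paste0("trace_", gsub("[^A-Za-z0-9_]", "_", gname), ".csv"))
    utils::write.csv(format_num_df(rec$traces[[gname]]), p,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}

# Full-precision numeric formatting so CSVs are byte-stable and lossless.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Read back a recording set written by \code{\link{write_recordings}}
#'
#' @param dir Directory containing the CSV files.
#' @return A list with \code{raster}, \code{rates} and \code{traces} in the
#'   same shapes as the corresponding \code{recording_set} fields.
#' @export
read_recordings <- function(dir) {
  raster <- utils::read.csv(file.path(dir, "raster.csv"),
                            colClasses = c("numeric", "integer", "character"))
  rates <- utils::read.csv(file.path(dir, "rates.csv"),
                           colClasses = c("integer", "character", "integer"))
  trace_files <- list.files(dir, pattern = "^trace_.*\\.csv$", full.names = TRUE)
  traces <- lapply(trace_files, utils::read.csv)
  names(traces) <- sub("^trace_(.*)\\.csv$", "\\1", basename(trace_files))
  list(raster = raster, rates = rates, traces = traces)
}
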