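test_that("a quiescent network stays silent", {
  cfg <- quiet_config(n_per_group = 5, weight = 0, sigma = 0,
                      g_init_max = 0, duration = 150)
  rec <- run_network(cfg, seed = 8)
  expect_equal(nrow(rec$raster), 0)
  expect_true(all(rec$rates$count == 0))
  # resting potentials stay below cutoff the whole run
  expect_true(all(rec$v < 30))
})

test_that("an isolated neuron in the engine matches the single-neuron model event for event", {
  # one excitatory group of 2 unconnected neurons under constant drive
  groups <- rbind(group_spec("E", "pyramidal", "L2/3", 2, "RS", "AMPA"),
                  group_spec("F", "pyramidal", "L5", 2, "RS", "AMPA"))
  cfg <- network_config(groups,
                        connection_spec("E", "F", sparseness = 0, weight = 0),
                        noise = noise_spec(sigma_exc = 0, sigma_inh = 0,
                                           bias = 10),
                        synapse = synapse_params(g_init_max = 0),
                        duration = 300, seed = 21L)
  rec <- run_network(cfg, seed = 21)

  # reproduce the engine's jittered initial conditions for neuron 1
  p <- phenotype_parameters("RS")
  set.seed(izhnet:::substream_seed(21, "init"))
  v0 <- p$c + runif(4, 0, 5)[1]
  iso <- simulate_neuron(p, I = 10, duration = 300, dt = 0.5,
                         v0 = v0, u0 = p$b * v0)
  engine_spikes <- rec$raster$t_ms[rec$raster$neuron_id == 0]
  expect_equal(sort(engine_spikes), iso$spike_times)
  expect_gt(length(engine_spikes), 3)
})

test_that("raster events and rate bins conserve the same spike count", {
  cfg <- make_fixture(3, 20, seed = 6)
  rec <- run_network(cfg, seed = 6)
  expect_gt(nrow(rec$raster), 0)
  expect_equal(sum(rec$rates$count), nrow(rec$raster))
  # per group and per bin
  for (gname in rec$groups) {
    r <- rec$rates[rec$rates$group == gname, ]
    ev <- rec$raster[rec$raster$group == gname, ]
    expect_equal(sum(r$count), nrow(ev))
    if (nrow(ev) > 0) {
      bins <- table(ceiling(ev$t_ms - 1e-9))
      expect_equal(unname(r$count[match(as.integer(names(bins)), r$t_ms)]),
                   as.integer(bins))
    }
  }
  # every raster event carries a valid provenance: id and ms within range
  expect_true(all(rec$raster$neuron_id >= 0 &
                    rec$raster$neuron_id < sum(cfg$groups$count)))
  expect_true(all(rec$raster$t_ms > 0 & rec$raster$t_ms <= rec$duration))
})

test_that("identical config and seed give byte-identical recordings", {
  cfg <- make_fixture(2, 25, seed = 14)
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  write_recordings(run_network(cfg, seed = 14), d1)
  write_recordings(run_network(cfg, seed = 14), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("recordings round-trip through CSV", {
  cfg <- make_fixture(2, 10, seed = 31, duration = 60)
  rec <- run_network(cfg, seed = 31)
  dir <- file.path(tempdir(), "roundtrip")
  write_recordings(rec, dir)
  back <- read_recordings(dir)
  expect_equal(back$raster, rec$raster)
  expect_equal(back$rates, rec$rates)
  expect_setequal(names(back$traces), names(rec$traces))
  for (gname in names(rec$traces)) {
    expect_equal(back$traces[[gname]], rec$traces[[gname]])
  }
  unlink(dir, recursive = TRUE)
})

test_that("an empty recording still writes header-only files", {
  cfg <- quiet_config(duration = 20)
  rec <- run_network(cfg, seed = 2)
  dir <- file.path(tempdir(), "empty_rec")
  write_recordings(rec, dir)
  raster_lines <- readLines(file.path(dir, "raster.csv"))
  expect_equal(raster_lines, "t_ms,neuron_id,group")
  back <- read_recordings(dir)
  expect_equal(nrow(back$raster), 0)
  unlink(dir, recursive = TRUE)
})

test_that("probe traces clamp spikes to 30 mV and track the first neuron of each group", {
  cfg <- make_fixture(2, 10, seed = 17)
  cfg$noise <- noise_spec(sigma_exc = 8, sigma_inh = 8)
  rec <- run_network(cfg, seed = 17)
  expect_identical(names(rec$traces), rec$groups)
  for (tr in rec$traces) {
    expect_identical(names(tr), c("t_ms", "v_mV", "u", "g_ampa", "g_nmda", "g_gaba"))
    expect_true(all(tr$v_mV <= 30))
    expect_equal(tr$t_ms, seq_len(rec$duration))
  }
  # probe rows equal the corresponding rows of the full membrane matrix
  offs <- cumsum(c(0, cfg$groups$count))[1:2] + 1
  for (k in 1:2) {
    expect_equal(rec$traces[[k]]$v_mV, unname(rec$v[offs[k], ]))
  }
})

test_that("decoupled connectivity (weight 0) equals absent connectivity", {
  cfg0 <- quiet_config(n_per_group = 10, weight = 0, sigma = 4,
                       g_init_max = 0, duration = 100, seed = 3L)
  rec0 <- run_network(cfg0, seed = 3)
  cfg_none <- cfg0
  cfg_none$connections <- cfg_none$connections[0, ]
  rec_none <- run_network(cfg_none, seed = 3)
  expect_equal(rec0$raster, rec_none$raster)
  expect_equal(rec0$v, rec_none$v)
})
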