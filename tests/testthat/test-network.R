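test_that("default cortical circuit reproduces the published composition", {
  cfg <- default_cortex_config()
  g <- cfg$groups
  expect_equal(sum(g$count), 10000)
  expect_equal(sum(g$count[g$polarity == "excitatory"]), 8000)
  expect_equal(sum(g$count[g$polarity == "inhibitory"]), 2000)
  expect_equal(sum(g$count[g$polarity == "excitatory"]) / sum(g$count), 0.80)

  # per-row counts of the excitatory and inhibitory tables
  expect_equal(g$count[g$name == "RS_p2"], 2500)
  expect_equal(g$layer[g$name == "RS_p2"], "L2/3")
  expect_equal(g$spiking_type[g$name == "RS_p2"], "RS")
  exc_counts <- c(2500, 1000, 500, 100, 1400, 500, 1000, 1000)
  inh_counts <- c(200, 400, 200, 100, 200, 200, 400, 100, 200)
  expect_equal(g$count[g$polarity == "excitatory"], exc_counts)
  expect_equal(g$count[g$polarity == "inhibitory"], inh_counts)

  # receptor assignment: AMPA for L2/3+L4 pyramidal and all spiny cells,
  # NMDA for deep-layer pyramidal, GABA for every inhibitory group
  expect_true(all(g$receptor[g$cell_class == "spiny"] == "AMPA"))
  expect_true(all(g$receptor[g$cell_class == "pyramidal" &
                               g$layer %in% c("L2/3", "L4")] == "AMPA"))
  expect_true(all(g$receptor[g$cell_class == "pyramidal" &
                               g$layer == "L5/6"] == "NMDA"))
  expect_true(all(g$receptor[g$polarity == "inhibitory"] == "GABA"))

  # full bidirectional block connectivity at sparseness 0.1
  expect_equal(nrow(cfg$connections), 17^2)
  expect_true(all(cfg$connections$sparseness == 0.1))
  expect_length(validate_config(cfg), 0)
})

test_that("validation reports violations instead of throwing", {
  cfg <- default_cortex_config()
  bad <- cfg
  bad$connections <- rbind(bad$connections,
                           connection_spec("RS_p2", "NOT_A_GROUP"))
  v <- validate_config(bad)
  expect_length(v, 1)
  expect_match(v, "NOT_A_GROUP")

  bad2 <- cfg
  bad2$connections$sparseness[3] <- 1.5
  expect_match(validate_config(bad2), "sparseness")

  bad3 <- cfg
  bad3$groups$count[1] <- -5
  v3 <- validate_config(bad3)
  expect_true(any(grepl("count", v3)))
  # composition check also trips once a count changes
  expect_true(any(grepl("composition", v3)))

  bad4 <- cfg
  bad4$groups$receptor[1] <- "GABA"   # excitatory group, inhibitory receptor
  expect_true(any(grepl("GABA", validate_config(bad4))))
  expect_error(build_adjacency(bad4), "invalid_config")
})

test_that("adjacency sampling honours sparseness limits and excludes autapses", {
  cfg <- make_fixture(2, 10, seed = 9)

  cfg$connections$sparseness <- 0
  expect_equal(nrow(build_adjacency(cfg)$edges), 0)

  cfg$connections$sparseness <- 1
  adj <- build_adjacency(cfg)
  e <- adj$edges
  # complete bipartite blocks of 10x10 between groups; recurrent blocks
  # are complete minus the diagonal
  expect_equal(nrow(e), 2 * 100 + 2 * 90)
  expect_false(any(e$source == e$target))
  expect_true(all(e$weight == cfg$connections$weight[1]))

  # distinct groups of 10 and 20 at sparseness 1: exactly 200 edges
  g2 <- rbind(group_spec("A", "pyramidal", "L2/3", 10, "RS", "AMPA"),
              group_spec("B", "pyramidal", "L4", 20, "RS", "AMPA"))
  c2 <- connection_spec("A", "B", sparseness = 1, weight = 2)
  adj2 <- build_adjacency(network_config(g2, c2, seed = 1))
  expect_equal(nrow(adj2$edges), 200)
})

test_that("edge counts are binomial in distribution across seeds", {
  g <- rbind(group_spec("A", "pyramidal", "L2/3", 100, "RS", "AMPA"),
             group_spec("B", "pyramidal", "L4", 100, "RS", "AMPA"))
  cfg <- network_config(g, connection_spec("A", "B", sparseness = 0.1))
  counts <- vapply(1:1000, function(s) {
    nrow(build_adjacency(cfg, seed = s)$edges)
  }, numeric(1))
  n_pairs <- 100 * 100
  p <- 0.1
  se <- sqrt(n_pairs * p * (1 - p)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n_pairs * p), 3 * se)
})

test_that("adjacency is deterministic given the seed and routes by polarity", {
  cfg <- make_fixture(4, 15, seed = 12)
  a1 <- build_adjacency(cfg, seed = 77)
  a2 <- build_adjacency(cfg, seed = 77)
  expect_identical(a1$edges, a2$edges)
  a3 <- build_adjacency(cfg, seed = 78)
  expect_false(identical(a1$edges, a3$edges))

  # polarity routing: GABA rows only from inhibitory sources, AMPA rows
  # only from excitatory sources
  idx <- a1$index
  pol_of <- idx$polarity[idx$group_of]
  src_pol <- pol_of[a1$edges$source + 1L]
  expect_true(all(src_pol[a1$edges$receptor == "GABA"] == "inhibitory"))
  expect_true(all(src_pol[a1$edges$receptor != "GABA"] == "excitatory"))
  # per-receptor sparse matrices agree with the edge list
  expect_equal(sum(vapply(a1$W, function(m) length(m@x), numeric(1))),
               nrow(a1$edges))
})

test_that("adjacency CSV export writes 0-based ids with the documented header", {
  cfg <- make_fixture(2, 5, seed = 2)
  adj <- build_adjacency(cfg)
  path <- file.path(tempdir(), "adj.csv")
  write_adjacency(adj, path)
  got <- read.csv(path)
  expect_identical(names(got), c("source_id", "target_id", "weight_mV", "receptor"))
  expect_equal(nrow(got), nrow(adj$edges))
  expect_gte(min(got$source_id), 0)
  expect_lt(max(got$target_id), adj$n)
  unlink(path)
})

test_that("scaling a config preserves composition ratios approximately", {
  cfg <- scale_config(default_cortex_config(), 0.1)
  expect_equal(sum(cfg$groups$count), 1000)
  expect_equal(cfg$groups$count[cfg$groups$name == "RS_p2"], 250)
  frac <- sum(cfg$groups$count[cfg$groups$polarity == "excitatory"]) /
    sum(cfg$groups$count)
  expect_equal(frac, 0.8, tolerance = 0.01)
  expect_length(validate_config(cfg), 0)
})
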