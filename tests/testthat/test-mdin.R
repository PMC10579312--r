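test_that("the default transformation catalogue is complete and additive", {
  tr <- default_transformations()
  expect_equal(nrow(tr), 13)
  expect_setequal(tr$label, c("CH2", "H2", "O", "H2O", "CO2", "HCN", "NH",
                              "NH3", "S", "SO", "SO2", "SO3", "SO4"))
  # every exact mass equals the monoisotopic mass of its delta
  m <- as.matrix(tr[, c("C", "H", "N", "O", "S", "Na", "Mg", "Cl")])
  expect_equal(tr$exact_mass, monoisotopic_mass(m), tolerance = 1e-12)
  # additivity: SO4 - SO3 = O
  get <- function(l) tr$exact_mass[tr$label == l]
  expect_equal(get("SO4") - get("SO3"), get("O"), tolerance = 1e-9)
  expect_equal(get("CH2"), 14.0156500638, tolerance = 1e-9)

  expect_equal(nrow(default_transformations(include_co2 = FALSE)), 12)
  expect_error(transformation_catalogue(c("CH2", "CH2")), "unique")
})

test_that("hand-checkable networks come out exactly", {
  net <- build_network(c("C6H6O", "C7H8O", "C6H6O2"))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$transformation, c("CH2", "O"))
  expect_equal(net$n_connected_nodes, 3)
  expect_equal(sum(net$per_transformation_counts), 2)

  single <- build_network("C6H6O")
  expect_equal(nrow(single$edges), 0)
  expect_equal(single$n_connected_nodes, 0)

  expect_error(build_network(c("C6H6O", "C6H6O")), "duplicate")
})

test_that("elemental edges equal the all-pairs exact-mass-difference oracle", {
  cfg <- population_config(n_formulas = 200, seed = 23)
  pop <- generate_population(cfg)
  net <- build_network(pop)

  # brute-force oracle: all pairs, mass difference against catalogue
  masses <- monoisotopic_mass(formula_matrix(pop))
  tr <- default_transformations()
  oracle_edges <- character(0)
  for (i in seq_along(pop)) {
    d <- masses - masses[i]
    for (k in seq_len(nrow(tr))) {
      j <- which(abs(d - tr$exact_mass[k]) < 1e-6)
      if (length(j) > 0) {
        oracle_edges <- c(oracle_edges, paste(pop[i], pop[j], tr$label[k]))
      }
    }
  }
  got <- paste(net$edges$from, net$edges$to, net$edges$transformation)
  expect_setequal(got, oracle_edges)
})

test_that("network statistics satisfy the conservation laws", {
  cfg <- population_config(n_formulas = 300, seed = 29)
  pop <- generate_population(cfg)
  net <- build_network(pop)
  st <- network_stats(net)
  expect_equal(sum(st$counts), st$n_edges)
  expect_equal(st$n_connected_nodes + st$n_unconnected_nodes, st$n_nodes)
  expect_equal(sum(st$percentages), 100, tolerance = 1e-9)
  expect_gte(st$pct_nitrogen, 0)
  expect_gte(st$pct_sulfur, 0)

  # single-edge network: 100% on that transformation
  net1 <- build_network(c("C6H6O", "C7H8O"))
  st1 <- network_stats(net1)
  expect_equal(unname(st1$percentages["CH2"]), 100)

  # empty network: all-zero summary, no division error
  st0 <- network_stats(build_network("C6H6O"))
  expect_true(all(st0$percentages == 0))
})

test_that("mass-based networks respect the catalogue and contain the formula edges", {
  # CH4-vs-O spacing is not a catalogue transformation
  pl <- peaklist(c(300, 300.0363855), c(1, 1), c(10, 10))
  expect_equal(nrow(mass_based_network(pl, tol_ppm = 1)$edges), 0)

  pl2 <- peaklist(c(300, 300 + 14.0156500), c(1, 1), c(10, 10))
  e2 <- mass_based_network(pl2, tol_ppm = 1)$edges
  expect_equal(e2$transformation, "CH2")

  # on an assigned synthetic list, mass edges cover the formula edges
  cfg <- population_config(n_formulas = 150, seed = 37)
  pop <- generate_population(cfg)
  sim <- simulate_peaklist(pop, ppm_sigma = 0, seed = 38)
  net_f <- build_network(pop)
  net_m <- mass_based_network(sim$peaklist, tol_ppm = 0.5)
  expect_gte(nrow(net_m$edges), nrow(net_f$edges))
})

test_that("network export round-trips and produces parseable GraphML", {
  net <- build_network(c("C6H6O", "C7H8O", "C6H6O2", "C10H22"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tmp, format = "edge_tsv")
  back <- import_network(tmp)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(back$edges[order(back$edges$from, back$edges$to), ],
               net$edges[order(net$edges$from, net$edges$to), ],
               ignore_attr = TRUE)
  expect_equal(back$per_transformation_counts, net$per_transformation_counts)
  expect_equal(back$n_connected_nodes, net$n_connected_nodes)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("formula" %in% igraph::vertex_attr_names(g) ||
                "name" %in% igraph::vertex_attr_names(g))
})

test_that("planted CH2 chains appear as network edges", {
  planted <- list(list(base = "C10H12N2O3", length = 5))
  cfg <- population_config(n_formulas = 100, seed = 41, series = planted)
  pop <- generate_population(cfg)
  net <- build_network(pop)
  members <- attr(pop, "planted_series")[[1]]
  for (i in seq_len(length(members) - 1)) {
    hit <- net$edges$from == members[i] & net$edges$to == members[i + 1] &
      net$edges$transformation == "CH2"
    expect_equal(sum(hit), 1)
  }
})
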