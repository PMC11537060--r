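test_that("Spearman matrix handles monotone, anti-monotone and tied ranks", {
  m <- make_table(rbind(c(1, 2, 3, 4), c(10, 20, 30, 40),
                        c(8, 6, 4, 2), c(5, 5, 5, 5)),
                  asv = c("up", "up2", "down", "flat"))
  cc <- suppressWarnings(spearman_matrix(m))
  expect_equal(cc["up", "up2"], 1)
  expect_equal(cc["up", "down"], -1)
  expect_false("flat" %in% rownames(cc))
  expect_equal(attr(cc, "dropped_zero_variance"), "flat")

  hand <- make_table(rbind(c(1, 2, 3), c(1, 3, 2)), asv = c("x", "y"))
  expect_error(spearman_matrix(hand), "4 samples")
  hand4 <- make_table(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
                      asv = c("x", "y"))
  expect_equal(suppressWarnings(spearman_matrix(hand4))["x", "y"], 0.8)
})

test_that("RMT scan flags degenerate spectra and errors with diagnostics", {
  cc <- diag(60)
  dimnames(cc) <- list(sprintf("a%d", 1:60), sprintf("a%d", 1:60))
  err <- tryCatch(suppressWarnings(rmt_threshold(cc)),
                  rmt_no_threshold = function(e) e)
  expect_s3_class(err, "rmt_no_threshold")
  expect_true(is.data.frame(err$diagnostics))
  expect_true(all(is.na(err$diagnostics$p_poisson)))
})

test_that("RMT finds the noise floor of an iid correlation matrix", {
  set.seed(5)
  x <- matrix(rnorm(200 * 50), 200)
  rownames(x) <- sprintf("a%03d", 1:200)
  cc <- cor(t(x), method = "spearman")
  th <- rmt_threshold(cc)
  expect_gte(th$threshold, 0.30)
  expect_lt(th$threshold, 0.60)
  # below the chosen threshold the NNSD is not Poisson-consistent,
  # except possibly within the persistence window
  below <- th$diagnostics[th$diagnostics$s < th$threshold - 0.02, ]
  if (nrow(below)) expect_lt(min(below$p_poisson, na.rm = TRUE), 0.05)
})

test_that("network construction thresholds edges and keeps signs", {
  cc <- matrix(c(1, 0.95, -0.92, 0.95, 1, 0.1, -0.92, 0.1, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- build_network(cc, 0.9)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$sign, c(1L, -1L))
  expect_equal(igraph::graph_attr(g, "threshold"), 0.9)

  empty <- build_network(cc, 1.0)
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(igraph::graph_attr(empty, "n_isolated"), 3)

  tri <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tri) <- 1
  gt <- build_network(tri, 0.9)
  expect_equal(igraph::ecount(gt), 3)
})

test_that("edge sets shrink monotonically as the threshold rises", {
  set.seed(2)
  x <- matrix(rnorm(30 * 20), 30, dimnames = list(sprintf("a%d", 1:30),
                                                  NULL))
  cc <- cor(t(x), method = "spearman")
  sizes <- vapply(seq(0.2, 0.8, 0.1), function(s) {
    igraph::ecount(build_network(cc, s))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("topology metrics match closed forms on reference graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  t4 <- network_topology(k4)
  expect_equal(t4$n_nodes, 4)
  expect_equal(t4$n_links, 6)
  expect_equal(t4$avgK, 3)
  expect_equal(t4$connectedness, 1)
  expect_equal(t4$modularity, 0)

  two_tri <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  tt <- network_topology(two_tri)
  expect_equal(tt$avgK, 2)
  expect_equal(tt$connectedness, 6 / 15)
  expect_equal(tt$modularity, 0.5)
  expect_equal(tt$n_components, 2)

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:6)
  ts <- network_topology(star)
  hub <- ts$nodes[which.max(ts$nodes$degree), ]
  expect_equal(hub$degree, 5)
  expect_equal(hub$betweenness, 1)
  expect_equal(sum(ts$nodes$degree), 2 * ts$n_links)

  expect_error(network_topology(igraph::make_empty_graph(0)), "empty")
})

test_that("Maslov-Sneppen rewiring preserves the degree sequence exactly", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- letters[1:3]
  rt <- maslov_sneppen_rewire(tri, seed = 4)
  expect_equal(sort(igraph::as_ids(igraph::E(rt))),
               sort(igraph::as_ids(igraph::E(tri))))

  set.seed(10)
  g <- igraph::sample_gnm(40, 80)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  for (s in 1:5) {
    rg <- maslov_sneppen_rewire(g, seed = s)
    expect_identical(igraph::degree(rg), igraph::degree(g))
    expect_true(igraph::is_simple(rg))
  }
})

test_that("P4 rewiring reaches exactly its two degree-preserving graphs", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  canon <- function(g) {
    el <- igraph::as_data_frame(g)
    paste(sort(paste(pmin(el$from, el$to), pmax(el$from, el$to))),
          collapse = ";")
  }
  seen <- unique(vapply(1:60, function(s) {
    canon(maslov_sneppen_rewire(p4, n_swaps = 50, seed = s))
  }, character(1)))
  # the labelled degree sequence (1,2,2,1) admits exactly two simple graphs
  allowed <- c("a b;b c;c d", "a c;b c;b d")
  expect_true(all(seen %in% allowed))
  expect_setequal(seen, allowed)
})

test_that("null ensembles flag degree-determined metrics and find planted modularity", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, a - d)
  ne <- null_ensemble(g, n = 30, seed = 7)
  s <- ne$summary
  expect_true(is.na(s$z[s$metric == "avgK"]))
  expect_equal(s$null_sd[s$metric == "avgK"], 0)
  expect_gt(s$z[s$metric == "modularity"], 0)
  ne2 <- null_ensemble(g, n = 30, seed = 7)
  expect_identical(ne$summary, ne2$summary)
})

test_that("keystone ranking rewards joint degree and betweenness", {
  # two hubs bridged by a path through one relay
  g <- igraph::make_graph(~ h1 - a, h1 - b, h1 - c, h1 - r, h2 - d, h2 - e,
                          h2 - f, h2 - r)
  topo <- network_topology(g)
  keys <- keystone_species(topo, k = 2)
  expect_setequal(keys$asv_id, c("h1", "h2"))

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("n", 6:1)  # ids deliberately unsorted
  kr <- keystone_species(network_topology(ring), k = 3)
  expect_equal(kr$asv_id, c("n1", "n2", "n3"))

  small <- keystone_species(topo, k = 50)
  expect_true(isTRUE(attr(small, "underpopulated")))
  expect_equal(nrow(small), igraph::vcount(g))
})

test_that("network export formats round trip the edge list", {
  cc <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(cc) <- 1
  g <- build_network(cc, 0.9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_edgelist(g, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), 3)
  expect_named(el, c("source", "target", "r", "weight", "sign"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), 3)
})
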