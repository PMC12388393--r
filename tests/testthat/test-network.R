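# Co-occurrence networks: filters, Spearman matrix, thresholding, modules,
# topology statistics, keystones, module extraction and GraphML I/O.

make_corr <- function(rho, p = NULL) {
  if (is.null(p)) p <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  diag(p) <- 0
  structure(list(rho = rho, p = p, n = 10), class = "bloom_corr")
}

test_that("abundance/prevalence filter applies both strict rules", {
  rel <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    common = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
    rare_everywhere = rep(2e-4, 6),          # 0.02% mean, all samples: kept
    too_thin = rep(5e-5, 6),                 # below 0.01%: dropped
    one_sample = c(0.6995, 0, 0, 0, 0, 0),   # 16.7% prevalence: dropped
    two_samples = c(0, 0.0002, 0.0003, 0, 0, 0), # 33% prevalence, low mean: dropped
    solid = c(0.0003, 0.2993, 0.6992, 0.6995, 0.6995, 0.6993)
  )
  keep <- network_filter(rel)
  expect_setequal(keep, c("common", "rare_everywhere", "solid"))
  expect_error(
    network_filter(rel, min_abund = 0.99),
    "relax"
  )
  # hand enumeration on an 8-ASV toy: prevalence exactly 20% is excluded
  rel5 <- tibble::tibble(sample_id = paste0("s", 1:5),
                         boundary = c(0.5, 0, 0, 0, 0), # 1/5 = 20%: strict, dropped
                         ok = c(0.5, 1, 1, 1, 1))
  expect_setequal(network_filter(rel5), "ok")
})

test_that("Spearman matrix matches mid-rank computation and the exhaustive permutation null", {
  x <- c(1.0, 2.0, 2.0, 3.0, 4.0, 5.0) # one tie
  y <- c(2.1, 3.0, 4.5, 4.4, 6.0, 8.0)
  z <- rev(y) + c(0.1, 0, -0.2, 0.3, 0, 0)
  m <- cbind(x = x, y = y, z = z)
  rownames(m) <- paste0("s", 1:6)
  cm <- spearman_matrix(m)
  rho_brute <- cor(rank(x), rank(y))
  expect_equal(cm$rho["x", "y"], rho_brute, tolerance = 1e-12)
  expect_equal(cm$rho["x", "y"], cor(x, y, method = "spearman"), tolerance = 1e-12)
  # the t-approximation p stays within 0.02 of the exhaustive 720-ordering null
  p_exact <- exhaustive_spearman_p(x, y)
  expect_lt(abs(cm$p["x", "y"] - p_exact), 0.02)
  p_exact_xz <- exhaustive_spearman_p(x, z)
  expect_lt(abs(cm$p["x", "z"] - p_exact_xz), 0.02)
  # perfectly monotone pairs: rho 1 (or -1) and p exactly 0
  mono <- cbind(a = 1:6, b = c(2, 4, 5, 7, 10, 30), c = -(1:6))
  rownames(mono) <- paste0("s", 1:6)
  cmono <- spearman_matrix(mono)
  expect_equal(cmono$rho["a", "b"], 1)
  expect_equal(cmono$p["a", "b"], 0)
  expect_equal(cmono$rho["a", "c"], -1)
  # constant columns are undefined
  cc <- cbind(a = 1:6, k = rep(2, 6))
  rownames(cc) <- paste0("s", 1:6)
  expect_true(is.na(spearman_matrix(cc)$rho["a", "k"]))
})

test_that("null false-edge frequency follows the t tail", {
  withr::with_seed(31, {
    hits <- vapply(1:400, function(i) {
      m <- matrix(rnorm(30 * 2), ncol = 2)
      rownames(m) <- paste0("s", 1:30)
      colnames(m) <- c("a", "b")
      cm <- spearman_matrix(m)
      abs(cm$rho["a", "b"]) > 0.6 && cm$p["a", "b"] < 0.05
    }, logical(1))
  })
  p_tail <- 2 * pt(-0.6 * sqrt(28 / (1 - 0.36)), df = 28)
  expect_lt(abs(mean(hits) - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / 400) + 1e-3)
})

test_that("network thresholding is strict on both rho and p, and drops isolated nodes", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4)
  dimnames(rho) <- list(ids, ids)
  rho["a", "b"] <- rho["b", "a"] <- 0.6    # exactly at threshold: no edge
  rho["a", "c"] <- rho["c", "a"] <- 0.9
  rho["b", "c"] <- rho["c", "b"] <- -0.7
  p <- matrix(0.01, 4, 4, dimnames = dimnames(rho))
  p["a", "d"] <- p["d", "a"] <- 0.2
  rho["a", "d"] <- rho["d", "a"] <- 0.8    # |rho| fine but p too large
  g <- build_network(make_corr(rho, p))
  expect_setequal(igraph::V(g)$name, c("a", "b", "c")) # d isolated, removed
  expect_equal(igraph::ecount(g), 2)
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to), c("a c", "b c"))
  expect_setequal(el$sign, c("positive", "negative"))

  # a rho-0.9 triangle survives whole
  tri <- matrix(0.9, 3, 3, dimnames = list(ids[1:3], ids[1:3]))
  diag(tri) <- 1
  g3 <- build_network(make_corr(tri))
  expect_equal(igraph::ecount(g3), 3)
})

test_that("edge sets are invariant to sample and ASV order", {
  withr::with_seed(41, {
    m <- matrix(rnorm(9 * 12), nrow = 9,
                dimnames = list(paste0("s", 1:9), paste0("t", 1:12)))
  })
  edges_of <- function(mm) {
    g <- build_network(spearman_matrix(mm), r_min = 0.3, p_max = 0.3)
    el <- igraph::as_data_frame(g)
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  }
  base <- edges_of(m)
  expect_equal(edges_of(m[sample(9), ]), base)
  expect_equal(edges_of(m[, sample(12)]), base)
})

test_that("fast-greedy partition equals the exhaustive modularity optimum on bridged cliques", {
  adj <- bridged_cliques_adj()
  g <- adj_to_graph(adj)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$weight <- 1
  igraph::E(g)$rho <- 1
  igraph::E(g)$sign <- "positive"
  mod <- fast_greedy_modules(g)
  # exhaustive search over all 4140 partitions of 8 nodes
  parts <- all_partitions(8)
  qs <- vapply(parts, function(pp) modularity_of(adj, pp), numeric(1))
  q_best <- max(qs)
  best <- parts[[which.max(qs)]]
  expect_equal(mod$modularity, q_best, tolerance = 1e-9)
  expect_equal(mod$n_modules, 2)
  got <- mod$membership$module
  expect_equal(length(unique(got[1:4])), 1)
  expect_equal(length(unique(got[5:8])), 1)
  expect_false(got[1] == got[5])
  # the optimum itself splits the cliques
  expect_equal(length(unique(best[1:4])), 1)

  # a single clique collapses to one module with Q = 0
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("c", 1:4)
  igraph::E(k4)$weight <- 1
  m1 <- fast_greedy_modules(k4)
  expect_equal(m1$n_modules, 1)
  expect_equal(m1$modularity, 0, tolerance = 1e-12)

  # edgeless network: singleton modules, Q = 0
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("x", "y", "z")
  m0 <- fast_greedy_modules(g0)
  expect_equal(m0$n_modules, 3)
  expect_equal(m0$modularity, 0)

  # partition quality invariants
  expect_gte(mod$modularity, 0)
})

test_that("topology statistics match the hand-computed 3-node path and degree identity", {
  g <- igraph::make_graph(~ a - b, b - c)
  igraph::E(g)$sign <- c("positive", "negative")
  igraph::E(g)$rho <- c(0.9, -0.8)
  igraph::E(g)$weight <- c(0.9, 0.8)
  st <- network_stats(g)
  expect_equal(st$n_nodes, 3)
  expect_equal(st$n_edges, 2)
  expect_equal(st$average_degree, round(4 / 3, 3))
  expect_equal(st$proportion_positive, 0.5)
  expect_equal(st$average_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(st$diameter, 2)
  expect_equal(st$mean_betweenness, 1 / 3, tolerance = 1e-12)

  expect_equal(average_degree(401, 1040), 5.187)
  expect_equal(average_degree(903, 4300), 9.524)

  # sum of degrees = 2E on random graphs
  withr::with_seed(8, {
    for (i in 1:5) {
      adj <- random_adj(10, 0.4)
      gg <- adj_to_graph(adj)
      expect_equal(sum(igraph::degree(gg)), 2 * igraph::ecount(gg))
      igraph::E(gg)$sign <- "positive"
      sst <- network_stats(gg)
      expect_equal(sst$average_degree,
                   round(2 * sst$n_edges / sst$n_nodes, 3))
    }
  })
})

test_that("betweenness agrees with naive path counting and keystones are ranked correctly", {
  # toy 7-node graph with a known bridge structure
  g7 <- igraph::make_graph(~ a - b, a - c, b - c, c - d, d - e, d - f, e - f, f - g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g7))
  expect_equal(
    unname(igraph::betweenness(g7, weights = NA)),
    naive_betweenness(adj),
    tolerance = 1e-12
  )
  ks <- keystone_rank(g7)
  oracle_order <- order(-naive_betweenness(adj))
  expect_equal(ks$asv_id[1], igraph::V(g7)$name[oracle_order[1]])
  expect_true(all(ks$betweenness > 0))

  # random graphs up to 12 nodes
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      adj <- random_adj(n, stats::runif(1, 0.2, 0.6))
      gg <- adj_to_graph(adj)
      expect_equal(unname(igraph::betweenness(gg, weights = NA)),
                   naive_betweenness(adj), tolerance = 1e-9)
    }
  })

  # star graph: the hub is the only keystone
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:6)
  ks_star <- keystone_rank(star)
  expect_equal(nrow(ks_star), 1)
  expect_equal(ks_star$asv_id, "v1")

  # disjoint cliques: all betweenness zero, keystone list empty
  dj <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  igraph::V(dj)$name <- paste0("u", 1:8)
  expect_equal(nrow(keystone_rank(dj)), 0)
})

test_that("module extraction finds negative-edge and focal-genus modules", {
  # two modules: 1 = {a,b,c} prokaryote with one negative edge,
  # 2 = {d,e} mixed, all positive, containing the focal genus
  g <- igraph::make_graph(~ a - b, b - c, a - c, d - e)
  igraph::V(g)$domain <- c("prokaryote", "prokaryote", "prokaryote",
                           "eukaryote", "prokaryote")
  igraph::V(g)$genus <- c("G1", "G2", "G3", "Noctiluca", "G4")
  igraph::E(g)$sign <- c("positive", "negative", "positive", "positive")
  igraph::E(g)$rho <- c(0.9, -0.7, 0.8, 0.95)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  mods <- fast_greedy_modules(g)
  rep <- extract_modules(g, mods, "Noctiluca")
  expect_setequal(rep$largest_negative$asv_id, c("a", "b", "c"))
  expect_setequal(rep$largest_negative_prokaryote$asv_id, c("a", "b", "c"))
  expect_true(rep$focal_found)
  expect_equal(rep$focal$neighbor, "e")
  expect_equal(rep$focal$sign, "positive")

  # all-positive network: negative-module reports are empty
  igraph::E(g)$sign <- rep("positive", 4)
  rep2 <- extract_modules(g, fast_greedy_modules(g), "Noctiluca")
  expect_equal(nrow(rep2$largest_negative), 0)
  expect_equal(nrow(rep2$largest_negative_prokaryote), 0)

  # absent focal genus: flagged empty report
  rep3 <- extract_modules(g, fast_greedy_modules(g), "Absentella")
  expect_false(rep3$focal_found)
  expect_equal(nrow(rep3$focal), 0)
})

test_that("region comparison flags directions and the strict multi-module rule", {
  mk <- function(nodes, edges, q) tibble::tibble(
    n_nodes = nodes, n_prok_nodes = nodes - 10, n_euk_nodes = 10,
    n_edges = edges, proportion_positive = 0.8,
    average_degree = round(2 * edges / nodes, 3),
    average_path_length = 1.3, diameter = 6, clustering_coefficient = 0.95,
    mean_betweenness = 5e-4, n_modules = 95, modularity = q
  )
  br <- mk(401, 1040, 0.41)
  nr <- mk(903, 4300, 0.40)
  br$average_path_length <- 1.303
  nr$average_path_length <- 1.123
  cmp <- compare_regions(br, nr)
  expect_equal(cmp$direction[cmp$metric == "n_nodes"], "nr_higher")
  expect_equal(cmp$direction[cmp$metric == "n_edges"], "nr_higher")
  expect_equal(cmp$direction[cmp$metric == "average_degree"], "nr_higher")
  expect_equal(cmp$direction[cmp$metric == "average_path_length"], "br_higher")
  expect_equal(cmp$br[cmp$metric == "multi_module"], 1) # 0.41 > 0.4
  expect_equal(cmp$nr[cmp$metric == "multi_module"], 0) # 0.40 is not strict
  same <- compare_regions(br, br)
  expect_true(all(same$direction[!is.na(same$direction)] == "equal"))
})

test_that("GraphML export round-trips attributes and validates as XML", {
  withr::with_seed(17, {
    m <- matrix(rnorm(10 * 8), nrow = 10,
                dimnames = list(paste0("s", 1:10), paste0("t", 1:8)))
    m[, 2] <- m[, 1] + rnorm(10, 0, 0.1)
    m[, 3] <- -m[, 1] + rnorm(10, 0, 0.1)
  })
  meta <- tibble::tibble(
    asv_id = colnames(m), domain = "prokaryote",
    genus = paste0("G", 1:8), lineage = paste0("d__B;g__G", 1:8),
    mean_rel_abund = colMeans(abs(m))
  )
  g <- build_network(spearman_matrix(m), meta, r_min = 0.5, p_max = 0.1)
  mods <- fast_greedy_modules(g)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, mods, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  back <- read_graphml(path)
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_setequal(
    igraph::vertex_attr_names(back),
    union(igraph::vertex_attr_names(g), c("module", "betweenness", "id"))
  )
  expect_equal(sort(igraph::E(back)$rho), sort(igraph::E(g)$rho), tolerance = 1e-9)

  # an empty network still writes valid GraphML
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  path0 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g0, path = path0)
  expect_equal(xml2::xml_name(xml2::read_xml(path0)), "graphml")
  back0 <- read_graphml(path0)
  expect_equal(igraph::ecount(back0), 0)
})
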