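# Thresholded Spearman co-occurrence networks: abundance/prevalence
# filtering, correlation matrix, graph construction, fast-greedy modules,
# topology statistics, keystone ranking, module extraction, GraphML export.

#' Abundance/prevalence filter for network construction
#'
#' Keeps ASVs whose overall mean relative abundance strictly exceeds
#' `min_abund` and which are present (count > 0) in strictly more than
#' `min_prev` of the samples.
#'
#' @param rel_abund Relative-abundance tibble or matrix (rows sum to 1).
#' @param min_abund Mean relative-abundance threshold (default 1e-4,
#'   i.e. 0.01%).
#' @param min_prev Prevalence threshold as a fraction of samples (default
#'   0.2).
#' @return Character vector of retained ASV ids.
#' @export
network_filter <- function(rel_abund, min_abund = 1e-4, min_prev = 0.2) {
  m <- count_matrix(rel_abund)
  keep <- colMeans(m) > min_abund & colMeans(m > 0) > min_prev
  if (!any(keep)) {
    abort("no ASVs pass the abundance/prevalence filter; relax min_abund/min_prev")
  }
  colnames(m)[keep]
}

#' Pairwise Spearman correlation matrix with p-values
#'
#' Mid-rank (average-rank) Spearman rho for every ASV pair, with two-sided
#' p-values from the t approximation t = rho * sqrt((n-2)/(1-rho^2));
#' |rho| = 1 maps to p = 0. Constant columns yield undefined (NA)
#' correlations and never form edges.
#'
#' @param x Samples-x-ASVs abundance tibble or matrix (>= 5 samples).
#' @return A `bloom_corr` object: `rho` and `p` matrices plus `n`.
#' @export
spearman_matrix <- function(x) {
  m <- count_matrix(x)
  n <- nrow(m)
  if (n < 5) abort("Spearman matrix needs at least 5 samples")
  constant <- apply(m, 2, function(col) length(unique(col)) == 1)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  p <- matrix(spearman_p(rho, n), ncol(m), ncol(m), dimnames = dimnames(rho))
  diag(p) <- ifelse(constant, NA_real_, 0)
  structure(list(rho = rho, p = p, n = n), class = "bloom_corr")
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Retains an edge between two ASVs iff |rho| strictly exceeds `r_min` AND
#' p is strictly below `p_max`. Nodes left without any edge are removed, so
#' node counts refer to connected nodes. Edge sign is carried as an
#' attribute; an optional Benjamini-Hochberg correction can be applied to
#' the edge p-values before thresholding.
#'
#' @param corr A `bloom_corr` from [spearman_matrix()].
#' @param node_meta Tibble with `asv_id` and optionally `domain`
#'   (prokaryote/eukaryote), `lineage`, `genus`, `mean_rel_abund`.
#' @param r_min Correlation-magnitude threshold (default 0.6).
#' @param p_max Significance threshold (default 0.05).
#' @param region Optional region label stored on the graph.
#' @param bh_correct Apply Benjamini-Hochberg correction to the pairwise
#'   p-values before thresholding (default FALSE: raw p-values).
#' @return An `igraph` undirected graph with node attributes (`name`,
#'   `domain`, `lineage`, `genus`, `mean_rel_abund`) and edge attributes
#'   (`rho`, `weight` = |rho|, `sign`, `p`).
#' @export
build_network <- function(corr, node_meta = NULL, r_min = 0.6, p_max = 0.05,
                          region = NA_character_, bh_correct = FALSE) {
  stopifnot(inherits(corr, "bloom_corr"))
  rho <- corr$rho
  p <- corr$p
  ids <- colnames(rho)
  ut <- upper.tri(rho)
  if (bh_correct) {
    praw <- p[ut]
    p[ut] <- stats::p.adjust(praw, method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  sel <- ut & !is.na(rho) & abs(rho) > r_min & !is.na(p) & p < p_max
  idx <- which(sel, arr.ind = TRUE)
  edges <- tibble(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    rho = rho[sel], p = p[sel]
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$weight <- abs(edges$rho)
  igraph::E(g)$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  igraph::E(g)$p <- edges$p
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  if (!is.null(node_meta)) {
    meta <- node_meta[match(igraph::V(g)$name, node_meta$asv_id), ]
    for (col in intersect(c("domain", "lineage", "genus", "mean_rel_abund"), names(meta))) {
      g <- igraph::set_vertex_attr(g, col, value = meta[[col]])
    }
  }
  g$region <- region
  g
}

#' Fast-greedy module detection
#'
#' Clauset-Newman-Moore agglomerative modularity maximization on the
#' unsigned graph weighted by |rho|. Edge signs are annotations, not inputs
#' to modularity. An edgeless network places every node in its own module
#' with Q = 0.
#'
#' @param net An `igraph` network from [build_network()].
#' @return A `bloom_modules` object: `membership` tibble (`asv_id`,
#'   `module`), `modularity`, `n_modules`.
#' @export
fast_greedy_modules <- function(net) {
  if (igraph::ecount(net) == 0) {
    memb <- seq_len(igraph::vcount(net))
    return(structure(
      list(
        membership = tibble(
          asv_id = igraph::V(net)$name %||% as.character(memb),
          module = as.integer(memb)
        ),
        modularity = 0,
        n_modules = length(memb)
      ),
      class = "bloom_modules"
    ))
  }
  cl <- igraph::cluster_fast_greedy(net, weights = igraph::E(net)$weight)
  # cut the agglomeration dendrogram at its maximum-modularity step (the
  # algorithm's own stopping point can sit below it on dense graphs)
  qpath <- cl$modularity
  n_comm <- igraph::vcount(net) - (which.max(qpath) - 1L)
  memb <- igraph::cut_at(cl, no = n_comm)
  q <- igraph::modularity(net, memb, weights = igraph::E(net)$weight)
  structure(
    list(
      membership = tibble(
        asv_id = igraph::V(net)$name %||% as.character(seq_along(memb)),
        module = as.integer(memb)
      ),
      modularity = q,
      n_modules = length(unique(memb))
    ),
    class = "bloom_modules"
  )
}

#' @export
print.bloom_modules <- function(x, ...) {
  cat(sprintf(
    "Fast-greedy partition: %d modules, modularity Q = %.3f\n",
    x$n_modules, x$modularity
  ))
  invisible(x)
}

#' Average degree from node and edge counts
#'
#' The identity 2E/N, rounded to three decimals as reported in network
#' topology tables.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return `round(2 * n_edges / n_nodes, 3)`.
#' @export
#' @examples
#' average_degree(401, 1040)
average_degree <- function(n_nodes, n_edges) {
  stopifnot(n_nodes > 0, n_edges >= 0)
  round(2 * n_edges / n_nodes, 3)
}

#' Topological summary of a co-occurrence network
#'
#' Computes the standard topology suite on the unweighted graph: node/edge
#' counts (split by domain when available), proportion of positive edges,
#' average degree (2E/N), average shortest-path length over connected pairs
#' only, diameter (largest within-component eccentricity), mean local
#' clustering coefficient over nodes of degree >= 2, mean normalized
#' betweenness (Brandes; normalization (N-1)(N-2)/2), and module count and
#' modularity from the partition. Networks with fewer than 3 nodes report
#' betweenness 0 with a flag.
#'
#' @param net An `igraph` network from [build_network()].
#' @param modules A `bloom_modules` partition (default: computed here).
#' @return A `bloom_netstats` one-row tibble.
#' @export
network_stats <- function(net, modules = NULL) {
  if (is.null(modules)) modules <- fast_greedy_modules(net)
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  domain <- igraph::vertex_attr(net, "domain")
  n_prok <- if (is.null(domain)) NA_integer_ else sum(domain == "prokaryote", na.rm = TRUE)
  n_euk <- if (is.null(domain)) NA_integer_ else sum(domain == "eukaryote", na.rm = TRUE)
  prop_pos <- if (e > 0) mean(igraph::E(net)$sign == "positive") else NA_real_
  small <- n < 3
  btw <- if (small) 0 else mean(igraph::betweenness(net, weights = NA, normalized = TRUE))
  out <- tibble(
    n_nodes = n,
    n_prok_nodes = n_prok,
    n_euk_nodes = n_euk,
    n_edges = e,
    proportion_positive = prop_pos,
    average_degree = average_degree(max(n, 1L), e),
    average_path_length = if (e > 0) igraph::mean_distance(net, weights = NA, unconnected = TRUE) else NA_real_,
    diameter = if (e > 0) igraph::diameter(net, weights = NA, unconnected = TRUE) else NA_real_,
    clustering_coefficient = if (e > 0) igraph::transitivity(net, type = "localaverage", isolates = "NaN") else NA_real_,
    mean_betweenness = btw,
    betweenness_flag = if (small) "fewer than 3 nodes" else NA_character_,
    n_modules = modules$n_modules,
    modularity = modules$modularity
  )
  class(out) <- c("bloom_netstats", class(out))
  out
}

#' Rank keystone candidates by betweenness centrality
#'
#' Sorts nodes by raw (unnormalized) betweenness, descending; ties break by
#' degree (descending) then node id. Nodes with zero betweenness are never
#' keystones, so disjoint-clique networks return an empty list.
#'
#' @param net An `igraph` network.
#' @param top_k Maximum number of keystones to report (default 10).
#' @return A tibble: `asv_id`, `betweenness`, `degree` plus `genus`,
#'   `lineage`, `domain` when present on the graph.
#' @export
keystone_rank <- function(net, top_k = 10) {
  btw <- igraph::betweenness(net, weights = NA, normalized = FALSE)
  deg <- igraph::degree(net)
  out <- tibble(
    asv_id = igraph::V(net)$name,
    betweenness = unname(btw),
    degree = unname(deg)
  )
  for (col in c("genus", "lineage", "domain")) {
    v <- igraph::vertex_attr(net, col)
    if (!is.null(v)) out[[col]] <- v
  }
  out %>%
    filter(.data$betweenness > 0) %>%
    arrange(desc(.data$betweenness), desc(.data$degree), .data$asv_id) %>%
    head(top_k)
}

module_edge_table <- function(net, modules) {
  el <- igraph::as_data_frame(net, what = "edges")
  memb <- setNames(modules$membership$module, modules$membership$asv_id)
  el$module_from <- memb[el$from]
  el$module_to <- memb[el$to]
  as_tibble(el)
}

#' Extract ecologically focal modules from a network partition
#'
#' Returns three reports: (a) the largest module (by node count) containing
#' at least one negative edge; (b) the largest module composed entirely of
#' prokaryotic nodes and containing at least one negative edge; (c) every
#' module containing an ASV annotated to the focal genus, with the focal
#' ASVs' neighbors, lineages and edge signs. All-positive networks return
#' empty (a) and (b); a focal genus absent from the network returns an
#' empty (c) with a flag.
#'
#' @param net An `igraph` network.
#' @param modules A `bloom_modules` partition of `net`.
#' @param focal_genus Genus name to search for (e.g. `"Noctiluca"`).
#' @param tax Optional taxonomy tibble used when the graph carries no
#'   `genus` attribute.
#' @return A list: `largest_negative` (tibble of member nodes or empty),
#'   `largest_negative_prokaryote`, `focal` (tibble of focal-ASV neighbor
#'   records), `focal_found` (logical).
#' @export
extract_modules <- function(net, modules, focal_genus, tax = NULL) {
  memb <- modules$membership
  edges <- module_edge_table(net, modules)
  within <- edges[edges$module_from == edges$module_to, ]
  neg_modules <- unique(within$module_from[within$sign == "negative"])
  sizes <- memb %>% group_by(.data$module) %>% summarise(n = n())
  domain <- igraph::vertex_attr(net, "domain")
  names(domain) <- igraph::V(net)$name

  member_table <- function(mod_id) {
    if (length(mod_id) == 0) return(memb[0, ])
    memb %>% filter(.data$module == mod_id)
  }
  pick_largest <- function(cands) {
    if (length(cands) == 0) return(integer(0))
    sz <- sizes$n[match(cands, sizes$module)]
    cands[order(-sz, cands)][1]
  }
  largest_neg <- pick_largest(neg_modules)
  all_prok_modules <- sizes$module[vapply(sizes$module, function(mo) {
    ids <- memb$asv_id[memb$module == mo]
    !is.null(domain) && all(domain[ids] == "prokaryote", na.rm = FALSE)
  }, logical(1))]
  largest_neg_prok <- pick_largest(intersect(neg_modules, all_prok_modules))

  genus <- igraph::vertex_attr(net, "genus")
  if (is.null(genus) && !is.null(tax)) {
    genus <- tax$genus[match(igraph::V(net)$name, tax$asv_id)]
  }
  focal_report <- tibble(
    focal_asv = character(0), module = integer(0), neighbor = character(0),
    neighbor_genus = character(0), sign = character(0), rho = numeric(0)
  )
  focal_found <- FALSE
  if (!is.null(genus)) {
    focal_ids <- igraph::V(net)$name[!is.na(genus) & genus == focal_genus]
    focal_found <- length(focal_ids) > 0
    if (focal_found) {
      el <- igraph::as_data_frame(net, what = "edges")
      genus_of <- setNames(genus, igraph::V(net)$name)
      memb_of <- setNames(memb$module, memb$asv_id)
      rows <- purrr::map_dfr(focal_ids, function(fid) {
        hit <- el$from == fid | el$to == fid
        if (!any(hit)) {
          return(tibble(
            focal_asv = fid, module = as.integer(memb_of[fid]),
            neighbor = NA_character_, neighbor_genus = NA_character_,
            sign = NA_character_, rho = NA_real_
          ))
        }
        nb <- ifelse(el$from[hit] == fid, el$to[hit], el$from[hit])
        tibble(
          focal_asv = fid, module = as.integer(memb_of[fid]),
          neighbor = nb, neighbor_genus = unname(genus_of[nb]),
          sign = el$sign[hit], rho = el$rho[hit]
        )
      })
      focal_report <- rows
    }
  }
  list(
    largest_negative = member_table(largest_neg),
    largest_negative_prokaryote = member_table(largest_neg_prok),
    focal = focal_report,
    focal_found = focal_found
  )
}

#' Side-by-side comparison of two networks' topology
#'
#' Produces a long table with one row per metric, the BR and NR values, a
#' directional flag (`br_higher` / `nr_higher` / `equal`), and appends a
#' multi-module indicator per region (modularity strictly greater than
#' 0.4).
#'
#' @param stats_br,stats_nr `bloom_netstats` rows from [network_stats()].
#' @return A tibble: `metric`, `br`, `nr`, `direction`.
#' @export
compare_regions <- function(stats_br, stats_nr) {
  metrics <- c(
    "n_nodes", "n_prok_nodes", "n_euk_nodes", "n_edges",
    "proportion_positive", "average_degree", "average_path_length",
    "diameter", "clustering_coefficient", "mean_betweenness",
    "n_modules", "modularity"
  )
  out <- purrr::map_dfr(metrics, function(mt) {
    b <- as.numeric(stats_br[[mt]])
    r <- as.numeric(stats_nr[[mt]])
    dir <- dplyr::case_when(
      is.na(b) || is.na(r) ~ NA_character_,
      b > r ~ "br_higher",
      b < r ~ "nr_higher",
      TRUE ~ "equal"
    )
    tibble(metric = mt, br = b, nr = r, direction = dir)
  })
  bind_rows(
    out,
    tibble(
      metric = "multi_module",
      br = as.numeric(stats_br$modularity > 0.4),
      nr = as.numeric(stats_nr$modularity > 0.4),
      direction = NA_character_
    )
  )
}

#' Export a network with module annotations to GraphML
#'
#' Writes a schema-valid GraphML file carrying node attributes (lineage,
#' domain, genus, mean relative abundance, module id, betweenness) and edge
#' attributes (rho, sign, p), re-readable by igraph and Gephi.
#'
#' @param net An `igraph` network.
#' @param modules Optional `bloom_modules` partition; module ids and raw
#'   betweenness are attached to the nodes before export.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, modules = NULL, path) {
  if (!is.null(modules)) {
    memb <- setNames(modules$membership$module, modules$membership$asv_id)
    net <- igraph::set_vertex_attr(
      net, "module",
      value = as.integer(memb[igraph::V(net)$name])
    )
  }
  net <- igraph::set_vertex_attr(
    net, "betweenness",
    value = igraph::betweenness(net, weights = NA, normalized = FALSE)
  )
  tryCatch(
    igraph::write_graph(net, path, format = "graphml"),
    error = function(e) abort(paste0("GraphML export failed for ", path, ": ", conditionMessage(e)))
  )
  invisible(path)
}

#' Read a GraphML network back
#'
#' @param path Path to a GraphML file written by [write_graphml()].
#' @return An `igraph` graph.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("GraphML file not found: ", path))
  igraph::read_graph(path, format = "graphml")
}
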