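# Independent oracles used to verify the package's algorithms: brute-force
# path counting, exhaustive set-partition modularity, exhaustive Spearman
# permutation nulls. These deliberately share no code with the package.

# All-pairs shortest-path lengths and path counts from the adjacency matrix
# using matrix powers: sigma(i,j) = (A^d)[i,j] where d is the smallest k
# with (A^k)[i,j] > 0.
path_counts <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(d) <- 0
  diag(sigma) <- 1
  pk <- diag(n)
  for (k in seq_len(n)) {
    pk <- pk %*% adj
    newly <- is.infinite(d) & pk > 0
    d[newly] <- k
    sigma[newly] <- pk[newly]
  }
  list(d = d, sigma = sigma)
}

# Naive betweenness: for every unordered pair (s, t) and every interior
# node v on a shortest s-t path, add sigma(s,v) * sigma(v,t) / sigma(s,t).
naive_betweenness <- function(adj) {
  n <- nrow(adj)
  pc <- path_counts(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(pc$d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(pc$d[s, v]) && is.finite(pc$d[v, t]) &&
          pc$d[s, v] + pc$d[v, t] == pc$d[s, t]) {
          btw[v] <- btw[v] + pc$sigma[s, v] * pc$sigma[v, t] / pc$sigma[s, t]
        }
      }
    }
  }
  btw
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(code, maxv) {
    if (length(code) == n) {
      out[[length(out) + 1]] <<- code
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) {
      recurse(c(code, v), max(maxv, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Newman-Girvan modularity of a membership vector on an unweighted graph.
modularity_of <- function(adj, membership) {
  m <- sum(adj) / 2
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(adj[idx, ])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# All permutations of seq_len(n) (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive permutation two-sided p-value for Spearman rho with mid-ranks.
exhaustive_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- all_perms(length(y))
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= obs - 1e-12)
}

# Two bridged 4-cliques (the classic two-community graph).
bridged_cliques_adj <- function() {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 1
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

random_adj <- function(n, p = 0.3) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# Small deterministic count-table fixture: 4 samples x 5 ASVs.
toy_counts <- function() {
  tibble::tibble(
    sample_id = c("A1", "A2", "B1", "B2"),
    ASV1 = c(10L, 8L, 0L, 1L),
    ASV2 = c(5L, 0L, 7L, 2L),
    ASV3 = c(0L, 0L, 3L, 3L),
    ASV4 = c(1L, 2L, 0L, 0L),
    ASV5 = c(4L, 10L, 10L, 20L)
  )
}

toy_taxonomy <- function(ids, ...) {
  dots <- list(...)
  tax <- tibble::tibble(
    asv_id = ids,
    domain = "Bacteria", phylum = "Proteobacteria", class = "Alphaproteobacteria",
    order = "Rhodobacterales", family = "Rhodobacteraceae", genus = "GenusX"
  )
  for (nm in names(dots)) {
    where <- dots[[nm]] # list(asv_id, rank)
    tax[[where[[2]]]][tax$asv_id == where[[1]]] <- nm
  }
  tax
}

# Metadata frame whose surface layer carries the reference survey's printed
# regional means (constant within region), used for fold-change arithmetic.
surface_means_frame <- function() {
  n_br <- 6
  n_nr <- 9
  tibble::tibble(
    sample_id = c(paste0("BR", 1:n_br, "_S"), paste0("NR", 1:n_nr, "_S")),
    region = c(rep("BR", n_br), rep("NR", n_nr)),
    layer = "S",
    site = sub("_S", "", sample_id),
    T = c(rep(22.9, n_br), rep(23.5, n_nr)),
    NH4 = c(rep(851.8, n_br), rep(130.2, n_nr)),
    PO4 = c(rep(72.8, n_br), rep(27.2, n_nr))
  )
}

small_sim_config <- function(seed, ...) {
  sim_config(
    n_prok_taxa = 120, n_euk_taxa = 80, depth_per_sample = 8000,
    seed = seed, ...
  )
}
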