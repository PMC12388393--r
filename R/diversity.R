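# Alpha diversity, rank-sum tests, Bray-Curtis / PCoA, PERMANOVA, and
# region-by-layer environmental comparison.

#' Per-sample alpha-diversity indices
#'
#' Computes observed richness (Sobs), Shannon entropy H (natural log) and
#' Pielou's evenness J = H / ln(Sobs) for each sample of a (typically
#' rarefied) count table. J is undefined and reported `NA` when a sample
#' holds a single ASV.
#'
#' @param table A count-table tibble.
#' @param metadata Optional metadata tibble; if given, `region`, `layer` and
#'   `site` are joined onto the result by `sample_id`.
#' @return A `bloom_alpha` tibble: `sample_id`, `sobs`, `shannon`, `pielou`
#'   (+ grouping columns).
#' @export
alpha_diversity <- function(table, metadata = NULL) {
  m <- count_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) abort(paste0("zero-sum sample: ", rownames(m)[rs == 0][1]))
  p <- sweep(m, 1, rs, "/")
  shannon <- apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log(pi))
  })
  sobs <- rowSums(m > 0)
  pielou <- ifelse(sobs > 1, shannon / log(sobs), NA_real_)
  out <- tibble(
    sample_id = rownames(m),
    sobs = as.integer(sobs),
    shannon = unname(shannon),
    pielou = unname(pielou)
  )
  if (!is.null(metadata)) {
    keep <- intersect(c("sample_id", "region", "layer", "site"), names(metadata))
    out <- left_join(out, metadata[, keep], by = "sample_id")
  }
  class(out) <- c("bloom_alpha", class(out))
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when the pooled sample size is at most
#' 20 and the data are tie-free; otherwise the normal approximation with tie
#' and continuity corrections. Fully degenerate data (all values identical
#' across both groups) return p = 1 with a `degenerate` flag rather than an
#' error.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return A one-row tibble: `statistic` (W), `p_value`, `n_x`, `n_y`,
#'   `method`, `degenerate`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs at least 2 values")
  if (length(unique(c(x, y))) == 1) {
    return(tibble(
      statistic = length(x) * length(y) / 2, p_value = 1,
      n_x = length(x), n_y = length(y),
      method = "degenerate", degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_x = length(x), n_y = length(y),
    method = if (exact) "exact" else "normal approximation",
    degenerate = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between sample abundance rows
#' (counts or proportions). Returns a `dist` object with sample labels.
#'
#' @param table A count-table tibble, proportion tibble, or numeric matrix.
#' @return A `stats::dist` object.
#' @export
bray_curtis <- function(table) {
  m <- count_matrix(table)
  if (nrow(m) < 2) abort("Bray-Curtis needs at least 2 samples")
  if (any(m < 0)) abort("abundances must be non-negative")
  if (any(rowSums(m) == 0)) {
    abort(paste0(
      "all-zero sample makes Bray-Curtis undefined: ",
      rownames(m)[rowSums(m) == 0][1]
    ))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Percent variance explained per axis uses the positive
#' eigenvalues only as denominator; negative eigenvalues are reported but
#' carry no axes. By default no correction is applied to negative
#' eigenvalues; the Cailliez additive correction is available by flag.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param n_axes Number of axes to return (default 2; truncated with a
#'   warning if fewer positive eigenvalues exist).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return A `bloom_pcoa` object: `scores` tibble (`sample_id`, `Axis1`,
#'   ...), `eigenvalues`, `percent_explained`, `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  fit <- suppressWarnings(
    cmdscale(d, k = n - 1, eig = TRUE, add = (correction == "cailliez"))
  )
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warn(sprintf(
      "only %d positive-eigenvalue axes available; truncating from %d",
      n_pos, n_axes
    ))
    n_axes <- n_pos
  }
  pts <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(n_axes))
  pct <- 100 * eig[pos] / sum(eig[pos])
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(sample_id = labels(d)),
        as_tibble(pts)
      ),
      eigenvalues = eig[pos],
      percent_explained = pct[seq_len(n_axes)],
      negative_eigenvalues = eig[eig < 0],
      correction = correction
    ),
    class = "bloom_pcoa"
  )
}

#' @export
print.bloom_pcoa <- function(x, ...) {
  cat(sprintf(
    "PCoA: %d samples, %d axes kept (%s)\n",
    nrow(x$scores), ncol(x$scores) - 1L,
    paste0(sprintf("%.1f%%", x$percent_explained), collapse = ", ")
  ))
  if (length(x$negative_eigenvalues) > 0) {
    cat(sprintf(
      "  %d negative eigenvalues (min %.4g), correction: %s\n",
      length(x$negative_eigenvalues), min(x$negative_eigenvalues), x$correction
    ))
  }
  invisible(x)
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (Anderson's pseudo-F) and assesses significance
#' by seeded permutation of group labels:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so the smallest attainable
#' p with 999 permutations is 0.001.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample (>= 2 groups, each n >= 2).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed (mandatory).
#' @return A `bloom_permanova` one-row tibble: `pseudo_F`, `R2`, `df_between`,
#'   `df_within`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  if (missing(seed)) abort("`seed` is required for PERMANOVA")
  stopifnot(inherits(d, "dist"))
  groups <- droplevels(as.factor(groups))
  n <- attr(d, "Size")
  if (length(groups) != n) abort("`groups` length must match the distance matrix")
  if (nlevels(groups) < 2) abort("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples")
  d2 <- as.matrix(d)^2
  a <- nlevels(groups)
  sst <- sum(d2) / (2 * n)
  ssw_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(g) {
    ssw <- ssw_of(g)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  r2 <- (sst - ssw_of(groups)) / sst
  f_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_of(groups[sample.int(n)]), numeric(1))
  })
  out <- tibble(
    pseudo_F = f_obs, R2 = r2,
    df_between = a - 1L, df_within = n - a,
    p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
    n_perm = as.integer(n_perm)
  )
  class(out) <- c("bloom_permanova", class(out))
  out
}

#' Region-by-layer environmental comparison
#'
#' For each environmental variable within each depth layer, tests BR vs NR
#' with the Wilcoxon rank-sum test, reports group means and the BR/NR fold
#' change (rounded to one decimal). Missing values are excluded per
#' variable; a variable entirely missing in one region of a layer is
#' flagged and skipped.
#'
#' @param metadata Metadata tibble with `region`, `layer` and numeric
#'   environmental columns.
#' @param variables Environmental columns to compare (default: all numeric
#'   columns other than identifiers).
#' @return A tibble: `layer`, `variable`, `mean_br`, `mean_nr`,
#'   `fold_change`, `p_value`, `n_br`, `n_nr`, `skipped`.
#' @export
group_compare_environment <- function(metadata, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(
      names(metadata)[vapply(metadata, is.numeric, logical(1))],
      c("sample_id", "site")
    )
  }
  layers <- intersect(c("S", "M", "B"), unique(metadata$layer))
  rows <- list()
  for (ly in layers) {
    sub <- metadata[metadata$layer == ly, ]
    if (!all(c("BR", "NR") %in% sub$region)) {
      abort(paste0("layer ", ly, " lacks one of the regions"))
    }
    for (v in variables) {
      xb <- sub[[v]][sub$region == "BR"]
      xn <- sub[[v]][sub$region == "NR"]
      xb <- xb[is.finite(xb)]
      xn <- xn[is.finite(xn)]
      if (length(xb) < 2 || length(xn) < 2) {
        rows[[length(rows) + 1]] <- tibble(
          layer = ly, variable = v, mean_br = NA_real_, mean_nr = NA_real_,
          fold_change = NA_real_, p_value = NA_real_,
          n_br = length(xb), n_nr = length(xn), skipped = TRUE
        )
        next
      }
      ht <- wilcoxon_rank_sum(xb, xn)
      rows[[length(rows) + 1]] <- tibble(
        layer = ly, variable = v,
        mean_br = mean(xb), mean_nr = mean(xn),
        fold_change = round(mean(xb) / mean(xn), 1),
        p_value = ht$p_value,
        n_br = length(xb), n_nr = length(xn), skipped = FALSE
      )
    }
  }
  bind_rows(rows)
}
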