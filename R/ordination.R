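# Environment-constrained ordination: transforms, imputation, collinearity
# screening, redundancy analysis, and permutation-based forward selection.

#' Hellinger transform
#'
#' y_ij = sqrt(x_ij / rowsum_i); each transformed row has unit Euclidean
#' norm, making Euclidean-based ordination appropriate for count data.
#'
#' @param table A count-table tibble or matrix with positive row sums.
#' @return A numeric matrix (samples x ASVs).
#' @export
hellinger <- function(table) {
  m <- count_matrix(table)
  if (any(rowSums(m) == 0)) {
    abort(paste0("zero-sum sample: ", rownames(m)[rowSums(m) == 0][1]))
  }
  vegan::decostand(m, method = "hellinger")
}

#' Aggregate ASV counts to genus level
#'
#' Sums counts of ASVs sharing a genus annotation; unclassified genera are
#' pooled per-family into `Unclassified_<family>` bins so they are not
#' merged across unrelated lineages.
#'
#' @param table A count-table tibble.
#' @param tax Taxonomy tibble covering the table's ASVs.
#' @return A count-table tibble with genus columns.
#' @export
aggregate_genus <- function(table, tax) {
  m <- count_matrix(table)
  tax <- tax[match(colnames(m), tax$asv_id), ]
  genus <- ifelse(
    tolower(tax$genus) == "unclassified",
    paste0("Unclassified_", tax$family),
    tax$genus
  )
  agg <- t(rowsum(t(m), group = genus))
  matrix_tibble(agg)
}

#' Prepare the environmental matrix for constrained ordination
#'
#' Mean-imputes missing values per variable (imputation strictly precedes
#' the transform), then applies log10(x + 1) to every variable. Cells that
#' were imputed are flagged in the `imputed` attribute. Variables with no
#' observed values are dropped with a warning.
#'
#' @param metadata Metadata tibble with numeric environmental columns.
#' @param variables Variables to include (default: the standard set present
#'   in the table).
#' @return An `env_matrix` tibble (`sample_id` + transformed variables) with
#'   attribute `imputed` (logical matrix of the same shape).
#' @export
prepare_env <- function(metadata, variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(env_var_names(), names(metadata))
  }
  if (length(variables) < 1) abort("no environmental variables to prepare")
  out <- metadata[, "sample_id", drop = FALSE]
  imputed <- matrix(FALSE, nrow(metadata), 0)
  kept <- character(0)
  for (v in variables) {
    x <- metadata[[v]]
    obs <- is.finite(x)
    if (!any(obs)) {
      warn(paste0("environmental variable `", v, "` has no observed values; dropped"))
      next
    }
    x[!obs] <- mean(x[obs])
    out[[v]] <- log10(x + 1)
    imputed <- cbind(imputed, !obs)
    kept <- c(kept, v)
  }
  colnames(imputed) <- kept
  rownames(imputed) <- metadata$sample_id
  out <- as_tibble(out)
  attr(out, "imputed") <- imputed
  class(out) <- c("env_matrix", class(out))
  out
}

env_as_matrix <- function(env, variables = NULL) {
  df <- as.data.frame(env)
  vars <- setdiff(names(df), "sample_id")
  if (!is.null(variables)) vars <- intersect(variables, vars)
  m <- as.matrix(df[, vars, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Iterative variance-inflation-factor screening
#'
#' Computes VIF_j = 1 / (1 - R^2_j) from regressing each variable on the
#' others and iteratively removes the largest-VIF variable until all VIFs
#' are at or below the threshold. Perfectly collinear variables have
#' infinite VIF and are removed first; ties break by column order.
#'
#' @param env An `env_matrix` (or plain tibble/matrix of predictors).
#' @param threshold Maximum allowed VIF (default 10).
#' @return Character vector of retained variable names, with attribute
#'   `removed` (tibble of removal order and the VIF at removal).
#' @export
vif_screen <- function(env, threshold = 10) {
  m <- env_as_matrix(env)
  if (ncol(m) < 2) return(colnames(m))
  if (nrow(m) <= ncol(m)) {
    warn("fewer samples than variables + 1; screening proceeds by iterative removal")
  }
  vif_of <- function(mm) {
    vapply(seq_len(ncol(mm)), function(j) {
      fit <- lm(mm[, j] ~ mm[, -j, drop = FALSE])
      # suppressed: summary.lm warns about "essentially perfect fit" on the
      # exact collinearity this screen exists to remove
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- list()
  while (ncol(m) > 1) {
    v <- vif_of(m)
    if (all(v <= threshold)) break
    worst <- which.max(v) # which.max returns the first maximum: column-order ties
    removed[[length(removed) + 1]] <- tibble(
      variable = colnames(m)[worst], vif = v[worst]
    )
    m <- m[, -worst, drop = FALSE]
  }
  out <- colnames(m)
  attr(out, "removed") <- if (length(removed)) bind_rows(removed) else
    tibble(variable = character(0), vif = numeric(0))
  out
}

# Internal RDA engine on pre-transformed matrices: returns the pieces
# needed for both the public fit and the forward-selection loop.
rda_core <- function(y, x) {
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  qrx <- qr(xc)
  if (qrx$rank < ncol(xc)) {
    dep <- colnames(xc)[qrx$pivot[(qrx$rank + 1):ncol(xc)]]
    abort(paste0("rank-deficient constraint matrix; dependent variable(s): ",
                 paste(dep, collapse = ", ")))
  }
  fitted <- qr.fitted(qrx, yc)
  ss_total <- sum(yc^2)
  ss_fit <- sum(fitted^2)
  list(yc = yc, xc = xc, qrx = qrx, fitted = fitted,
       ss_total = ss_total, ss_fit = ss_fit)
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Redundancy analysis (RDA)
#'
#' Multivariate least squares of the (typically Hellinger-transformed)
#' community matrix on centered environmental predictors, followed by
#' eigendecomposition of the fitted values. R^2 is the constrained share of
#' total inertia; adjusted R^2 applies the Ezekiel correction
#' 1 - (1 - R^2)(n - 1)/(n - p - 1).
#'
#' @param y Community matrix (samples x taxa), e.g. from [hellinger()].
#' @param env An `env_matrix` of predictors.
#' @param variables Predictors to constrain on (default: all in `env`).
#' @return A `bloom_rda` object: `eigenvalues` (constrained), `total_inertia`,
#'   `r_squared`, `adj_r_squared`, `site_scores`, `variable_scores`,
#'   `variables`.
#' @export
rda_fit <- function(y, env, variables = NULL) {
  y <- count_matrix(y)
  x <- env_as_matrix(env, variables)
  if (nrow(y) != nrow(x)) abort("community and environment row counts differ")
  n <- nrow(y)
  p <- ncol(x)
  if (n <= p + 1) abort("RDA needs more samples than predictors + 1")
  core <- rda_core(y, x)
  # constrained axes: eigen of the fitted-value cross-product
  sv <- svd(core$fitted)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig[1], 0) * 1e-10
  eig <- eig[keep]
  u <- sv$u[, keep, drop = FALSE]
  axes <- paste0("RDA", seq_along(eig))
  site <- sweep(u, 2, sv$d[keep], "*")
  colnames(site) <- axes
  varcor <- cor(core$xc, site)
  colnames(varcor) <- axes
  r2 <- core$ss_fit / core$ss_total
  structure(
    list(
      eigenvalues = setNames(eig, axes),
      total_inertia = core$ss_total / (n - 1),
      r_squared = r2,
      adj_r_squared = adj_r2(r2, n, p),
      site_scores = dplyr::bind_cols(
        tibble(sample_id = rownames(y) %||% as.character(seq_len(n))),
        as_tibble(site)
      ),
      variable_scores = dplyr::bind_cols(
        tibble(variable = colnames(x)),
        as_tibble(varcor)
      ),
      variables = colnames(x),
      n = n
    ),
    class = "bloom_rda"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bloom_rda <- function(x, ...) {
  cat(sprintf(
    "RDA on %d predictors: R2 = %.3f, adjusted R2 = %.3f\n",
    length(x$variables), x$r_squared, x$adj_r_squared
  ))
  invisible(x)
}

#' Permutation-based forward selection of environmental variables
#'
#' Stepwise model building with the double stopping rule: at each step the
#' candidate giving the largest adjusted R^2 is considered, admitted only if
#' (i) its marginal permutation p-value (residual permutation of the reduced
#' model) is at or below `alpha` and (ii) the cumulative adjusted R^2 does
#' not exceed the full-model adjusted R^2. Selection stops at the first
#' refusal. Run the VIF screen first. Never selects a variable whose
#' marginal p exceeds `alpha`.
#'
#' @param y Community matrix (samples x taxa), e.g. from [hellinger()].
#' @param env An `env_matrix` of candidate predictors.
#' @param variables Candidate set (default: all `env` variables).
#' @param alpha Admission threshold on the permutation p-value (default
#'   0.05).
#' @param n_perm Number of residual permutations per test (default 999).
#' @param seed Integer seed (mandatory).
#' @return A `bloom_forward` object: `selection` tibble (`step`, `variable`,
#'   `adj_r2`, `p_value`), `model` (the final [rda_fit()] or NULL when
#'   nothing is admitted), `full_adj_r2`.
#' @export
forward_select <- function(y, env, variables = NULL, alpha = 0.05,
                           n_perm = 999, seed) {
  if (missing(seed)) abort("`seed` is required for forward selection")
  y <- count_matrix(y)
  x_all <- env_as_matrix(env, variables)
  n <- nrow(y)
  full_adj <- adj_r2(rda_core(y, x_all)$ss_fit / sum(scale(y, scale = FALSE)^2),
                     n, ncol(x_all))
  withr::with_seed(seed, {
    selected <- character(0)
    trace <- list()
    repeat {
      candidates <- setdiff(colnames(x_all), selected)
      if (length(candidates) == 0) break
      stats <- purrr::map_dbl(candidates, function(v) {
        core <- rda_core(y, x_all[, c(selected, v), drop = FALSE])
        adj_r2(core$ss_fit / core$ss_total, n, length(selected) + 1)
      })
      best <- candidates[which.max(stats)]
      best_adj <- max(stats)
      if (best_adj > full_adj + 1e-12) break
      pval <- marginal_perm_p(y, x_all, selected, best, n_perm)
      if (pval > alpha) break
      selected <- c(selected, best)
      trace[[length(trace) + 1]] <- tibble(
        step = length(selected), variable = best,
        adj_r2 = best_adj, p_value = pval
      )
    }
    structure(
      list(
        selection = if (length(trace)) bind_rows(trace) else
          tibble(step = integer(0), variable = character(0),
                 adj_r2 = numeric(0), p_value = numeric(0)),
        model = if (length(selected)) rda_fit(y, env, selected) else NULL,
        full_adj_r2 = full_adj,
        alpha = alpha, n_perm = as.integer(n_perm)
      ),
      class = "bloom_forward"
    )
  })
}

# Marginal permutation test for adding `candidate` to the model holding
# `selected`: permute residuals of the reduced model and compare the
# incremental F statistic.
marginal_perm_p <- function(y, x_all, selected, candidate, n_perm) {
  n <- nrow(y)
  yc <- scale(y, center = TRUE, scale = FALSE)
  if (length(selected) > 0) {
    xr <- scale(x_all[, selected, drop = FALSE], center = TRUE, scale = FALSE)
    qr_r <- qr(xr)
    fit_r <- qr.fitted(qr_r, yc)
    res_r <- yc - fit_r
    # component of the candidate orthogonal to the reduced design
    v <- x_all[, candidate] - mean(x_all[, candidate])
    v <- v - qr.fitted(qr_r, v)
  } else {
    fit_r <- matrix(0, n, ncol(yc))
    res_r <- yc
    v <- x_all[, candidate] - mean(x_all[, candidate])
  }
  v <- v / sqrt(sum(v^2))
  k <- length(selected) + 1
  f_stat <- function(res) {
    ss_add <- sum((crossprod(v, res))^2)
    ss_res_full <- sum(res^2) - ss_add
    (ss_add / 1) / (ss_res_full / (n - k - 1))
  }
  f_obs <- f_stat(res_r)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    f_stat(res_r[sample.int(n), , drop = FALSE])
  }, numeric(1))
  (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
}

#' @export
print.bloom_forward <- function(x, ...) {
  if (nrow(x$selection) == 0) {
    cat("Forward selection: no variable admitted\n")
  } else {
    cat(sprintf(
      "Forward selection: %d variable(s) admitted (full-model adj R2 = %.3f)\n",
      nrow(x$selection), x$full_adj_r2
    ))
    print(as.data.frame(x$selection), row.names = FALSE)
  }
  invisible(x)
}

#' Spearman correlations between a focal taxon and environmental variables
#'
#' Per-variable Spearman rho and two-sided p (t approximation, shared with
#' the co-occurrence network stage) between a taxon's relative abundance and
#' each environmental variable. A constant taxon vector yields missing rho
#' with a flag.
#'
#' @param taxon_rel_abund Numeric vector of the taxon's relative abundances,
#'   aligned with the rows of `env`.
#' @param env An `env_matrix` (or tibble of variables).
#' @return A tibble: `variable`, `rho`, `p_value`, `n`, `undefined`.
#' @export
taxon_env_spearman <- function(taxon_rel_abund, env) {
  m <- env_as_matrix(env)
  if (length(taxon_rel_abund) != nrow(m)) {
    abort("taxon vector length must match the environmental matrix rows")
  }
  if (length(taxon_rel_abund) < 5) abort("need at least 5 paired observations")
  purrr::map_dfr(colnames(m), function(v) {
    st <- spearman_test(taxon_rel_abund, m[, v])
    tibble(
      variable = v, rho = st$rho, p_value = st$p,
      n = st$n, undefined = is.na(st$rho)
    )
  })
}
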