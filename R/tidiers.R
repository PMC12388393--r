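# broom-style tidiers for the fitted result objects.

#' @export
tidy.bloom_pcoa <- function(x, ...) {
  x$scores
}

#' @export
glance.bloom_pcoa <- function(x, ...) {
  tibble(
    n_axes = ncol(x$scores) - 1L,
    axis1_pct = x$percent_explained[1],
    axis2_pct = if (length(x$percent_explained) >= 2) x$percent_explained[2] else NA_real_,
    n_negative_eig = length(x$negative_eigenvalues),
    correction = x$correction
  )
}

#' @export
tidy.bloom_rda <- function(x, ...) {
  x$variable_scores
}

#' @export
glance.bloom_rda <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    total_inertia = x$total_inertia,
    n_variables = length(x$variables),
    n = x$n
  )
}

#' @export
tidy.bloom_forward <- function(x, ...) {
  x$selection
}

#' @export
glance.bloom_forward <- function(x, ...) {
  tibble(
    n_selected = nrow(x$selection),
    adj_r_squared = if (is.null(x$model)) 0 else x$model$adj_r_squared,
    full_adj_r_squared = x$full_adj_r2,
    alpha = x$alpha,
    n_perm = x$n_perm
  )
}

#' @export
tidy.bloom_modules <- function(x, ...) {
  x$membership
}

#' @export
glance.bloom_modules <- function(x, ...) {
  tibble(n_modules = x$n_modules, modularity = x$modularity)
}

#' @export
tidy.bloom_corr <- function(x, ...) {
  ids <- colnames(x$rho)
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    asv_a = ids[ut[, 1]], asv_b = ids[ut[, 2]],
    rho = x$rho[upper.tri(x$rho)], p_value = x$p[upper.tri(x$p)],
    n = x$n
  )
}
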