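# Internal helpers shared across the pipeline.

# Canonical environmental variable names used throughout.
env_var_names <- function() {
  c("T", "Sal", "Depth", "pH", "DO", "Chla", "NO3", "NO2", "NH4", "PO4", "SiO3")
}

# Columns that may carry missing values in field data (bottle/nutrient assays).
nutrient_var_names <- function() {
  c("Chla", "NO3", "NO2", "NH4", "PO4", "SiO3")
}

taxonomy_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Convert a count-table tibble to a numeric matrix
#'
#' Count tables travel through the pipeline as tibbles whose first column is
#' `sample_id` and whose remaining columns are ASVs. This helper extracts the
#' numeric matrix (samples x ASVs) with sample ids as row names. Matrices and
#' data frames with row names pass through unchanged.
#'
#' @param table A count-table tibble (first column `sample_id`) or a numeric
#'   matrix with sample row names.
#' @return Numeric matrix, samples in rows, ASVs in columns.
#' @export
count_matrix <- function(table) {
  if (is.matrix(table)) {
    return(table)
  }
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)
  if (!("sample_id" %in% names(df))) {
    abort("count table must have a `sample_id` column")
  }
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

# Inverse of count_matrix(): matrix -> tibble with sample_id first.
matrix_tibble <- function(m) {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

validate_count_table <- function(table, require_integer = TRUE) {
  m <- count_matrix(table)
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate sample id: ", rownames(m)[duplicated(rownames(m))][1]))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate ASV id: ", colnames(m)[duplicated(colnames(m))][1]))
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative or non-finite count at sample '%s', ASV '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  if (require_integer && any(abs(m - round(m)) > 1e-8)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    abort(sprintf(
      "non-integer count at sample '%s', ASV '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  invisible(m)
}

# Deterministic per-stage seed derivation so stages can be re-run in
# isolation: child = (seed * 131 + offset) mod (2^31 - 1), kept positive.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, rarefy_prok = 23L, rarefy_euk = 29L,
    permanova_prok = 37L, permanova_euk = 41L,
    forward_prok = 53L, forward_euk = 59L, network = 67L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown pipeline stage for seed derivation: ", stage))
  }
  as.integer((as.double(seed) * 131 + offsets[[stage]]) %% 2147483647)
}

# Spearman rho with mid-ranks plus the t-distribution two-sided p-value
# (the Hmisc::rcorr convention); |rho| = 1 maps to p = 0.
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  exact1 <- !is.na(rho) & abs(rho) >= 1 - 1e-12
  p[exact1] <- 0
  mid <- !is.na(rho) & !exact1
  tstat <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  p[mid] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}
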