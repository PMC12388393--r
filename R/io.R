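# Readers, validators, cleanup filters and depth normalization.

#' Read a sample-by-ASV count table
#'
#' Expects a UTF-8, tab-delimited file with a header row; the first column is
#' the sample identifier and every other column an ASV. Counts must be
#' non-negative integers and sample/ASV ids unique.
#'
#' @param path Path to a TSV file.
#' @return A count-table tibble (first column `sample_id`).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(paste0("count table not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  validate_count_table(raw)
  raw
}

#' Read an ASV taxonomy table
#'
#' Accepts either rank columns (`domain` ... `genus`) or a two-column table
#' (`asv_id`, `lineage`) with semicolon-delimited, rank-prefixed lineages
#' (`d__...;p__...;c__...;o__...;f__...;g__...`). Missing ranks become
#' `"Unclassified"`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `asv_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(paste0("taxonomy table not found: ", path))
  raw <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(raw)[1] <- "asv_id"
  if (anyDuplicated(raw$asv_id)) {
    abort(paste0("duplicate ASV id in taxonomy: ", raw$asv_id[duplicated(raw$asv_id)][1]))
  }
  if ("lineage" %in% names(raw)) {
    parts <- stringr::str_split_fixed(raw$lineage, ";", length(taxonomy_ranks()))
    parts <- sub("^[a-z]__", "", parts)
    parts[parts == "" | is.na(parts)] <- "Unclassified"
    tax <- as_tibble(parts, .name_repair = ~taxonomy_ranks())
    return(dplyr::bind_cols(tibble(asv_id = raw$asv_id), tax))
  }
  missing_ranks <- setdiff(taxonomy_ranks(), names(raw))
  for (r in missing_ranks) raw[[r]] <- "Unclassified"
  out <- raw[, c("asv_id", taxonomy_ranks())]
  for (r in taxonomy_ranks()) {
    out[[r]][is.na(out[[r]]) | out[[r]] == ""] <- "Unclassified"
  }
  out
}

#' Read per-sample environmental metadata
#'
#' Requires columns `sample_id`, `region` (BR/NR), `layer` (S/M/B) and
#' accepts a `site` label plus any numeric environmental variables; numeric
#' fields may be missing but must otherwise be finite.
#'
#' @param path Path to a TSV file.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata table not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  for (col in c("region", "layer")) {
    if (!col %in% names(raw)) abort(paste0("metadata lacks required column `", col, "`"))
    if (anyNA(raw[[col]])) abort(paste0("metadata column `", col, "` has missing values"))
  }
  bad_region <- setdiff(unique(raw$region), c("BR", "NR"))
  if (length(bad_region) > 0) {
    abort(paste0("unknown region label '", bad_region[1], "' (expected BR or NR)"))
  }
  bad_layer <- setdiff(unique(raw$layer), c("S", "M", "B"))
  if (length(bad_layer) > 0) {
    abort(paste0("unknown layer label '", bad_layer[1], "' (expected S, M or B)"))
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicate sample id in metadata: ", raw$sample_id[duplicated(raw$sample_id)][1]))
  }
  num_cols <- names(raw)[vapply(raw, is.numeric, logical(1))]
  for (col in num_cols) {
    v <- raw[[col]]
    if (any(!is.na(v) & !is.finite(v))) {
      abort(paste0("non-finite value in metadata column `", col, "`"))
    }
  }
  raw
}

# case-insensitive whole-token match of a lineage rank against flagged names
lineage_has_token <- function(tax, tokens) {
  m <- tolower(as.matrix(tax[, taxonomy_ranks()]))
  apply(m, 1, function(r) any(r %in% tolower(tokens)))
}

#' Remove organelle, metazoan/plant, and phylum-unclassified ASVs
#'
#' Applies the standard post-annotation cleanup for marker-gene surveys. In
#' `prokaryote` mode, ASVs whose lineage contains `Chloroplast` or
#' `Mitochondria` at any rank are dropped; in `eukaryote` mode, lineages
#' containing `Metazoa`, `Rhodophyta`, `Streptophyta`, `Trebouxiophyceae` or
#' `Ulvophyceae` are dropped. Both modes drop ASVs unclassified at the
#' phylum level. Matching is case-insensitive on whole rank names, never on
#' substrings, so e.g. a "Chloroplastida" lineage is not a false hit. Column
#' order of surviving ASVs is preserved, and the filter is idempotent.
#'
#' @param table A count-table tibble.
#' @param tax Taxonomy tibble covering the table's ASVs.
#' @param mode `"prokaryote"` or `"eukaryote"`.
#' @return The filtered count-table tibble.
#' @export
filter_taxonomy <- function(table, tax, mode = c("prokaryote", "eukaryote")) {
  mode <- match.arg(mode)
  m <- validate_count_table(table, require_integer = FALSE)
  ids <- colnames(m)
  missing <- setdiff(ids, tax$asv_id)
  if (length(missing) > 0) {
    abort(paste0("ASV missing from taxonomy: ", missing[1]))
  }
  tax <- tax[match(ids, tax$asv_id), ]
  tokens <- if (mode == "prokaryote") {
    c("Chloroplast", "Mitochondria")
  } else {
    c("Metazoa", "Rhodophyta", "Streptophyta", "Trebouxiophyceae", "Ulvophyceae")
  }
  drop <- lineage_has_token(tax, tokens) | tolower(tax$phylum) == "unclassified"
  keep <- ids[!drop]
  if (length(keep) == 0) abort("all ASVs filtered: no taxa survive the cleanup rules")
  table[, c("sample_id", keep)]
}

#' Rarefy all samples to the minimum sequencing depth
#'
#' Randomly subsamples each sample's reads without replacement down to the
#' smallest library size in the table, so every row sum equals that minimum
#' exactly. Deterministic given `seed`.
#'
#' @param table A count-table tibble.
#' @param seed Integer seed (mandatory; subsampling is stochastic).
#' @return The rarefied count-table tibble.
#' @export
rarefy_min_depth <- function(table, seed) {
  if (missing(seed)) abort("`seed` is required for rarefaction")
  m <- validate_count_table(table)
  depths <- rowSums(m)
  if (any(depths == 0)) {
    abort(paste0("sample with zero total count: ", rownames(m)[depths == 0][1]))
  }
  d_min <- min(depths)
  out <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, d_min),
    # rrarefy emits a data-quality heuristic when no count equals 1;
    # irrelevant here since inputs are validated integer counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  matrix_tibble(out)
}

#' Convert counts to within-sample relative abundances
#'
#' @param table A count-table tibble (or matrix).
#' @return A tibble of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- count_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0("zero-sum sample: ", rownames(m)[rs == 0][1]))
  }
  matrix_tibble(sweep(m, 1, rs, "/"))
}

#' Shared and total ASVs between two regions
#'
#' An ASV is "present" in a region if it has at least one read in at least
#' one of the region's samples. Returns the shared count, the union size and
#' the shared percentage (rounded to one decimal), the summary behind a
#' two-set Venn diagram. Symmetric in its arguments.
#'
#' @param table_br,table_nr Count-table tibbles for the two regions
#'   (same marker gene, post-cleanup).
#' @return A one-row tibble: `n_shared`, `n_total`, `percent_shared`.
#' @export
shared_asv_summary <- function(table_br, table_nr) {
  present <- function(tbl) {
    m <- count_matrix(tbl)
    colnames(m)[colSums(m) > 0]
  }
  a <- present(table_br)
  b <- present(table_nr)
  n_shared <- length(intersect(a, b))
  n_total <- length(union(a, b))
  tibble(
    n_shared = n_shared, n_total = n_total,
    percent_shared = shared_percent(n_shared, n_total)
  )
}

#' Shared-ASV percentage from counts
#'
#' @param n_shared,n_total Shared and union ASV counts.
#' @return `100 * n_shared / n_total`, rounded to one decimal.
#' @export
shared_percent <- function(n_shared, n_total) {
  stopifnot(n_total > 0, n_shared >= 0, n_shared <= n_total)
  round(100 * n_shared / n_total, 1)
}

#' Classify cell density against a bloom threshold
#'
#' Applies the red-tide monitoring rule: a bloom is called when density
#' strictly exceeds the threshold (default 3e3 cells/L); equality is
#' classified `no_bloom`.
#'
#' @param density_cells_per_L Non-negative cell densities (cells/L).
#' @param threshold Bloom threshold in cells/L (default `3e3`).
#' @return Character vector of `"bloom"` / `"no_bloom"`.
#' @export
#' @examples
#' classify_bloom(c(2.8e4, 3e3, 0))
classify_bloom <- function(density_cells_per_L, threshold = 3e3) {
  if (any(!is.finite(density_cells_per_L)) || any(density_cells_per_L < 0)) {
    abort("cell density must be non-negative and finite")
  }
  ifelse(density_cells_per_L > threshold, "bloom", "no_bloom")
}
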