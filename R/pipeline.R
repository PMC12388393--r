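# Config-driven end-to-end orchestration: cleanup -> rarefaction ->
# diversity -> ordination -> per-region co-occurrence networks -> report.

default_run_config <- function() {
  list(
    focal_genus = "Noctiluca",
    r_min = 0.6,
    p_max = 0.05,
    min_abund = 1e-4,
    min_prev = 0.2,
    alpha = 0.05,
    n_perm = 999,
    seed = NULL,
    output_dir = NULL,
    bh_correct = FALSE,
    pcoa_correction = "none",
    genus_rda = TRUE,
    simulate = NULL,
    inputs = NULL
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a plain list; fills in the analysis defaults
#' (r_min 0.6, p_max 0.05, min_abund 1e-4, min_prev 0.2, alpha 0.05,
#' n_perm 999), rejects unknown keys, and checks every threshold's range.
#' Exactly one of `simulate` (a [sim_config()] block) or `inputs` (paths to
#' `prok_counts`, `euk_counts`, `taxonomy`, `metadata` TSVs) must be given,
#' and `seed` is mandatory because rarefaction and permutation tests are
#' stochastic.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file path or a named list")
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key: ", unknown[1]))
  }
  cfg <- utils::modifyList(defaults, config)
  check_range <- function(key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1 && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok) abort(sprintf("config key `%s` out of range [%s, %s]", key, lo, hi))
  }
  check_range("r_min", 0, 1, hi_open = TRUE)
  check_range("p_max", 0, 1, lo_open = TRUE)
  check_range("min_abund", 0, 1, hi_open = TRUE)
  check_range("min_prev", 0, 1, hi_open = TRUE)
  check_range("alpha", 0, 1, lo_open = TRUE)
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1) abort("config key `n_perm` out of range")
  if (is.null(cfg$seed)) abort("config key `seed` is mandatory")
  if (!is.character(cfg$pcoa_correction) ||
    !cfg$pcoa_correction %in% c("none", "cailliez")) {
    abort("config key `pcoa_correction` must be 'none' or 'cailliez'")
  }
  if (is.null(cfg$simulate) == is.null(cfg$inputs)) {
    abort("config needs exactly one of `simulate` or `inputs`")
  }
  if (!is.null(cfg$inputs)) {
    need <- c("prok_counts", "euk_counts", "taxonomy", "metadata")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing) > 0) abort(paste0("config `inputs` lacks: ", missing[1]))
  }
  if (!is.null(cfg$simulate)) {
    # validated (and given the run seed if absent) via sim_config
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(cfg$seed, "simulate")
    cfg$simulate <- do.call(sim_config, sim_args)
  }
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, report, output_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(output_dir)) {
      writeLines(
        c(paste0("FAILED at stage: ", stage), conditionMessage(e)),
        file.path(output_dir, "FAILED")
      )
      write_report_tables(report, output_dir)
    }
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full comparative bloom analysis
#'
#' Executes the analysis in the survey's order: taxonomic cleanup of both
#' markers, shared-ASV summary, minimum-depth rarefaction, alpha diversity
#' with BR-vs-NR rank-sum tests, Bray-Curtis PCoA and PERMANOVA,
#' region-by-layer environmental comparison, Hellinger RDA with VIF
#' screening and permutation forward selection, focal-taxon/environment
#' correlations, and per-region surface co-occurrence networks (integrated
#' prokaryote + eukaryote) with modules, keystones and focal-module
#' extraction. The single run seed fans out deterministically to every
#' stochastic stage, so identical configs give identical reports.
#'
#' @param config A `run_config` (see [validate_config()]), a list, or a
#'   YAML path.
#' @return A `bloom_report` list of tidy result tables (see Details), with
#'   the networks and fitted objects attached.
#' @details Report elements: `env_comparison`, `shared`, `alpha`,
#'   `alpha_tests`, `beta` (PERMANOVA + PCoA percents), `forward_selection`,
#'   `focal_env`, `network_stats`, `network_comparison`, `keystones`,
#'   `module_reports`, `flags`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list()

  data <- run_stage("input", report, out_dir, {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_community(cfg$simulate)
      list(
        prok = sim$prok, euk = sim$euk, taxonomy = sim$taxonomy,
        metadata = sim$metadata, truth = sim$truth
      )
    } else {
      list(
        prok = read_count_table(cfg$inputs$prok_counts),
        euk = read_count_table(cfg$inputs$euk_counts),
        taxonomy = read_taxonomy(cfg$inputs$taxonomy),
        metadata = read_metadata(cfg$inputs$metadata),
        truth = NULL
      )
    }
  })
  tax <- data$taxonomy
  meta <- data$metadata

  filtered <- run_stage("taxonomy_filter", report, out_dir, list(
    prok = filter_taxonomy(data$prok, tax, "prokaryote"),
    euk = filter_taxonomy(data$euk, tax, "eukaryote")
  ))

  report$shared <- run_stage("shared_asvs", report, out_dir, {
    purrr::map_dfr(c("prok", "euk"), function(mk) {
      tbl <- filtered[[mk]]
      br <- tbl[tbl$sample_id %in% meta$sample_id[meta$region == "BR"], ]
      nr <- tbl[tbl$sample_id %in% meta$sample_id[meta$region == "NR"], ]
      dplyr::bind_cols(tibble(marker = mk), shared_asv_summary(br, nr))
    })
  })

  rarefied <- run_stage("rarefaction", report, out_dir, list(
    prok = rarefy_min_depth(filtered$prok, seed = derive_seed(cfg$seed, "rarefy_prok")),
    euk = rarefy_min_depth(filtered$euk, seed = derive_seed(cfg$seed, "rarefy_euk"))
  ))

  report$alpha <- run_stage("alpha_diversity", report, out_dir, {
    purrr::map_dfr(c("prok", "euk"), function(mk) {
      dplyr::bind_cols(tibble(marker = mk), alpha_diversity(rarefied[[mk]], meta))
    })
  })
  report$alpha_tests <- run_stage("alpha_tests", report, out_dir, {
    purrr::map_dfr(c("prok", "euk"), function(mk) {
      a <- report$alpha[report$alpha$marker == mk, ]
      purrr::map_dfr(c("sobs", "shannon", "pielou"), function(ix) {
        v <- a[[ix]]
        ok <- is.finite(v)
        ht <- wilcoxon_rank_sum(v[ok & a$region == "BR"], v[ok & a$region == "NR"])
        dplyr::bind_cols(tibble(marker = mk, index = ix), ht)
      })
    })
  })

  beta <- run_stage("beta_diversity", report, out_dir, {
    purrr::map(setNames(c("prok", "euk"), c("prok", "euk")), function(mk) {
      d <- bray_curtis(rarefied[[mk]])
      ids <- labels(d)
      groups <- meta$region[match(ids, meta$sample_id)]
      pv <- permanova(d, groups,
        n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, paste0("permanova_", mk))
      )
      pc <- pcoa(d, n_axes = 2, correction = cfg$pcoa_correction)
      list(dist = d, permanova = pv, pcoa = pc)
    })
  })
  report$beta <- purrr::map_dfr(c("prok", "euk"), function(mk) {
    b <- beta[[mk]]
    tibble(
      marker = mk,
      permanova_F = b$permanova$pseudo_F,
      permanova_R2 = b$permanova$R2,
      permanova_p = b$permanova$p_value,
      axis1_pct = b$pcoa$percent_explained[1],
      axis2_pct = b$pcoa$percent_explained[2]
    )
  })

  report$env_comparison <- run_stage(
    "environment_comparison", report, out_dir,
    group_compare_environment(meta)
  )

  env <- run_stage("environment_matrix", report, out_dir, prepare_env(meta))
  retained <- run_stage("vif_screen", report, out_dir, vif_screen(env))

  fwd <- run_stage("forward_selection", report, out_dir, {
    purrr::map(setNames(c("prok", "euk"), c("prok", "euk")), function(mk) {
      tbl <- rarefied[[mk]]
      if (isTRUE(cfg$genus_rda)) tbl <- aggregate_genus(tbl, tax)
      forward_select(
        hellinger(tbl), env,
        variables = as.character(retained),
        alpha = cfg$alpha, n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, paste0("forward_", mk))
      )
    })
  })
  report$forward_selection <- purrr::map_dfr(c("prok", "euk"), function(mk) {
    sel <- fwd[[mk]]$selection
    if (nrow(sel) == 0) return(tibble(
      marker = mk, step = NA_integer_, variable = NA_character_,
      adj_r2 = NA_real_, p_value = NA_real_
    ))
    dplyr::bind_cols(tibble(marker = mk), sel)
  })

  report$focal_env <- run_stage("focal_taxon_environment", report, out_dir, {
    rel <- relative_abundance(rarefied$euk)
    m <- count_matrix(rel)
    focal_ids <- tax$asv_id[tax$genus == cfg$focal_genus]
    focal_ids <- intersect(focal_ids, colnames(m))
    if (length(focal_ids) == 0) {
      tibble(variable = character(0), rho = numeric(0), p_value = numeric(0),
             n = integer(0), undefined = logical(0))
    } else {
      focal_abund <- rowSums(m[, focal_ids, drop = FALSE])
      taxon_env_spearman(focal_abund, env)
    }
  })

  nets <- run_stage("networks", report, out_dir, {
    purrr::map(setNames(c("BR", "NR"), c("BR", "NR")), function(rg) {
      ids <- meta$sample_id[meta$region == rg & meta$layer == "S"]
      build_region_network(
        rarefied, tax, ids,
        min_abund = cfg$min_abund, min_prev = cfg$min_prev,
        r_min = cfg$r_min, p_max = cfg$p_max,
        bh_correct = cfg$bh_correct, region = rg
      )
    })
  })
  report$network_stats <- purrr::map_dfr(c("BR", "NR"), function(rg) {
    dplyr::bind_cols(tibble(region = rg), nets[[rg]]$stats)
  })
  report$network_comparison <- compare_regions(nets$BR$stats, nets$NR$stats)
  report$keystones <- purrr::map_dfr(c("BR", "NR"), function(rg) {
    ks <- keystone_rank(nets[[rg]]$graph)
    if (nrow(ks) == 0) return(tibble(region = character(0)))
    dplyr::bind_cols(tibble(region = rg), ks)
  })
  report$module_reports <- run_stage("module_extraction", report, out_dir, {
    purrr::map(nets, function(nt) {
      extract_modules(nt$graph, nt$modules, cfg$focal_genus, tax)
    })
  })

  report$flags <- run_stage("summary_flags", report, out_dir, {
    a <- report$alpha
    lower_alpha <- all(vapply(c("sobs", "shannon", "pielou"), function(ix) {
      mean(a[[ix]][a$region == "BR"], na.rm = TRUE) <
        mean(a[[ix]][a$region == "NR"], na.rm = TRUE)
    }, logical(1)))
    ns <- report$network_stats
    # complexity direction rests on network size (connected nodes, edges):
    # with 6 vs 9 samples the attainable Spearman p-levels differ between
    # regions, which makes per-node density metrics incommensurable
    lower_complexity <- all(
      ns$n_nodes[ns$region == "BR"] < ns$n_nodes[ns$region == "NR"],
      ns$n_edges[ns$region == "BR"] < ns$n_edges[ns$region == "NR"]
    )
    tibble(
      flag = c("br_lower_alpha_diversity", "br_lower_network_complexity"),
      value = c(lower_alpha, lower_complexity)
    )
  })

  report$networks <- nets
  report$pcoa <- purrr::map(beta, "pcoa")
  report$permanova <- purrr::map(beta, "permanova")
  report$forward_fits <- fwd
  report$vif_retained <- as.character(retained)
  report$truth <- data$truth
  report$config <- cfg
  class(report) <- "bloom_report"

  if (!is.null(out_dir)) {
    write_report_tables(report, out_dir)
    for (rg in c("BR", "NR")) {
      write_graphml(
        nets[[rg]]$graph, nets[[rg]]$modules,
        file.path(out_dir, paste0("network_", rg, ".graphml"))
      )
    }
  }
  report
}

# Build the integrated (prokaryote + eukaryote) co-occurrence network for
# one region's surface samples: per-marker relative abundances, per-marker
# abundance/prevalence filters, concatenation, Spearman, thresholding.
build_region_network <- function(rarefied, tax, sample_ids, min_abund, min_prev,
                                 r_min, p_max, bh_correct = FALSE,
                                 region = NA_character_) {
  mats <- purrr::map(c(prok = "prok", euk = "euk"), function(mk) {
    tbl <- rarefied[[mk]]
    sub <- tbl[tbl$sample_id %in% sample_ids, ]
    rel <- relative_abundance(sub)
    keep <- network_filter(rel, min_abund = min_abund, min_prev = min_prev)
    count_matrix(rel)[, keep, drop = FALSE]
  })
  combined <- cbind(mats$prok, mats$euk)
  domain <- c(
    rep("prokaryote", ncol(mats$prok)),
    rep("eukaryote", ncol(mats$euk))
  )
  tax_idx <- match(colnames(combined), tax$asv_id)
  node_meta <- tibble(
    asv_id = colnames(combined),
    domain = domain,
    genus = tax$genus[tax_idx],
    lineage = lineage_string(tax[tax_idx, ]),
    mean_rel_abund = colMeans(combined)
  )
  corr <- spearman_matrix(combined)
  g <- build_network(corr, node_meta,
    r_min = r_min, p_max = p_max,
    region = region, bh_correct = bh_correct
  )
  modules <- fast_greedy_modules(g)
  list(graph = g, modules = modules, stats = network_stats(g, modules))
}

write_report_tables <- function(report, out_dir) {
  tables <- c(
    "env_comparison", "shared", "alpha", "alpha_tests", "beta",
    "forward_selection", "focal_env", "network_stats",
    "network_comparison", "keystones", "flags"
  )
  for (nm in tables) {
    if (!is.null(report[[nm]]) && is.data.frame(report[[nm]])) {
      readr::write_tsv(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
        progress = FALSE
      )
    }
  }
  invisible(out_dir)
}

#' @export
print.bloom_report <- function(x, ...) {
  cat("Comparative bloom analysis report\n")
  if (!is.null(x$beta)) {
    for (i in seq_len(nrow(x$beta))) {
      cat(sprintf(
        "  %s PERMANOVA: F = %.2f, R2 = %.3f, p = %.3f\n",
        x$beta$marker[i], x$beta$permanova_F[i], x$beta$permanova_R2[i],
        x$beta$permanova_p[i]
      ))
    }
  }
  if (!is.null(x$network_stats)) {
    print(as.data.frame(x$network_stats[, c(
      "region", "n_nodes", "n_edges",
      "average_degree", "n_modules", "modularity"
    )]), row.names = FALSE)
  }
  if (!is.null(x$flags)) {
    for (i in seq_len(nrow(x$flags))) {
      cat(sprintf("  %s: %s\n", x$flags$flag[i], x$flags$value[i]))
    }
  }
  invisible(x)
}
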