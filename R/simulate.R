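#' Configuration for the synthetic community generator
#'
#' Builds and validates the parameter set for [simulate_community()]. The
#' defaults emulate the sampling design of a coastal *Noctiluca scintillans*
#' bloom survey: 6 bloom-region (BR) sites, 9 reference-region (NR) sites,
#' three depth layers (surface/middle/bottom), a eukaryote bloom taxon at
#' ~96% relative abundance in BR surface waters, ammonium and phosphate
#' covarying with the bloom, planted correlated taxon modules, and a
#' richness deficit in the bloom region.
#'
#' @param n_sites_br,n_sites_nr Number of sites in the bloom and reference
#'   regions.
#' @param layers Ordered depth-layer labels.
#' @param n_prok_taxa,n_euk_taxa Number of ASVs in the 16S and 18S tables.
#' @param depth_per_sample Target library size; per-sample depths are
#'   log-normally jittered around it.
#' @param bloom_taxon_fraction_surface Expected relative abundance of the
#'   bloom taxon in BR surface samples, in (0, 1).
#' @param n_modules,module_size Number and size of planted co-occurring taxon
#'   modules (prokaryote table).
#' @param module_rho Target expected pairwise Spearman correlation within a
#'   planted module, in (0, 1).
#' @param env_effect Named numeric vector of per-variable multiplicative
#'   responses to bloom-taxon relative abundance; names must be environmental
#'   variables (see Details). Variables with non-zero effect are the true
#'   environmental drivers recorded in the ground truth.
#' @param richness_deficit_br Fraction of the low-abundance shared taxon pool
#'   whose expectation is set to zero in BR samples, in \[0, 1).
#' @param env_missing_frac Fraction of nutrient measurements set missing at
#'   random (exercises mean imputation downstream).
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @details Environmental variables are `T`, `Sal`, `Depth`, `pH`, `DO`,
#'   `Chla`, `NO3`, `NO2`, `NH4`, `PO4`, `SiO3`. Per-layer baselines are the
#'   reference-region field values of the emulated survey and are shared by
#'   both regions, so regional environmental contrasts arise only through
#'   `env_effect`.
#'
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' names(cfg)
sim_config <- function(n_sites_br = 6,
                       n_sites_nr = 9,
                       layers = c("S", "M", "B"),
                       n_prok_taxa = 300,
                       n_euk_taxa = 150,
                       depth_per_sample = 50000,
                       bloom_taxon_fraction_surface = 0.96,
                       n_modules = 3,
                       module_size = 8,
                       module_rho = 0.9,
                       env_effect = c(NH4 = 6.3, PO4 = 1.8),
                       richness_deficit_br = 0.3,
                       env_missing_frac = 0.05,
                       seed = 1) {
  cfg <- list(
    n_sites_br = as.integer(n_sites_br),
    n_sites_nr = as.integer(n_sites_nr),
    layers = as.character(layers),
    n_prok_taxa = as.integer(n_prok_taxa),
    n_euk_taxa = as.integer(n_euk_taxa),
    depth_per_sample = as.integer(depth_per_sample),
    bloom_taxon_fraction_surface = bloom_taxon_fraction_surface,
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_rho = module_rho,
    env_effect = env_effect,
    richness_deficit_br = richness_deficit_br,
    env_missing_frac = env_missing_frac,
    seed = as.integer(seed)
  )
  counts <- c(
    "n_sites_br", "n_sites_nr", "n_prok_taxa", "n_euk_taxa",
    "depth_per_sample", "module_size"
  )
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      abort(paste0("`", f, "` must be a single count >= 1"))
    }
  }
  if (cfg$n_modules < 0) abort("`n_modules` must be >= 0")
  for (f in c("bloom_taxon_fraction_surface", "module_rho")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      abort(paste0("`", f, "` must lie in (0, 1)"))
    }
  }
  if (cfg$richness_deficit_br < 0 || cfg$richness_deficit_br >= 1) {
    abort("`richness_deficit_br` must lie in [0, 1)")
  }
  if (cfg$env_missing_frac < 0 || cfg$env_missing_frac >= 1) {
    abort("`env_missing_frac` must lie in [0, 1)")
  }
  if (length(cfg$env_effect) > 0) {
    bad <- setdiff(names(cfg$env_effect), env_var_names())
    if (length(bad) > 0) {
      abort(paste0("unknown environmental variable in `env_effect`: ", bad[1]))
    }
  }
  if (length(cfg$layers) < 1 || anyDuplicated(cfg$layers)) {
    abort("`layers` must be distinct labels")
  }
  structure(cfg, class = "sim_config")
}

# Per-layer environmental baselines (reference-region surface/middle/bottom
# field values of the emulated survey). Shared by both regions so that the
# planted bloom response is the only systematic regional contrast.
env_baselines <- function() {
  tibble(
    layer = c("S", "M", "B"),
    T = c(23.5, 22.9, 22.9),
    Sal = c(29.1, 29.5, 29.6),
    Depth = c(0.1, 5.1, 10.0),
    pH = c(7.6, 7.6, 7.6),
    DO = c(7.1, 7.1, 7.1),
    Chla = c(2.1, 2.1, 3.1),
    NO3 = c(240.8, 97.3, 90.9),
    NO2 = c(28.9, 21.0, 21.4),
    NH4 = c(130.2, 316.1, 311.1),
    PO4 = c(27.2, 10.8, 12.4),
    SiO3 = c(260.4, 574.4, 502.2)
  )
}

# Expected bloom-taxon relative abundance per region x layer; the surface
# bloom value comes from the config, the rest are the genus-level fractions
# characteristic of the emulated survey. Cell densities (cells/L) are
# surface-concentrated in the bloom region: relative dominance persists at
# depth (sinking cells in a thin eukaryote community) while absolute
# density, which drives the environmental response, does not.
default_bloom_profile <- function(surface_fraction) {
  tibble(
    region = c("BR", "BR", "BR", "NR", "NR", "NR"),
    layer = c("S", "M", "B", "S", "M", "B"),
    fraction = c(surface_fraction, 0.39, 0.32, 0.20, 0.31, 0.21),
    density_cells_per_L = c(1.5e4, 2000, 800, 300, 200, 100)
  )
}

prok_genus_pool <- function() {
  c(
    "Nautella", "Marivivens", "HIMB11", "Aurantivirga", "Donghicola",
    "Synechococcus_CC9902", "Candidatus_Actinomarina", "Litorimicrobium",
    "Halomonas", "Lutimaribacter", "Roseibacillus", "Sva0996_marine_group",
    "Polaribacter", "Sulfitobacter", "Lentibacter", "Planktomarina"
  )
}

euk_genus_pool <- function() {
  c(
    "Dino-Group-I-Clade-1_X", "Dorataspis_F3", "Micromonas", "Lepidodinium",
    "Protaspa", "Minutocellus", "Gymnodinium", "Chaetoceros", "Teleaulax",
    "Pterosperma", "Cryothecomonas", "Skeletonema"
  )
}

# Build a taxonomy tibble for one marker, planting cleanup-filter targets:
# chloroplast/mitochondria lineages in the prokaryote table, metazoan/plant
# lineages in the eukaryote table, and phylum-level unclassified ASVs in both.
simulate_taxonomy <- function(ids, marker) {
  n <- length(ids)
  if (marker == "prok") {
    phyla <- c(
      "Proteobacteria", "Bacteroidota", "Actinobacteriota",
      "Cyanobacteria", "Verrucomicrobiota", "Planctomycetota"
    )
    tax <- tibble(
      asv_id = ids,
      domain = "Bacteria",
      phylum = sample(phyla, n, replace = TRUE),
      class = paste0(sample(phyla, n, replace = TRUE), "ia"),
      order = paste0("Order_", sample.int(40, n, replace = TRUE)),
      family = paste0("Family_", sample.int(60, n, replace = TRUE)),
      genus = sample(prok_genus_pool(), n, replace = TRUE)
    )
    n_chloro <- max(2L, round(0.02 * n))
    n_mito <- max(1L, round(0.01 * n))
    n_unk <- max(2L, round(0.02 * n))
    idx <- n - seq_len(n_chloro + n_mito + n_unk) + 1L
    chloro <- idx[seq_len(n_chloro)]
    mito <- idx[n_chloro + seq_len(n_mito)]
    unk <- idx[n_chloro + n_mito + seq_len(n_unk)]
    tax$order[chloro] <- "Chloroplast"
    tax$phylum[chloro] <- "Cyanobacteria"
    tax$family[mito] <- "Mitochondria"
    tax$phylum[unk] <- "Unclassified"
  } else {
    phyla <- c("Dinoflagellata", "Ochrophyta", "Chlorophyta", "Cercozoa", "Ciliophora")
    tax <- tibble(
      asv_id = ids,
      domain = "Eukaryota",
      phylum = sample(phyla, n, replace = TRUE),
      class = paste0(sample(phyla, n, replace = TRUE), "_X"),
      order = paste0("Order_", sample.int(30, n, replace = TRUE)),
      family = paste0("Family_", sample.int(40, n, replace = TRUE)),
      genus = sample(euk_genus_pool(), n, replace = TRUE)
    )
    # the bloom taxon is always the first ASV
    tax$phylum[1] <- "Dinoflagellata"
    tax$class[1] <- "Dinophyceae"
    tax$order[1] <- "Noctilucales"
    tax$family[1] <- "Noctilucaceae"
    tax$genus[1] <- "Noctiluca"
    n_metazoa <- max(2L, round(0.02 * n))
    n_plant <- max(1L, round(0.01 * n))
    n_unk <- max(2L, round(0.02 * n))
    idx <- n - seq_len(n_metazoa + n_plant + n_unk) + 1L
    metazoa <- idx[seq_len(n_metazoa)]
    plant <- idx[n_metazoa + seq_len(n_plant)]
    unk <- idx[n_metazoa + n_plant + seq_len(n_unk)]
    tax$phylum[metazoa] <- "Metazoa"
    tax$phylum[plant] <- sample(
      c("Rhodophyta", "Streptophyta", "Trebouxiophyceae", "Ulvophyceae"),
      n_plant,
      replace = TRUE
    )
    tax$phylum[unk] <- "Unclassified"
  }
  tax
}

#' Simulate a paired 16S/18S bloom-survey community
#'
#' Generates prokaryote and eukaryote ASV count tables, a taxonomy table,
#' per-sample environmental metadata, and a ground-truth record describing
#' every planted structure. Abundances follow a log-normal species-abundance
#' model with per-sample logistic-normal jitter and multinomial read
#' sampling; planted modules share a latent log-abundance factor calibrated
#' so realized pairwise Spearman correlations reach the configured target;
#' the eukaryote bloom taxon's expected relative abundance follows a
#' region-by-layer profile peaking in bloom-region surface samples; true
#' environmental drivers respond linearly to bloom relative abundance; and a
#' configurable fraction of the rare shared taxon pool is suppressed in BR
#' samples, depressing richness and evenness there.
#'
#' @param config A [sim_config()] object.
#' @return A `bloom_sim` list with elements `prok` and `euk` (count-table
#'   tibbles, first column `sample_id`), `taxonomy` (tibble with rank
#'   columns), `metadata` (sample tibble with region, layer, site and
#'   environmental variables), and `truth` (ground-truth list: module
#'   assignment, bloom taxon id, true drivers, bloom profile, suppressed
#'   taxa).
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_prok_taxa = 60, n_euk_taxa = 40,
#'                                      depth_per_sample = 2000, seed = 7))
#' dim(count_matrix(sim$prok))
simulate_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(config) {
  layers <- config$layers
  sites <- c(
    paste0("BR", seq_len(config$n_sites_br)),
    paste0("NR", seq_len(config$n_sites_nr))
  )
  samples <- tidyr::expand_grid(site = sites, layer = layers) %>%
    mutate(
      region = ifelse(grepl("^BR", .data$site), "BR", "NR"),
      sample_id = paste0(.data$site, "_", .data$layer)
    ) %>%
    select("sample_id", "region", "layer", "site")

  prok_ids <- sprintf("pASV_%04d", seq_len(config$n_prok_taxa))
  euk_ids <- sprintf("eASV_%04d", seq_len(config$n_euk_taxa))
  tax <- bind_rows(
    simulate_taxonomy(prok_ids, "prok"),
    simulate_taxonomy(euk_ids, "euk")
  )

  # --- planted module memberships (prokaryote table) -----------------------
  n_module_taxa <- config$n_modules * config$module_size
  prok_tax <- tax[match(prok_ids, tax$asv_id), ]
  flagged_prok <- prok_tax$order == "Chloroplast" |
    prok_tax$family == "Mitochondria" | prok_tax$phylum == "Unclassified"
  eligible_prok <- prok_ids[!flagged_prok]
  if (n_module_taxa > 0 && n_module_taxa > length(eligible_prok)) {
    abort(sprintf(
      "planted modules need %d taxa but only %d eligible prokaryote ASVs exist",
      n_module_taxa, length(eligible_prok)
    ))
  }

  # log-normal species-abundance model
  mu_prok <- rnorm(config$n_prok_taxa, 0, 1.5)
  mu_euk <- rnorm(config$n_euk_taxa, 0, 1.5)
  names(mu_prok) <- prok_ids
  names(mu_euk) <- euk_ids
  # keep filter-target ASVs rare so cleanup does not reshape the community
  mu_prok[flagged_prok] <- mu_prok[flagged_prok] - 2
  euk_tax <- tax[match(euk_ids, tax$asv_id), ]
  flagged_euk <- euk_tax$phylum %in%
    c("Metazoa", "Rhodophyta", "Streptophyta", "Trebouxiophyceae", "Ulvophyceae", "Unclassified")
  mu_euk[flagged_euk] <- mu_euk[flagged_euk] - 2

  # module members: abundant (top ranks after the 5 most dominant) so count
  # noise barely attenuates the planted correlation
  module_assignment <- tibble(asv_id = character(0), module = integer(0))
  module_of <- setNames(rep(NA_integer_, config$n_prok_taxa), prok_ids)
  if (n_module_taxa > 0) {
    ord <- order(mu_prok[eligible_prok], decreasing = TRUE)
    member_ids <- eligible_prok[ord[5 + seq_len(n_module_taxa)]]
    module_of[member_ids] <- rep(seq_len(config$n_modules), each = config$module_size)
    module_assignment <- tibble(
      asv_id = member_ids,
      module = unname(module_of[member_ids])
    )
  }

  # richness-deficit pool: low-abundance shared taxa (never modules, bloom
  # taxon, or filter targets), suppressed in all BR samples
  suppress_pool_prok <- setdiff(
    prok_ids[mu_prok < stats::median(mu_prok)],
    c(names(module_of)[!is.na(module_of)], prok_ids[flagged_prok])
  )
  suppress_pool_euk <- setdiff(
    euk_ids[mu_euk < stats::median(mu_euk)],
    c(euk_ids[1], euk_ids[flagged_euk])
  )
  n_sup_prok <- round(config$richness_deficit_br * length(suppress_pool_prok))
  n_sup_euk <- round(config$richness_deficit_br * length(suppress_pool_euk))
  suppressed <- c(
    if (n_sup_prok > 0) sample(suppress_pool_prok, n_sup_prok),
    if (n_sup_euk > 0) sample(suppress_pool_euk, n_sup_euk)
  )

  # a copiotroph responder in the prokaryote table: the most abundant
  # eligible non-module taxon blooms alongside the focal eukaryote,
  # recreating the strong surface-layer prokaryote community shift that
  # accompanies a dinoflagellate bloom
  responder_pool <- setdiff(eligible_prok, names(module_of)[!is.na(module_of)])
  responder_id <- responder_pool[which.max(mu_prok[responder_pool])]
  tax$genus[tax$asv_id == responder_id] <- "Nautella"
  resp_effect <- 2.5

  bloom_profile <- default_bloom_profile(config$bloom_taxon_fraction_surface)
  # latent Pearson correlation implied by the target Spearman (Greiner's
  # relation for bivariate normals) with a small margin for sampling
  # attenuation on counts
  rho_latent <- min(0.995, 1.02 * 2 * sin(pi * config$module_rho / 6))
  tau <- 1.0 # per-sample log-abundance jitter sd

  n_samp <- nrow(samples)
  draw_depth <- function() {
    pmax(100L, as.integer(round(config$depth_per_sample * exp(rnorm(n_samp, 0, 0.15)))))
  }
  depths_prok <- draw_depth()
  depths_euk <- draw_depth()

  prof_key <- paste(bloom_profile$region, bloom_profile$layer)
  frac_of <- setNames(bloom_profile$fraction, prof_key)
  sample_bloom_frac <- plogis(
    qlogis(unname(frac_of[paste(samples$region, samples$layer)])) +
      rnorm(n_samp, 0, 0.2)
  )
  dens_of <- setNames(bloom_profile$density_cells_per_L, prof_key)
  sample_density <- unname(dens_of[paste(samples$region, samples$layer)]) *
    exp(rnorm(n_samp, 0, 0.2))
  # bloom intensity, normalized so a typical BR surface sample sits near 1;
  # environmental drivers and the copiotroph respond to this, not to the
  # relative-abundance profile
  intensity <- sample_density / 1.5e4

  counts_prok <- matrix(0L, n_samp, config$n_prok_taxa,
    dimnames = list(samples$sample_id, prok_ids)
  )
  counts_euk <- matrix(0L, n_samp, config$n_euk_taxa,
    dimnames = list(samples$sample_id, euk_ids)
  )
  for (s in seq_len(n_samp)) {
    in_br <- samples$region[s] == "BR"
    f <- rnorm(config$n_modules)
    eps <- rnorm(config$n_prok_taxa)
    jit <- tau * eps
    mem <- !is.na(module_of)
    if (any(mem)) {
      jit[mem] <- tau * (sqrt(rho_latent) * f[module_of[mem]] +
        sqrt(1 - rho_latent) * eps[mem])
    }
    w <- exp(mu_prok + jit)
    w[responder_id] <- w[responder_id] * exp(resp_effect * intensity[s])
    if (in_br) w[prok_ids %in% suppressed] <- 0
    counts_prok[s, ] <- rmultinom(1, depths_prok[s], w / sum(w))

    w_e <- exp(mu_euk + tau * rnorm(config$n_euk_taxa))
    if (in_br) w_e[euk_ids %in% suppressed] <- 0
    w_e[1] <- 0
    p_e <- (1 - sample_bloom_frac[s]) * w_e / sum(w_e)
    p_e[1] <- sample_bloom_frac[s]
    counts_euk[s, ] <- rmultinom(1, depths_euk[s], p_e)
  }

  # --- environmental metadata ----------------------------------------------
  base <- env_baselines()
  base <- base[match(samples$layer, base$layer), ]
  env <- as.data.frame(base[, env_var_names()])
  for (v in env_var_names()) {
    beta <- if (v %in% names(config$env_effect)) config$env_effect[[v]] else 0
    env[[v]] <- env[[v]] * (1 + beta * intensity) *
      exp(rnorm(n_samp, 0, 0.08))
  }
  if (config$env_missing_frac > 0) {
    for (v in nutrient_var_names()) {
      miss <- stats::runif(n_samp) < config$env_missing_frac
      env[[v]][miss] <- NA_real_
    }
  }
  metadata <- dplyr::bind_cols(
    samples,
    as_tibble(round(env, 3)),
    tibble(noctiluca_density = round(sample_density, 1))
  )

  truth <- structure(
    list(
      module_assignment = module_assignment,
      bloom_taxon_id = euk_ids[1],
      bloom_responder_id = responder_id,
      true_env_drivers = names(config$env_effect)[
        vapply(config$env_effect, function(x) x != 0, logical(1))
      ],
      bloom_profile = bloom_profile,
      suppressed_taxa = tibble(
        asv_id = suppressed,
        table = ifelse(grepl("^p", suppressed), "prok", "euk")
      )
    ),
    class = "bloom_truth"
  )

  structure(
    list(
      prok = matrix_tibble(counts_prok),
      euk = matrix_tibble(counts_euk),
      taxonomy = tax,
      metadata = metadata,
      truth = truth,
      config = config
    ),
    class = "bloom_sim"
  )
}

#' @export
print.bloom_sim <- function(x, ...) {
  cat("Synthetic bloom-survey community\n")
  cat(sprintf(
    "  %d samples (%d BR, %d NR), %d prokaryote + %d eukaryote ASVs\n",
    nrow(x$metadata), sum(x$metadata$region == "BR"),
    sum(x$metadata$region == "NR"),
    ncol(x$prok) - 1L, ncol(x$euk) - 1L
  ))
  cat(sprintf(
    "  bloom taxon %s; %d planted modules; %d suppressed BR taxa\n",
    x$truth$bloom_taxon_id,
    max(c(0L, x$truth$module_assignment$module)),
    nrow(x$truth$suppressed_taxa)
  ))
  invisible(x)
}

lineage_string <- function(tax) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__")
  apply(
    as.matrix(tax[, taxonomy_ranks()]), 1,
    function(r) paste0(prefixes, r, collapse = ";")
  )
}

#' Write a simulated dataset to TSV fixtures
#'
#' Writes the count tables, taxonomy, metadata and ground truth as
#' tab-separated files plus a `MANIFEST.tsv` with SHA-256 checksums, so a
#' fixture directory is self-validating.
#'
#' @param sim A `bloom_sim` object from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`file`, `sha256`).
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "bloom_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    prok_counts = "prok_counts.tsv", euk_counts = "euk_counts.tsv",
    taxonomy = "taxonomy.tsv", metadata = "metadata.tsv",
    ground_truth = "ground_truth.tsv"
  )
  tax_out <- tibble(asv_id = sim$taxonomy$asv_id, lineage = lineage_string(sim$taxonomy))
  truth <- sim$truth
  truth_out <- bind_rows(
    tibble(
      field = "module",
      key = truth$module_assignment$asv_id,
      value = as.character(truth$module_assignment$module)
    ),
    tibble(field = "bloom_taxon", key = "bloom_taxon_id", value = truth$bloom_taxon_id),
    tibble(field = "bloom_responder", key = "bloom_responder_id", value = truth$bloom_responder_id),
    tibble(field = "env_driver", key = truth$true_env_drivers, value = ""),
    tibble(
      field = "bloom_profile",
      key = paste(truth$bloom_profile$region, truth$bloom_profile$layer, sep = "_"),
      value = as.character(truth$bloom_profile$fraction)
    ),
    tibble(
      field = "suppressed",
      key = truth$suppressed_taxa$asv_id,
      value = truth$suppressed_taxa$table
    )
  )
  objs <- list(sim$prok, sim$euk, tax_out, sim$metadata, truth_out)
  for (i in seq_along(paths)) {
    path <- file.path(dir, paths[[i]])
    tryCatch(
      readr::write_tsv(objs[[i]], path, progress = FALSE),
      error = function(e) abort(paste0("failed writing fixture file ", path, ": ", conditionMessage(e)))
    )
  }
  manifest <- tibble(
    file = unname(paths),
    sha256 = vapply(
      file.path(dir, paths),
      function(p) digest::digest(file = p, algo = "sha256"),
      character(1)
    )
  )
  readr::write_tsv(manifest, file.path(dir, "MANIFEST.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Read a fixture directory back, verifying checksums
#'
#' @param dir Directory written by [write_fixture()].
#' @param verify Verify SHA-256 checksums against the manifest (default TRUE).
#' @return A list with `prok`, `euk`, `taxonomy`, `metadata`, `truth`.
#' @export
read_fixture <- function(dir, verify = TRUE) {
  manifest <- readr::read_tsv(file.path(dir, "MANIFEST.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  if (verify) {
    for (i in seq_len(nrow(manifest))) {
      path <- file.path(dir, manifest$file[i])
      got <- digest::digest(file = path, algo = "sha256")
      if (!identical(got, manifest$sha256[i])) {
        abort(paste0("checksum mismatch for fixture file ", path))
      }
    }
  }
  truth_raw <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  prof <- truth_raw[truth_raw$field == "bloom_profile", ]
  prof_parts <- stringr::str_split_fixed(prof$key, "_", 2)
  truth <- structure(
    list(
      module_assignment = tibble(
        asv_id = truth_raw$key[truth_raw$field == "module"],
        module = as.integer(truth_raw$value[truth_raw$field == "module"])
      ),
      bloom_taxon_id = truth_raw$value[truth_raw$field == "bloom_taxon"][1],
      bloom_responder_id = truth_raw$value[truth_raw$field == "bloom_responder"][1],
      true_env_drivers = truth_raw$key[truth_raw$field == "env_driver"],
      bloom_profile = tibble(
        region = prof_parts[, 1], layer = prof_parts[, 2],
        fraction = as.numeric(prof$value)
      ),
      suppressed_taxa = tibble(
        asv_id = truth_raw$key[truth_raw$field == "suppressed"],
        table = truth_raw$value[truth_raw$field == "suppressed"]
      )
    ),
    class = "bloom_truth"
  )
  list(
    prok = read_count_table(file.path(dir, "prok_counts.tsv")),
    euk = read_count_table(file.path(dir, "euk_counts.tsv")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    metadata = read_metadata(file.path(dir, "metadata.tsv")),
    truth = truth
  )
}
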