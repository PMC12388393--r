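# Transforms, imputation, VIF screening, RDA and forward selection.

test_that("Hellinger rows are unit-norm square-root proportions", {
  tbl <- tibble::tibble(sample_id = c("a", "b"), x = c(1L, 4L), y = c(1L, 0L))
  h <- hellinger(tbl)
  expect_equal(unname(h["a", ]), c(sqrt(0.5), sqrt(0.5)))
  expect_equal(unname(h["b", ]), c(1, 0))
  withr::with_seed(2, m <- matrix(rpois(50, 8) + 1L, nrow = 5,
    dimnames = list(paste0("s", 1:5), paste0("t", 1:10))))
  expect_equal(unname(sqrt(rowSums(hellinger(m)^2))), rep(1, 5), tolerance = 1e-12)
})

test_that("genus aggregation sums ASVs by genus and keeps unclassified lineages apart", {
  tbl <- toy_counts()
  tax <- toy_taxonomy(paste0("ASV", 1:5))
  tax$genus <- c("G1", "G1", "G2", "Unclassified", "Unclassified")
  tax$family <- c("F1", "F1", "F1", "FA", "FB")
  agg <- aggregate_genus(tbl, tax)
  m <- count_matrix(agg)
  expect_equal(unname(m[, "G1"]), unname(rowSums(count_matrix(tbl)[, c("ASV1", "ASV2")])))
  expect_setequal(colnames(m), c("G1", "G2", "Unclassified_FA", "Unclassified_FB"))
})

test_that("environment preparation imputes means before the log10(x+1) transform", {
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c"), region = "NR", layer = "S",
    NH4 = c(1, NA, 3), PO4 = c(2, 2, 2), SiO3 = c(NA, NA, NA)
  )
  expect_warning(env <- prepare_env(meta), "SiO3")
  expect_equal(env$NH4, log10(c(2, 3, 4)), tolerance = 1e-12)
  expect_equal(env$NH4[2], 0.4771, tolerance = 1e-4)
  expect_false("SiO3" %in% names(env))
  imp <- attr(env, "imputed")
  expect_identical(unname(imp[, "NH4"]), c(FALSE, TRUE, FALSE))
  expect_false(any(imp[, "PO4"]))
})

test_that("VIF screening matches explicit regression and removes collinear columns", {
  withr::with_seed(4, {
    n <- 40
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    x3 <- 0.9 * x1 + 0.4 * x2 + rnorm(n, 0, 0.3)
    env <- tibble::tibble(sample_id = paste0("s", 1:n), A = x1, B = x2, C = x3)
  })
  # oracle: VIF_j = 1 / (1 - R2_j) by explicit regression of j on the rest
  vif_oracle <- vapply(c("A", "B", "C"), function(v) {
    r2 <- summary(lm(env[[v]] ~ ., data = env[setdiff(c("A", "B", "C"), v)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_true(all(vif_oracle < 10))
  expect_setequal(as.character(vif_screen(env)), c("A", "B", "C"))

  # orthogonal predictors all retained
  orth <- tibble::tibble(sample_id = paste0("s", 1:4),
                         A = c(1, 1, -1, -1), B = c(1, -1, 1, -1))
  expect_setequal(as.character(vif_screen(orth)), c("A", "B"))

  # a duplicated column has infinite VIF and is removed first
  dup <- env
  dup$D <- dup$A
  kept <- vif_screen(dup)
  expect_equal(length(as.character(kept)), 3)
  expect_true(xor("A" %in% kept, "D" %in% kept))
  expect_true(is.infinite(attr(kept, "removed")$vif[1]))
})

test_that("RDA matches vegan and the analytic single-axis construction", {
  withr::with_seed(11, {
    y <- matrix(rnorm(20 * 6), nrow = 20,
                dimnames = list(paste0("s", 1:20), paste0("t", 1:6)))
    env <- tibble::tibble(
      sample_id = paste0("s", 1:20),
      A = rnorm(20), B = rnorm(20)
    )
  })
  fit <- rda_fit(y, env)
  vfit <- vegan::rda(y ~ A + B, data = as.data.frame(env[, c("A", "B")]))
  vadj <- vegan::RsquareAdj(vfit)
  expect_equal(fit$r_squared, vadj$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, vadj$adj.r.squared, tolerance = 1e-10)
  expect_equal(
    unname(fit$eigenvalues),
    unname(vfit$CCA$eig),
    tolerance = 1e-10
  )
  expect_lte(fit$adj_r_squared, fit$r_squared)

  # a predictor equal to the first principal-axis score captures exactly
  # that axis's share of total variance
  yc <- scale(y, center = TRUE, scale = FALSE)
  pc <- prcomp(yc)
  env1 <- tibble::tibble(sample_id = paste0("s", 1:20), PC = pc$x[, 1])
  fit1 <- rda_fit(y, env1)
  expect_equal(
    fit1$r_squared,
    pc$sdev[1]^2 / sum(pc$sdev^2),
    tolerance = 1e-10
  )

  # rank-deficient designs are refused with the dependency named
  env_bad <- env
  env_bad$C <- env$A
  expect_error(rda_fit(y, env_bad), "rank-deficient")

  # pure-noise predictors: adjusted R2 centers on zero
  withr::with_seed(12, {
    adjs <- vapply(1:20, function(i) {
      yy <- matrix(rnorm(60 * 5), nrow = 60)
      rownames(yy) <- paste0("s", 1:60)
      ee <- tibble::tibble(sample_id = rownames(yy),
                           A = rnorm(60), B = rnorm(60))
      rda_fit(yy, ee)$adj_r_squared
    }, numeric(1))
  })
  expect_lt(abs(mean(adjs)), 0.05)
})

test_that("forward selection mirrors ordiR2step and obeys both stopping rules", {
  withr::with_seed(21, {
    n <- 30
    driver <- rnorm(n)
    cof <- rnorm(n) # weaker secondary driver so the full model has real scope
    y <- cbind(
      outer(driver, c(1, -0.5, 0.8)) + outer(cof, c(0.3, 0.4, -0.3)) +
        matrix(rnorm(n * 3, 0, 0.6), n),
      matrix(rnorm(n * 3), n)
    )
    rownames(y) <- paste0("s", 1:n)
    env <- tibble::tibble(
      sample_id = rownames(y),
      D = driver, N1 = cof, N2 = rnorm(n)
    )
  })
  fs <- forward_select(y, env, n_perm = 199, seed = 3)
  expect_gte(nrow(fs$selection), 1)
  expect_equal(fs$selection$variable[1], "D")
  expect_true(all(fs$selection$p_value <= 0.05))
  expect_true(all(fs$selection$adj_r2 <= fs$full_adj_r2 + 1e-12))
  expect_identical(
    fs$selection,
    forward_select(y, env, n_perm = 199, seed = 3)$selection
  )

  # vegan's ordiR2step admits the same leading variable on the same data
  # (rda must be visible unqualified for ordiR2step's internal update())
  rda <- vegan::rda
  df <- as.data.frame(env[, c("D", "N1", "N2")])
  m0 <- rda(y ~ 1, data = df)
  m1 <- rda(y ~ ., data = df)
  step <- withr::with_seed(3, suppressMessages(vegan::ordiR2step(
    m0, scope = stats::formula(m1),
    permutations = permute::how(nperm = 199), trace = FALSE
  )))
  vsel <- attr(stats::terms(step), "term.labels")
  expect_equal(vsel[1], "D")
  expect_equal(fs$selection$variable, vsel)

  # selection order is invariant to candidate column permutation
  fs_perm <- forward_select(y, env[, c("sample_id", "N2", "D", "N1")],
                            n_perm = 199, seed = 3)
  expect_equal(fs_perm$selection$variable, fs$selection$variable)

  # all-noise candidates: empty (or near-empty) selection is a valid result
  withr::with_seed(22, {
    y0 <- matrix(rnorm(30 * 4), nrow = 30)
    rownames(y0) <- paste0("s", 1:30)
    e0 <- tibble::tibble(sample_id = rownames(y0), A = rnorm(30), B = rnorm(30))
  })
  fs0 <- forward_select(y0, e0, n_perm = 199, seed = 4)
  expect_lte(nrow(fs0$selection), 1)
})

test_that("taxon-environment Spearman hits the monotone boundaries and flags constants", {
  env <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    up = c(1, 2, 3, 4, 5, 6), down = c(9, 7, 5, 4, 2, 1), flat = rnorm(6)
  )
  taxon <- c(0.1, 0.2, 0.25, 0.4, 0.55, 0.9) # monotone in `up`
  out <- taxon_env_spearman(taxon, env)
  expect_equal(out$rho[out$variable == "up"], 1)
  expect_equal(out$p_value[out$variable == "up"], 0)
  expect_equal(out$rho[out$variable == "down"], -1)
  const <- taxon_env_spearman(rep(0.5, 6), env)
  expect_true(all(const$undefined))
  expect_error(taxon_env_spearman(taxon[1:4], env[1:4, ]), "at least 5")
})
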