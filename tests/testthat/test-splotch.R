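test_that("size factors divide spot totals by their median", {
  counts <- tibble::tibble(section_id = "s1",
                           barcode = c("b1", "b1", "b2", "b3"),
                           taxon = c("g1", "g2", "g1", "g1"),
                           count = c(60L, 40L, 200L, 300L))
  sf <- compute_size_factors(counts)
  expect_equal(sf$s[order(sf$total)], c(0.5, 1.0, 1.5))
  # identical totals: all 1; single spot: 1
  sf1 <- compute_size_factors(tibble::tibble(section_id = "s", barcode = "b",
                                             taxon = "g", count = 7L))
  expect_equal(sf1$s, 1)
  same <- tibble::tibble(section_id = "s", barcode = c("a", "b"),
                         taxon = "g", count = c(5L, 5L))
  expect_true(all(compute_size_factors(same)$s == 1))
  withzero <- dplyr::bind_rows(counts,
                               tibble::tibble(section_id = "s1", barcode = "b4",
                                              taxon = "g1", count = 0L))
  expect_warning(compute_size_factors(withzero), "all-zero")
})

test_that("rook adjacency counts four nearest neighbours", {
  two <- build_adjacency(c(1, 2), c(1, 1))
  expect_equal(as.matrix(two$W), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(two$K, c(1L, 1L))
  g <- expand.grid(x = 1:3, y = 1:3)
  adj <- build_adjacency(g$x, g$y)
  interior <- which(g$x == 2 & g$y == 2)
  corner <- which(g$x == 1 & g$y == 1)
  expect_equal(adj$K[interior], 4L)
  expect_equal(adj$K[corner], 2L)
  # isolated spot allowed with zero neighbours
  iso <- build_adjacency(c(1, 10), c(1, 10))
  expect_equal(iso$K, c(0L, 0L))
})

test_that("zero-inflated Poisson log-pmf matches its closed form and normalizes", {
  expect_equal(zip_logpmf(0, 1, 0), -1)
  expect_equal(zip_logpmf(0, 2, 0.5), log(0.5 + 0.5 * exp(-2)))
  expect_equal(zip_logpmf(3, 2, 1), -Inf)
  expect_error(zip_logpmf(-1, 2, 0.5), "nonnegative")
  # normalization over the support for a grid of rates and dropout probs
  for (rate in c(0.5, 3, 10)) {
    for (theta in c(0, 0.3, 0.9)) {
      total <- sum(exp(zip_logpmf(0:1000, rate, theta)))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
})

test_that("CAR precision is symmetric positive definite on connected grids", {
  Q <- car_precision(c(1, 1), matrix(c(0, 1, 1, 0), 2), alpha = 0.5, tau = 1)
  expect_equal(as.matrix(Q), matrix(c(1, -0.5, -0.5, 1), 2),
               ignore_attr = TRUE)
  expect_equal(det(as.matrix(Q)), 0.75)
  # alpha -> 0 approaches independent spots with precision tau K
  g <- expand.grid(x = 1:5, y = 1:5)
  adj <- build_adjacency(g$x, g$y)
  Q0 <- car_precision(adj$K, adj$W, alpha = 1e-9, tau = 2)
  expect_equal(as.matrix(Q0), diag(2 * adj$K), tolerance = 1e-6,
               ignore_attr = TRUE)
  for (alpha in c(0.05, 0.5, 0.95, 0.999)) {
    ev <- eigen(as.matrix(car_precision(adj$K, adj$W, alpha, 1.3)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(car_precision(c(1, 1), matrix(c(0, 1, 0, 0), 2), 0.5, 1),
               "symmetric")
})

test_that("fits are bitwise reproducible and recover a dropout-free gene", {
  tis <- small_tissue(taxa = "g1", theta = 0, sigma = 0.1, seed = 31,
                      beta_mean = 1.5, beta_sd = 0.5)
  inp <- splotch_input_true_s(tis)
  fit1 <- fit_splotch(inp, "g1", chains = 2, iter = 80, warmup = 40, seed = 3)
  fit2 <- fit_splotch(inp, "g1", chains = 2, iter = 80, warmup = 40, seed = 3)
  expect_identical(fit1$draws, fit2$draws)
  # no zero inflation in truth and few observed zeros: theta posterior small
  fit <- fit_splotch(inp, "g1", seed = 4)
  theta_draws <- stats::plogis(as.numeric(
    fit$draws[, , match("logit_theta", fit$par_names)]))
  expect_lt(mean(theta_draws), 0.1)
  expect_s3_class(glance(fit), "tbl_df")
  expect_true(all(is.finite(tidy(fit)$estimate)))
})

test_that("with spatial field and noise suppressed the fit matches stratified means", {
  # Poisson-GLM limit: psi, eps ~ 0 and theta = 0, one condition
  lay <- default_layout()
  secs <- tibble::tibble(section_id = "s1", condition = "SPF", animal_id = "m1")
  ann <- block_annotations(lay, secs, x_range = c(6, 30), y_range = c(10, 30))
  expect_gte(nrow(ann), 500)
  mrois <- c("E", "MI", "PP", "BASE")
  beta <- tidyr::expand_grid(taxon = "gX", condition = "SPF", animal = "m1",
                             mroi = mrois)
  beta$beta <- c(1.6, 0.7, 2.2, 1.2)
  pars <- spatial_params(beta, alpha = 0.5, tau = 1e6, sigma = 1e-4, theta = 0)
  tis <- make_spatial_dataset(lay, ann, pars, seed = 8)
  sfx <- dplyr::distinct(tis$latents[, c("section_id", "barcode", "s")])
  inp <- splotch_input(tis$counts, tis$annotations, lay, size_factors = sfx)
  expect_false(inp$two_level)
  fit <- fit_splotch(inp, "gX", seed = 9)
  td <- tidy(fit, pars = "^beta1\\[")
  td$mroi <- sub("^.*,(.*)\\]$", "\\1", td$term)
  joined <- dplyr::inner_join(tis$latents, tis$counts,
                              by = c("taxon", "section_id", "barcode"))
  strat <- tapply(joined$count / joined$s, joined$mroi, mean)
  for (i in seq_len(nrow(td))) {
    expect_lt(abs(exp(td$estimate[i]) - strat[[td$mroi[i]]]) /
                strat[[td$mroi[i]]], 0.05)
  }
})

test_that("Savage-Dickey Bayes factors match closed-form normal densities", {
  # posterior draws moment-matched to N(1, 0.5^2); level-1 prior N(0, 4) each
  set.seed(1)
  d <- rnorm(4000)
  d <- (d - mean(d)) / sd(d) * 0.5 + 1
  res <- bf_savage_dickey(d, prior_sd = sqrt(8))
  p_prior <- 1 / sqrt(16 * pi)            # density of N(0, 8) at 0
  p_post <- exp(-2) / (0.5 * sqrt(2 * pi))  # density of N(1, 0.25) at 0
  expect_equal(p_prior, 0.14104739589, tolerance = 1e-10)
  expect_equal(p_post, 0.10798193303, tolerance = 1e-10)
  expect_equal(res$bf, p_prior / p_post, tolerance = 1e-6)
  expect_equal(res$bf, 1.3062129, tolerance = 1e-6)
  expect_equal(res$log10_bf, log10(p_prior / p_post), tolerance = 1e-6)
  expect_equal(res$direction, 1)
  # posterior equal to prior: BF = 1 (Savage-Dickey identity)
  dp <- rnorm(4000)
  dp <- (dp - mean(dp)) / sd(dp) * sqrt(8)
  expect_equal(bf_savage_dickey(dp, sqrt(8))$bf, 1, tolerance = 1e-9)
  expect_lt(abs(bf_savage_dickey(dp, sqrt(8), method = "kde")$bf - 1), 0.15)
  # zero posterior spread: infinite BF, flagged
  resinf <- bf_savage_dickey(rep(2, 100), sqrt(8))
  expect_true(is.infinite(resinf$bf))
  expect_true(resinf$infinite)
})

test_that("differential-expression calls require positive shift and BF above cutoff", {
  bfres <- dplyr::bind_rows(
    bf_savage_dickey(rnorm(500, -3, 0.1), sqrt(8)),   # strong negative shift
    bf_savage_dickey(rnorm(500, 3, 0.1), sqrt(8)))    # strong positive shift
  bfres$log10_bf[1] <- 4                              # large BF, wrong sign
  de <- call_de(bfres)
  expect_false(de$de[1])
  expect_true(de$de[2])
  # the threshold is strict
  exact <- tibble::tibble(delta_mean = 1, log10_bf = 0.5)
  expect_false(call_de(exact)$de)
})

test_that("detection rule combines the GF ceiling with the 2% share floor", {
  spf <- tibble::tibble(taxon = rep("t1", 2), mroi = c("E", "MI"),
                        wmean = c(5, 1))
  gf <- tibble::tibble(taxon = rep("t1", 2), mroi = c("E", "MI"),
                       wmean = c(2, 2))
  counts <- tibble::tibble(taxon = rep("t1", 2), mroi = c("E", "MI"),
                           count = c(10L, 90L))
  det <- detect_taxa(spf, gf, counts)
  expect_true(det$detected[det$mroi == "E"])     # 5 > 2 and share 10%
  expect_false(det$detected[det$mroi == "MI"])   # 1 < 2
  # share below 2% blocks detection even with a strong mean
  counts2 <- tibble::tibble(taxon = rep("t1", 2), mroi = c("E", "MI"),
                            count = c(1L, 99L))
  det2 <- detect_taxa(spf, gf, counts2)
  expect_false(det2$detected[det2$mroi == "E"])
  # a taxon absent from GF gets a ceiling of zero
  det3 <- detect_taxa(spf, gf[0, ], counts)
  expect_true(det3$detected[det3$mroi == "E"])
})

test_that("fit objects expose region-weighted means for the detection rule", {
  tis <- small_tissue(taxa = "g1", seed = 13)
  inp <- splotch_input_true_s(tis)
  fit <- fit_splotch(inp, "g1", chains = 2, iter = 80, warmup = 40, seed = 5)
  wm <- region_weighted_means(fit)
  expect_setequal(wm$mroi, c("E", "MI", "PP", "BASE"))
  expect_true(all(wm$wmean > 0))
  wu <- region_weighted_means(fit, weights = "uniform")
  expect_equal(nrow(wu), nrow(wm))
})
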