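test_that("taxonomy generator builds balanced and uneven trees deterministically", {
  cfg <- fixture_config(n_genera = 3, species_per_genus = 2)
  tree <- make_taxonomy(cfg)
  expect_equal(sum(tree$rank == "species"), 6L)
  expect_equal(sum(tree$rank == "genus"), 3L)
  expect_identical(make_taxonomy(cfg), make_taxonomy(cfg))
  # the community shape of a conventional SPF mouse gut reference:
  # 65 species spread unevenly over 39 genera
  spf <- make_taxonomy(fixture_config(n_genera = 39, n_species = 65))
  expect_equal(sum(spf$rank == "species"), 65L)
  expect_equal(sum(spf$rank == "genus"), 39L)
  # genus lookup and LCA behave on the small tree
  sp <- tree$taxon_id[tree$rank == "species"]
  expect_equal(tax_rank(tree, genus_of(tree, sp[1])), "genus")
  expect_equal(tax_lca(tree, sp[1:2]), genus_of(tree, sp[1]))
})

test_that("reference generator embeds a conserved probe site and genus divergence", {
  cfg <- fixture_config(n_genera = 3, species_per_genus = 2, seed = 11)
  tree <- make_taxonomy(cfg)
  refs <- make_references(tree, cfg)
  rec <- refs$records
  expect_equal(nrow(rec), 6L)
  # the exact probe expansion sits at the recorded capture site in every record
  for (i in seq_len(nrow(rec))) {
    expect_equal(substr(rec$sequence[i], rec$capture_start[i], rec$capture_end[i]),
                 refs$probe_expansion)
  }
  expect_true(refs$probe_expansion %in% expand_degenerate(shm_probe()))
  # zero substitution rate collapses all species onto the template
  cfg0 <- fixture_config(n_genera = 3, species_per_genus = 2,
                         branch_substitution_rate = 0)
  rec0 <- make_references(make_taxonomy(cfg0), cfg0)$records
  expect_equal(length(unique(rec0$sequence)), 1L)
  # within-genus identity exceeds between-genus identity
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  within <- c(ident(rec$sequence[1], rec$sequence[2]),
              ident(rec$sequence[3], rec$sequence[4]))
  between <- c(ident(rec$sequence[1], rec$sequence[3]),
               ident(rec$sequence[1], rec$sequence[5]),
               ident(rec$sequence[3], rec$sequence[5]))
  expect_gt(min(within), max(between))
  # explicit variable region overlapping the probe site is rejected
  cfg_bad <- fixture_config(variable_region = c(990, 1010))
  expect_error(make_references(make_taxonomy(cfg_bad), cfg_bad), "overlaps")
})

test_that("spatial count generator honors the model equations", {
  tis <- small_tissue()
  # stored latents satisfy lambda = exp(B + psi + eps) exactly
  expect_lt(max(abs(tis$latents$lambda -
                      exp(tis$latents$B + tis$latents$psi + tis$latents$eps))),
            1e-12)
  # same seed, same matrix
  tis2 <- small_tissue()
  expect_identical(tis$counts, tis2$counts)
  # theta = 1 forces all counts of that taxon to zero
  lay <- default_layout()
  secs <- tibble::tibble(section_id = "s1", condition = "SPF", animal_id = "m1")
  ann <- block_annotations(lay, secs, x_range = c(10, 14), y_range = c(10, 14))
  beta <- tidyr::expand_grid(taxon = "gX", condition = "SPF", animal = "m1",
                             mroi = c("E", "MI", "PP", "BASE"))
  beta$beta <- 2
  pars <- spatial_params(beta, theta = c(gX = 1))
  tz <- make_spatial_dataset(lay, ann, pars, seed = 1)
  expect_true(all(tz$counts$count == 0))
})

test_that("with the spatial field and noise suppressed the mean count matches the rate", {
  # s * lambda = 2 with psi and eps pinned near zero: law of large numbers
  lay <- default_layout()
  secs <- tibble::tibble(section_id = sprintf("s%02d", 1:10),
                         condition = "SPF", animal_id = "m1")
  ann <- block_annotations(lay, secs, x_range = c(2, 34), y_range = c(2, 32))
  beta <- tidyr::expand_grid(taxon = "gX", condition = "SPF", animal = "m1",
                             mroi = c("E", "MI", "PP", "BASE"))
  beta$beta <- log(2)
  pars <- spatial_params(beta, alpha = 0.5, tau = 1e8, sigma = 0, theta = 0)
  tis <- make_spatial_dataset(lay, ann, pars, seed = 3)
  n <- nrow(tis$counts)
  expect_gt(n, 9000)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(tis$counts$count) - 2), 3 * se)
})

test_that("cell-type signatures have block-structured markers", {
  sig <- make_celltype_signatures(n_celltypes = 30, n_genes = 300, seed = 4)
  expect_equal(ncol(sig$means), 30L)
  # each marker gene peaks in its own cell type
  peak <- colnames(sig$means)[apply(sig$means[sig$markers$gene, ], 1, which.max)]
  expect_equal(peak, sig$markers$celltype)
  sig2 <- make_celltype_signatures(n_celltypes = 30, n_genes = 300, seed = 4)
  expect_identical(sig, sig2)
})
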