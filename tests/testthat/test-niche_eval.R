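test_that("gene standardization uses the sample-sd convention and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  expect_warning(z <- standardize_genes(m), "zero-variance")
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  expect_equal(rownames(z), "g1")
  expect_equal(standardize_genes(z), z)
  expect_error(standardize_genes(matrix(1, 2, 3)), "zero variance")
})

test_that("cell-spot similarity is a bounded correlation over common genes", {
  set.seed(1)
  genes <- paste0("g", 1:1000)
  spot <- matrix(rnorm(1000 * 4), 1000, 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  # a cell matrix with the same gene-wise distribution as the spots: matched
  # columns standardize to the same vectors, so identical profiles give r = 1
  # and sign-flipped profiles r = -1
  P <- cell_spot_similarity(spot, spot)
  expect_true(all(P >= -1 & P <= 1))
  expect_equal(unname(diag(P)), rep(1, 4), tolerance = 1e-12)
  Pneg <- cell_spot_similarity(-spot, spot)
  expect_equal(unname(diag(Pneg)), rep(-1, 4), tolerance = 1e-12)
  # independent random vectors: |r| concentrates near 0 at 1,000 genes
  rand <- matrix(rnorm(1000 * 3), 1000, 3,
                 dimnames = list(genes, paste0("c", 1:3)))
  Pr <- cell_spot_similarity(rand, spot)
  expect_lt(max(abs(Pr)), 0.15)
  expect_error(cell_spot_similarity(spot[1:2, , drop = FALSE], spot),
               "common genes")
})

test_that("module clustering recovers planted orthogonal blocks", {
  set.seed(2)
  spots <- 40
  pattern1 <- c(rep(3, 20), rep(-3, 20))
  pattern2 <- c(rep(-3, 20), rep(3, 20))
  m <- rbind(
    matrix(rep(pattern1, 10), 10, spots, byrow = TRUE),
    matrix(rep(pattern2, 10), 10, spots, byrow = TRUE)) +
    matrix(rnorm(20 * spots, 0, 0.2), 20, spots)
  rownames(m) <- paste0("g", 1:20)
  mods <- cluster_modules(m, n_modules = 2)
  expect_equal(length(unique(mods$module[1:10])), 1L)
  expect_equal(length(unique(mods$module[11:20])), 1L)
  expect_false(mods$module[1] == mods$module[11])
  # as many modules as genes: singletons
  singl <- cluster_modules(m, n_modules = 20)
  expect_equal(sort(unique(singl$module)), 1:20)
  expect_error(cluster_modules(m, n_modules = 21), "exceeds")
  # gene input order does not change the partition
  perm <- sample(20)
  mods_p <- cluster_modules(m[perm, ], n_modules = 2)
  agree <- table(mods$module[perm], mods_p$module)
  expect_equal(sum(agree > 0), 2L)
})

test_that("cluster-mean scaling puts each gene's peak at 1", {
  cells <- matrix(c(2, 2, 4, 4, 8, 8,
                    1, 1, 1, 1, 1, 1), 2, 6, byrow = TRUE,
                  dimnames = list(c("graded", "uniform"), NULL))
  labels <- rep(c("t1", "t2", "t3"), each = 2)
  sc <- scale_celltype_means(cells, labels, expression_floor = 0)
  expect_equal(unname(sc["graded", ]), c(0.25, 0.5, 1.0))
  expect_equal(unname(sc["uniform", ]), c(1, 1, 1))
  # marker genes from the signature generator peak in their own type
  sig <- make_celltype_signatures(n_celltypes = 5, n_genes = 50, seed = 3)
  sc2 <- scale_celltype_means(sig$cells, sig$cell_type, expression_floor = 0)
  mk <- sig$markers[sig$markers$gene %in% rownames(sc2), ]
  peak <- colnames(sc2)[apply(sc2[mk$gene, ], 1, which.max)]
  expect_equal(peak, mk$celltype)
})

test_that("submodule partitioning cuts the cosine tree at 0.4 of its height", {
  # two cell-type-disjoint marker groups
  m <- rbind(matrix(rep(c(1, 1, 0, 0, 0, 0), 6), 6, 6, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 0, 1, 1), 6), 6, 6, byrow = TRUE))
  m <- m + matrix(abs(rnorm(72, 0, 0.01)), 12, 6)
  rownames(m) <- paste0("g", 1:12)
  colnames(m) <- paste0("t", 1:6)
  sub <- partition_submodules(m)
  expect_equal(length(unique(sub$submodule)), 2L)
  expect_equal(length(unique(sub$submodule[1:6])), 1L)
  # identical rows collapse to one submodule; cutting at the root too
  ident <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(unique(partition_submodules(ident)$submodule), 1L)
  expect_equal(length(unique(partition_submodules(m, cutoff_frac = 1)$submodule)),
               1L)
  # single-gene module: one singleton
  one <- partition_submodules(m[1, , drop = FALSE])
  expect_equal(one$submodule, 1L)
})

test_that("cell-type enrichment flags the marker type with minimal FDR", {
  sig <- make_celltype_signatures(n_celltypes = 6, n_genes = 120,
                                  marker_fold = 12, seed = 4)
  sc <- scale_celltype_means(sig$cells, sig$cell_type, expression_floor = 0)
  markers_t3 <- sig$markers$gene[sig$markers$celltype == "celltype_03"]
  res <- enrich_celltypes(sc, markers_t3)
  expect_true(all(res$tested))
  # the marker type reaches the minimal FDR with a positive shift (other
  # types can tie on FDR with the opposite direction)
  r3 <- res[res$celltype == "celltype_03", ]
  expect_equal(r3$fdr, min(res$fdr))
  expect_lt(r3$fdr, 0.05)
  expect_equal(res$celltype[which.max(res$median_diff)], "celltype_03")
  # submodules below the size floor are reported untested
  tiny <- enrich_celltypes(sc, markers_t3[1:3])
  expect_false(any(tiny$tested))
  # BH correction matches the brute-force step-up on random p-values
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bf_bh(p))
  }
  expect_equal(bf_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("gene-set enrichment equals the hypergeometric upper tail", {
  universe <- paste0("g", 1:20)
  sub <- universe[1:10]
  sets <- list(hit = universe[1:10], miss = universe[11:20])
  res <- enrich_genesets(sub, sets, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)
  # agreement with Fisher's one-tailed exact test on random tables
  set.seed(6)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- paste0("x", seq_len(N))
    s1 <- sample(uni, sample(2:N, 1))
    s2 <- sample(uni, sample(2:N, 1))
    r <- enrich_genesets(s1, list(s = s2), uni)
    q <- length(intersect(s1, s2))
    tab <- matrix(c(q, length(setdiff(s1, s2)),
                    length(setdiff(s2, s1)),
                    N - length(union(s1, s2))), 2)
    expect_equal(r$p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # GMT round trip
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), gmt)
  gs <- read_gmt(gmt)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
})

test_that("TP10K normalization scales every cell to 10,000", {
  counts <- matrix(c(1, 1, 2, 0, 0, 0, 5, 5, 10), 3, 3,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  norm <- tp10k_normalize(counts)
  expect_equal(ncol(norm), 2L)                 # zero-total cell dropped
  expect_equal(unname(norm[, 1]), c(2500, 2500, 5000))
  expect_true(all(abs(colSums(norm) - 1e4) < 1e-9))
  expect_equal(tp10k_normalize(norm), norm)    # already normalized: unchanged
})

test_that("variable-gene selection recovers planted high-dispersion genes", {
  set.seed(7)
  n_genes <- 200; n_cells <- 80
  mu <- exp(rnorm(n_genes, 2, 1))
  m <- matrix(rpois(n_genes * n_cells, rep(mu, n_cells)), n_genes, n_cells)
  hot <- sample(n_genes, 10)
  # inflate dispersion of the planted genes
  m[hot, ] <- m[hot, ] * matrix(exp(rnorm(10 * n_cells, 0, 1)), 10, n_cells)
  rownames(m) <- paste0("g", seq_len(n_genes))
  sel <- select_variable_genes(m, n_bins = 10, n_top = 40)
  expect_equal(length(sel), 40L)
  expect_gte(sum(rownames(m)[hot] %in% sel), 8)
  expect_identical(sel, select_variable_genes(m, n_bins = 10, n_top = 40))
  expect_error(select_variable_genes(m, n_top = 1000), "exceeds")
})

test_that("nucleus filtering applies its thresholds in order", {
  set.seed(8)
  n_genes <- 1200
  counts <- matrix(rpois(n_genes * 5, 2), n_genes, 5,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("c", 1:5)))
  counts[, 2] <- 0
  counts[sample(n_genes, 300), 2] <- 1          # detects 300 genes < 800
  counts["g1", ] <- c(50, 0, 0, 0, 0)
  detected <- colSums(counts > 0)
  flagged <- paste0("g", 2:40)
  filt <- filter_nuclei(counts, flagged, min_genes = 800,
                        min_cells_per_gene = 2, max_flag_frac = 0.3)
  expect_false("c2" %in% colnames(filt))        # <= 800 genes: removed
  expect_true(all(colSums(filt > 0) >= 0))
  # hand tally on a toy: cell with exactly min_genes detected is removed
  toy <- matrix(1, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  toy[3, 2] <- 0
  out <- filter_nuclei(toy, character(0), min_genes = 2,
                       min_cells_per_gene = 1, max_flag_frac = 1)
  expect_equal(colnames(out), "a")              # "b" detects exactly 2: strict
  # a gene detected in too few cells is dropped
  out2 <- filter_nuclei(toy, character(0), min_genes = 0,
                        min_cells_per_gene = 2, max_flag_frac = 1)
  expect_false("g3" %in% rownames(out2))
})

test_that("Bray-Curtis dissimilarity follows its closed form and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(6, 1, 0), c(10, 0, 7)), 0.5)
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "nonnegative")
  set.seed(9)
  for (i in 1:20) {
    u <- runif(5); v <- runif(5)
    expect_gte(bray_curtis(u, v), 0)
    expect_lte(bray_curtis(u, v), 1)
    expect_equal(bray_curtis(u, v), bray_curtis(v, u))
  }
})

test_that("classification reports pool reads as bulk-like samples", {
  perfect <- classification_report(c("A", "B"), c("A", "B"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  r <- classification_report(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$fpr, 0.25)
  per <- attr(r, "per_genus")
  expect_equal(per$recall[per$genus == "A"], 0.5)
  # nothing classified: zero accuracy and zero FPR by convention
  none <- classification_report(c("A", "B"), c(NA, NA))
  expect_equal(none$accuracy, 0)
  expect_equal(none$fpr, 0)
  expect_error(classification_report(character(0), character(0)), "empty")
})

test_that("spot-group abundance agreement behaves at its extremes", {
  refs <- small_refs(n_genera = 4)
  rs <- simulate_readset(refs, n_reads = 5000, min_per_genus = 0, seed = 19)
  reads <- rs$reads
  expect_warning(
    perfect <- spotwise_abundance_agreement(reads, reads$genus,
                                            group_size = 2000, seed = 1),
    "single group")
  expect_equal(perfect, 1)
  expect_warning(
    bc <- spotwise_abundance_agreement(reads, reads$genus, group_size = 2000,
                                       metric = "bray_curtis", seed = 1),
    "single group")
  expect_equal(bc, 0)
  shuffled <- spotwise_abundance_agreement(reads, sample(reads$genus),
                                           group_size = 100, seed = 1)
  expect_lt(abs(shuffled), 0.5)
  a1 <- spotwise_abundance_agreement(reads, reads$genus, group_size = 100,
                                     seed = 2)
  a2 <- spotwise_abundance_agreement(reads, reads$genus, group_size = 100,
                                     seed = 2)
  expect_identical(a1, a2)
})

test_that("region-matched resampling correlation is rank-invariant and seeded", {
  set.seed(10)
  regions <- c("E", "MI", "PP")
  a <- tidyr::expand_grid(sample = c("s1", "s2"), region = regions,
                          rep = 1:8)
  a$value <- rnorm(nrow(a), match(a$region, regions) * 2, 0.1)
  b <- a
  b$value <- exp(a$value)          # monotone transform
  # within one sample ranks are invariant to a monotone transform: rho = 1
  a1 <- a[a$sample == "s1", ]; b1 <- b[b$sample == "s1", ]
  expect_equal(region_resampling_correlation(a1, b1, n_reps = 20, seed = 3), 1,
               tolerance = 1e-9)
  # pooling min-max-scaled samples only approximately preserves global ranks
  rho <- region_resampling_correlation(a, b, n_reps = 50, seed = 3)
  expect_gt(rho, 0.85)
  b2 <- a; b2$value <- rnorm(nrow(a))
  rho0 <- region_resampling_correlation(a, b2, n_reps = 200, seed = 3)
  expect_lt(abs(rho0), 0.35)
  expect_identical(region_resampling_correlation(a, b2, n_reps = 50, seed = 4),
                   region_resampling_correlation(a, b2, n_reps = 50, seed = 4))
  expect_error(region_resampling_correlation(
    a, dplyr::mutate(b, region = "ZZ"), n_reps = 5, seed = 1), "shared")
})
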