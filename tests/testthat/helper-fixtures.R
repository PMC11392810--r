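# shared fixture builders; everything is generated in code, no stored data

small_refs <- function(n_genera = 3, species_per_genus = 2, seed = 42, ...) {
  cfg <- fixture_config(seed = seed, n_genera = n_genera,
                        species_per_genus = species_per_genus, ...)
  make_references(make_taxonomy(cfg), cfg)
}

# annotations for a square block of the default layout, one section per
# (condition, animal); MROI assigned by a diagonal-band pattern
block_annotations <- function(layout, sections, x_range = c(10, 18),
                              y_range = c(10, 18),
                              mrois = c("E", "MI", "PP", "BASE")) {
  blk <- layout[layout$x >= x_range[1] & layout$x <= x_range[2] &
                  layout$y >= y_range[1] & layout$y <= y_range[2], ]
  dplyr::bind_rows(lapply(seq_len(nrow(sections)), function(i) {
    tibble::tibble(
      barcode = blk$barcode,
      mroi = mrois[1 + (blk$x + blk$y) %% length(mrois)],
      section_id = sections$section_id[i],
      condition = sections$condition[i],
      animal_id = sections$animal_id[i])
  }))
}

# a small two-condition tissue with known parameters, shared across tests
small_tissue <- function(taxa = c("g1", "g2"), seed = 5, theta = 0.1,
                         alpha = 0.7, tau = 3, sigma = 0.2,
                         sigma_l2 = 0.3, beta_mean = 0.5, beta_sd = 1.2,
                         beta_seed = 2) {
  lay <- default_layout()
  secs <- tibble::tibble(section_id = c("s1", "s2", "s3", "s4"),
                         condition = c("SPF", "SPF", "GF", "GF"),
                         animal_id = c("m1", "m2", "m3", "m4"))
  ann <- block_annotations(lay, secs)
  mrois <- c("E", "MI", "PP", "BASE")
  btrue <- withr::with_seed(beta_seed, {
    b <- tidyr::expand_grid(taxon = taxa, condition = c("SPF", "GF"),
                            mroi = mrois)
    b$beta_l1 <- rnorm(nrow(b), beta_mean, beta_sd)
    b
  })
  beta <- tidyr::expand_grid(taxon = taxa, condition = c("SPF", "GF"),
                             animal = c("m1", "m2", "m3", "m4"), mroi = mrois)
  beta <- dplyr::inner_join(beta, btrue, by = c("taxon", "condition", "mroi"))
  beta$beta <- withr::with_seed(beta_seed + 1,
                                beta$beta_l1 + rnorm(nrow(beta), 0, sigma_l2))
  pars <- spatial_params(beta[, c("taxon", "condition", "animal", "mroi", "beta")],
                         alpha = alpha, tau = tau, sigma = sigma, theta = theta)
  tis <- make_spatial_dataset(lay, ann, pars, seed = seed)
  tis$beta_l1_true <- btrue
  tis
}

splotch_input_true_s <- function(tissue, ...) {
  sfx <- dplyr::distinct(tissue$latents[, c("section_id", "barcode", "s")])
  splotch_input(tissue$counts, tissue$annotations, tissue$layout,
                size_factors = sfx, ...)
}

# deep model trained once per test run on the 3-genus fixture, cached
.test_cache <- new.env(parent = emptyenv())

cached_trained_model <- function() {
  if (!is.null(.test_cache$model)) return(.test_cache$model)
  refs <- small_refs()
  rs <- simulate_readset(refs, n_reads = 5000,
                         model = length_model(143, 13, 150),
                         mutation_rate = 0.001, min_per_genus = 100, seed = 7)
  model <- build_deep_model(sort(unique(rs$reads$genus)), seed = 1)
  model <- train_deep(model, rs$reads$sequence, rs$reads$genus,
                      deep_train_config(max_epochs = 3, seed = 3))
  .test_cache$model <- model
  .test_cache$model_refs <- refs
  model
}

# independent brute-force helpers used as oracles --------------------------

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force connected components of UMIs at Hamming distance <= 1
bf_umi_components <- function(umis) {
  u <- unique(umis)
  n <- length(u)
  if (n == 1) return(1L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- hamming(u[i], u[j]) <= 1
  }
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  nrow(unique(adj))
}

# brute-force Benjamini-Hochberg step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# a hand-built reference set: two genera in one family plus an outgroup genus,
# with a planted capture site after the species-specific region
toy_refs <- function(seed = 13, len = 400) {
  nodes <- tibble::tibble(
    taxon_id = 1:9,
    name = c("root", "famA", "famB", "genA1", "genA2", "genB1",
             "spA1a", "spA2a", "spB1a"),
    rank = c("root", "family", "family", "genus", "genus", "genus",
             "species", "species", "species"),
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L))
  tree <- taxonomy(nodes)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  expn <- expand_degenerate(shm_probe())[1]
  mk <- function() paste(sample(bases, len, replace = TRUE), collapse = "")
  shared_A <- mk()     # shared by the two genera of famA
  recA1 <- paste0(shared_A, mk(), expn)
  recA2 <- paste0(shared_A, mk(), expn)
  recB <- paste0(mk(), mk(), expn)
  structure(list(
    records = tibble::tibble(
      species_id = c(7L, 8L, 9L),
      species = c("spA1a", "spA2a", "spB1a"),
      genus = c("genA1", "genA2", "genB1"),
      family = c("famA", "famA", "famB"),
      sequence = c(recA1, recA2, recB),
      capture_start = 2L * len + 1L,
      capture_end = 2L * len + nchar(expn)),
    taxonomy = tree), class = "reference_set")
}

# independent oracle: species containing a k-mer found by substring search on
# both strands of the raw reference strings
oracle_hit_taxa <- function(kmer, refs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  hits <- vapply(refs$records$sequence, function(s)
    grepl(kmer, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1))
  refs$records$species_id[hits]
}

# independent brute-force oracle for the full classification contract
oracle_classify <- function(sequence, refs, k = 31, confidence = 0.01) {
  tree <- refs$taxonomy
  n <- nchar(sequence)
  if (n < k) return(NA_character_)
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  total <- length(kmers)
  hit_nodes <- integer(0)
  for (km in kmers) {
    if (grepl("N", km, fixed = TRUE)) next
    sp <- oracle_hit_taxa(km, refs)
    if (length(sp)) hit_nodes <- c(hit_nodes, tax_lca(tree, sp))
  }
  if (!length(hit_nodes)) return(NA_character_)
  hits <- table(hit_nodes)
  leaves <- tree$taxon_id[tree$rank == "species"]
  path_score <- vapply(leaves, function(s) {
    anc <- tax_ancestors(tree, s)
    sum(hits[as.character(intersect(anc, as.integer(names(hits))))])
  }, numeric(1))
  best <- leaves[path_score == max(path_score)]
  node <- if (length(best) > 1) tax_lca(tree, best) else best
  clade_support <- function(nd) {
    below <- tree$taxon_id[vapply(tree$taxon_id, function(x)
      nd %in% tax_ancestors(tree, x), logical(1))]
    sum(hits[as.character(intersect(below, as.integer(names(hits))))])
  }
  parent <- setNames(tree$parent_id, tree$taxon_id)
  while (clade_support(node) / total < confidence &&
         !is.na(parent[[as.character(node)]])) {
    node <- parent[[as.character(node)]]
  }
  rk <- tax_rank(tree, node)
  if (rk == "species") return(tax_name(tree, genus_of(tree, node)))
  if (rk == "genus") return(tax_name(tree, node))
  NA_character_
}
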