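test_that("capture-site location finds planted probe matches", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  probe <- shm_probe()
  expn <- expand_degenerate(probe)
  # exact expansion planted at position 900 of a random reference
  ref <- paste(sample(bases, 1500, replace = TRUE), collapse = "")
  ref <- paste0(substr(ref, 1, 899), expn[1], substr(ref, 900 + nchar(probe), 1500))
  site <- locate_capture_site(ref)
  expect_equal(site$start, 900L)
  expect_equal(site$score, nchar(probe))
  # fully degenerate probe matches everywhere; leftmost window wins
  site_nn <- locate_capture_site(ref, probe = "NN", floor_frac = 0.5)
  expect_equal(site_nn$start, 1L)
  expect_equal(site_nn$end, 2L)
  # a 1-mismatch planted copy loses to a distant exact match (brute force on
  # a 200-nt toy: the exact match scores 28, the mismatched one at most 26)
  toy <- paste(sample(bases, 200, replace = TRUE), collapse = "")
  mism <- expn[1]
  substr(mism, 5, 5) <- setdiff(bases, substr(mism, 5, 5))[1]
  toy <- paste0(substr(toy, 1, 19), mism,
                substr(toy, 20 + nchar(probe), 150 - 1), expn[1])
  site_toy <- locate_capture_site(toy)
  expect_equal(site_toy$score, nchar(probe))
  expect_gt(site_toy$start, 100L)
  # no alignment above the floor: site absent
  junk <- paste(sample(bases, 60, replace = TRUE), collapse = "")
  expect_null(locate_capture_site(junk))
})

test_that("fragments are taken immediately upstream of the site and trimmed", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  site <- list(start = 501L, end = 528L)
  # deterministic length: always the 120 bases upstream
  f <- sample_fragment(ref, site, length_model(120, 0, 150))
  expect_equal(f$sequence, substr(ref, 381, 500))
  expect_equal(c(f$start, f$end), c(381L, 500L))
  # long draws are trimmed to 150 nt keeping the site-adjacent end
  lens <- replicate(200, nchar(sample_fragment(ref, site,
                                               length_model(400, 44, 150))$sequence))
  expect_true(all(lens == 150L))
  # Monte-Carlo mean of the raw drawn length
  draws <- replicate(10000, nchar(sample_fragment(ref, site,
                                                  length_model(120, 10, 500))$sequence))
  expect_lt(abs(mean(draws) - 120), 3 * 10 / sqrt(10000))
  expect_error(sample_fragment(ref, list(start = 1L, end = 28L),
                               length_model()), "reference start")
})

test_that("mutation and sequencing-error processes have binomial rates", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 1e6, replace = TRUE), collapse = "")
  expect_identical(mutate_sequence(s, 0), s)
  flipped <- mutate_sequence("ACGTACGT", 1)
  expect_true(all(strsplit(flipped, "")[[1]] != strsplit("ACGTACGT", "")[[1]]))
  nm <- sum(strsplit(mutate_sequence(s, 0.001), "")[[1]] != strsplit(s, "")[[1]])
  expect_lt(abs(nm - 1000), 3 * sqrt(1e6 * 0.001 * 0.999))
  s2 <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE), collapse = "")
  expect_identical(add_sequencing_error(s2, 0), s2)
  ne <- sum(strsplit(add_sequencing_error(s2, 0.01), "")[[1]] !=
              strsplit(s2, "")[[1]])
  expect_lt(abs(ne - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
})

test_that("read simulation respects abundances, minimum genus counts and geometry", {
  refs <- small_refs(n_genera = 2, species_per_genus = 1)
  ab <- setNames(c(1, 0), as.character(refs$records$species_id))
  rs <- simulate_readset(refs, n_reads = 1000, abundances = ab,
                         min_per_genus = 0, seed = 1)
  expect_true(all(rs$reads$species_id == refs$records$species_id[1]))
  # fragment intervals lie immediately upstream of the capture site
  expect_true(all(rs$reads$frag_end ==
                    refs$records$capture_start[match(rs$reads$species_id,
                                                     refs$records$species_id)] - 1L))
  # top-up guarantees min_per_genus; undersized requests error
  refs5 <- small_refs(n_genera = 5)
  rs2 <- simulate_readset(refs5, n_reads = 600, min_per_genus = 100, seed = 2)
  expect_true(all(table(rs2$reads$genus) >= 100))
  expect_error(simulate_readset(refs5, n_reads = 100, min_per_genus = 100),
               "min_per_genus")
  expect_error(simulate_readset(refs5, n_reads = 100, min_per_genus = 0,
                                abundances = setNames(rep(0.3, 10),
                                                      refs5$records$species_id)),
               "sum to 1")
})

test_that("simulated genus composition follows the requested abundances", {
  refs <- small_refs(n_genera = 4, species_per_genus = 2, seed = 9)
  probs <- c(0.4, 0.3, 0.2, 0.1)
  sp_ab <- rep(probs / 2, each = 2)
  names(sp_ab) <- as.character(refs$records$species_id)
  rs <- simulate_readset(refs, n_reads = 1e5, abundances = sp_ab,
                         min_per_genus = 0, mutation_rate = 0, seed = 3)
  obs <- table(factor(rs$reads$genus, levels = sort(unique(refs$records$genus))))
  chi <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.01)
  # determinism and R1 structure round-trip through FASTQ
  dir <- withr::local_tempdir()
  write_readset(rs, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"),
                file.path(dir, "truth.tsv"), file.path(dir, "manifest.json"))
  back <- read_fastq_pairs(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  expect_equal(back$barcode_obs[1:100], rs$reads$barcode[1:100])
  expect_equal(back$umi[1:100], rs$reads$umi[1:100])
})
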