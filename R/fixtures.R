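#' Fixture generator configuration
#'
#' Parameters for the synthetic taxonomy / 16S reference generators. The
#' defaults emulate a small gut-community reference: full-length (1,500 nt)
#' 16S-like sequences, a conserved probe capture site near the 3' end with a
#' genus-discriminative variable region immediately upstream of it, and a
#' Jukes-Cantor-style uniform substitution process along tree branches.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (balanced tree).
#' @param n_species Optional total species count; when given, species are
#'   assigned to genera as evenly as possible (some genera get one extra),
#'   overriding `species_per_genus`.
#' @param n_families Number of families; defaults to about one per three
#'   genera.
#' @param ref_length Reference sequence length in nt.
#' @param variable_region_span Width (nt) of the genus-discriminative
#'   variable region; placed immediately upstream of the probe site unless
#'   `variable_region` is given.
#' @param variable_region Optional explicit `c(start, end)` (1-based) of the
#'   variable region; must not overlap the probe site.
#' @param branch_substitution_rate Per-base substitution probability applied
#'   on every tree branch (outside the probe site).
#' @param genus_boost Multiplier on the substitution rate inside the variable
#'   region on genus branches, making genera more divergent than species
#'   within a genus.
#' @param probe_site_position 1-based start of the embedded probe capture
#'   site on every reference.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_genera = 5L, species_per_genus = 2L,
                           n_species = NULL, n_families = NULL,
                           ref_length = 1500L, variable_region_span = 300L,
                           variable_region = NULL,
                           branch_substitution_rate = 0.02, genus_boost = 5,
                           probe_site_position = 1000L) {
  stopifnot(ref_length > variable_region_span,
            branch_substitution_rate >= 0, branch_substitution_rate <= 1,
            n_genera >= 1)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 n_species = if (!is.null(n_species)) as.integer(n_species),
                 n_families = if (!is.null(n_families)) as.integer(n_families),
                 ref_length = as.integer(ref_length),
                 variable_region_span = as.integer(variable_region_span),
                 variable_region = variable_region,
                 branch_substitution_rate = branch_substitution_rate,
                 genus_boost = genus_boost,
                 probe_site_position = as.integer(probe_site_position)),
            class = "fixture_config")
}

#' Generate a balanced synthetic taxonomy
#'
#' Builds a tree root -> family -> genus -> species. With `n_species` set,
#' species counts per genus are as even as possible (the first genera receive
#' the remainder), so e.g. 65 species over 39 genera is representable.
#'
#' @param config A [fixture_config()].
#' @return A `taxonomy` object: a tibble of nodes (`taxon_id`, `name`,
#'   `rank`, `parent_id`) with lookup attributes.
#' @export
make_taxonomy <- function(config = fixture_config()) {
  ng <- config$n_genera
  nf <- if (!is.null(config$n_families)) config$n_families else max(1L, ceiling(ng / 3))
  nf <- min(nf, ng)
  if (!is.null(config$n_species)) {
    base <- config$n_species %/% ng
    extra <- config$n_species %% ng
    sp_per_genus <- rep(base, ng) + c(rep(1L, extra), rep(0L, ng - extra))
    if (any(sp_per_genus < 1L)) stop("n_species must be >= n_genera")
  } else {
    sp_per_genus <- rep(config$species_per_genus, ng)
  }
  nodes <- tibble(taxon_id = 1L, name = "root", rank = "root", parent_id = NA_integer_)
  fam_ids <- 1L + seq_len(nf)
  nodes <- dplyr::bind_rows(nodes, tibble(
    taxon_id = fam_ids, name = sprintf("family_%02d", seq_len(nf)),
    rank = "family", parent_id = 1L))
  genus_fam <- fam_ids[((seq_len(ng) - 1L) %% nf) + 1L]
  gen_ids <- max(fam_ids) + seq_len(ng)
  nodes <- dplyr::bind_rows(nodes, tibble(
    taxon_id = gen_ids, name = sprintf("genus_%02d", seq_len(ng)),
    rank = "genus", parent_id = genus_fam))
  ns <- sum(sp_per_genus)
  sp_ids <- max(gen_ids) + seq_len(ns)
  nodes <- dplyr::bind_rows(nodes, tibble(
    taxon_id = sp_ids, name = sprintf("species_%03d", seq_len(ns)),
    rank = "species", parent_id = rep(gen_ids, sp_per_genus)))
  taxonomy(nodes)
}

#' Construct a taxonomy from a node table
#'
#' @param nodes Tibble with columns `taxon_id`, `name`, `rank`
#'   (root/phylum/class/order/family/genus/species), `parent_id` (NA for the
#'   single root).
#' @return A validated `taxonomy` object.
#' @export
taxonomy <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("taxon_id", "name", "rank", "parent_id") %in% names(nodes)))
  ranks <- c("root", "phylum", "class", "order", "family", "genus", "species")
  if (!all(nodes$rank %in% ranks)) stop("unknown rank in taxonomy")
  if (sum(is.na(nodes$parent_id)) != 1L) stop("taxonomy must have a single root")
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon ids")
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  rank <- setNames(nodes$rank, nodes$taxon_id)
  rank_ord <- setNames(seq_along(ranks), ranks)
  # ancestors (root first, self last) per node; also validates rank ordering
  anc <- vector("list", nrow(nodes))
  names(anc) <- as.character(nodes$taxon_id)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$taxon_id[i]
    path <- id
    p <- parent[[as.character(id)]]
    while (!is.na(p)) {
      path <- c(p, path)
      p <- parent[[as.character(p)]]
    }
    if (any(diff(rank_ord[rank[as.character(path)]]) <= 0)) {
      stop("ranks not strictly ordered on path to taxon ", id)
    }
    anc[[as.character(id)]] <- path
  }
  sp <- nodes$taxon_id[nodes$rank == "species"]
  g_of <- vapply(sp, function(id) {
    path <- anc[[as.character(id)]]
    g <- path[rank[as.character(path)] == "genus"]
    if (!length(g)) stop("species ", id, " has no genus ancestor")
    g
  }, integer(1))
  structure(nodes,
            ancestors = anc,
            genus_of = setNames(g_of, sp),
            class = c("taxonomy", class(nodes)))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", sum(x$rank == "species"), " species, ",
      sum(x$rank == "genus"), " genera, ", sum(x$rank == "family"),
      " families\n", sep = "")
  invisible(x)
}

#' Taxonomy accessors
#'
#' `tax_ancestors()` returns the root-to-node path of taxon ids;
#' `tax_lca()` the lowest common ancestor of a set of taxa; `genus_of()` the
#' genus ancestor of each species; `tax_rank()` the rank of given ids.
#'
#' @param tree A [taxonomy()].
#' @param id,ids Taxon id(s).
#' @return Integer ids (or character ranks for `tax_rank()`).
#' @export
tax_ancestors <- function(tree, id) attr(tree, "ancestors")[[as.character(id)]]

#' @rdname tax_ancestors
#' @export
tax_lca <- function(tree, ids) {
  ids <- unique(unname(ids))
  if (length(ids) == 1L) return(ids)
  anc <- attr(tree, "ancestors")
  paths <- anc[as.character(ids)]
  n <- min(lengths(paths))
  common <- 0L
  for (d in seq_len(n)) {
    lev <- vapply(paths, `[`, integer(1), d)
    if (all(lev == lev[1])) common <- unname(lev[1]) else break
  }
  common
}

#' @rdname tax_ancestors
#' @export
genus_of <- function(tree, ids) {
  unname(attr(tree, "genus_of")[as.character(ids)])
}

#' @rdname tax_ancestors
#' @export
tax_rank <- function(tree, ids) {
  rk <- setNames(tree$rank, tree$taxon_id)
  unname(rk[as.character(ids)])
}

#' @rdname tax_ancestors
#' @export
tax_name <- function(tree, ids) {
  nm <- setNames(tree$name, tree$taxon_id)
  unname(nm[as.character(ids)])
}

# internal: uniform substitution of a fraction `rate` of positions, restricted
# to `positions` (integer vector) of the sequence
.substitute_positions <- function(seq, rate, positions) {
  if (rate <= 0 || !length(positions)) return(seq)
  hit <- positions[runif(length(positions)) < rate]
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in hit) {
    cur <- chars[p]
    chars[p] <- sample(setdiff(bases, cur), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate per-species 16S-like reference sequences
#'
#' One sequence per species in `tree`: an ancestral random template is
#' evolved along the family, genus and species branches with a uniform
#' (Jukes-Cantor-style) substitution process. A fixed expansion of the 16S
#' surface-probe recognition segment is embedded, substitution-free, at
#' `probe_site_position` in every sequence (the conserved flank the capture
#' probe targets); genus branches get boosted substitution inside the
#' variable region immediately upstream of it.
#'
#' @param tree A [taxonomy()].
#' @param config A [fixture_config()].
#' @return A `reference_set`: list with `records` (tibble: `species_id`,
#'   `species`, `genus`, `family`, `sequence`, `capture_start`,
#'   `capture_end`), the `taxonomy`, and the embedded `probe_expansion`.
#' @export
make_references <- function(tree, config = fixture_config()) {
  len <- config$ref_length
  pos <- config$probe_site_position
  probe <- shm_probe()
  plen <- nchar(probe)
  if (pos < 1L || pos + plen - 1L > len) stop("probe site outside reference bounds")
  if (!is.null(config$variable_region)) {
    vr <- as.integer(config$variable_region)
    if (vr[2] >= pos && vr[1] <= pos + plen - 1L) {
      stop("variable region overlaps the probe site")
    }
  } else {
    vr <- c(max(1L, pos - config$variable_region_span), pos - 1L)
  }
  withr::with_seed(config$seed, {
    bases <- c("A", "C", "G", "T")
    template <- paste(sample(bases, len, replace = TRUE), collapse = "")
    expansion <- .expand_degenerate_one(probe)
    template <- paste0(substr(template, 1L, pos - 1L), expansion,
                       substr(template, pos + plen, len))
    probe_pos <- pos:(pos + plen - 1L)
    free_pos <- setdiff(seq_len(len), probe_pos)
    vr_pos <- setdiff(seq.int(vr[1], vr[2]), probe_pos)
    rate <- config$branch_substitution_rate
    fam_ids <- tree$taxon_id[tree$rank == "family"]
    gen <- tree[tree$rank == "genus", ]
    sp <- tree[tree$rank == "species", ]
    fam_seq <- setNames(vapply(fam_ids, function(f)
      .substitute_positions(template, rate, free_pos), character(1)), fam_ids)
    gen_seq <- setNames(vapply(seq_len(nrow(gen)), function(i) {
      s <- .substitute_positions(fam_seq[[as.character(gen$parent_id[i])]],
                                 rate, free_pos)
      .substitute_positions(s, min(1, config$genus_boost * rate), vr_pos)
    }, character(1)), gen$taxon_id)
    sp_seq <- vapply(seq_len(nrow(sp)), function(i)
      .substitute_positions(gen_seq[[as.character(sp$parent_id[i])]],
                            rate, free_pos), character(1))
  })
  g_ids <- genus_of(tree, sp$taxon_id)
  parent <- setNames(tree$parent_id, tree$taxon_id)
  f_ids <- unname(parent[as.character(g_ids)])
  records <- tibble(
    species_id = sp$taxon_id,
    species = sp$name,
    genus = tax_name(tree, g_ids),
    family = tax_name(tree, f_ids),
    sequence = sp_seq,
    capture_start = pos,
    capture_end = pos + plen - 1L
  )
  structure(list(records = records, taxonomy = tree,
                 probe_expansion = expansion),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", nrow(x$records), " species, ",
      nchar(x$records$sequence[1]), " nt references, capture site at ",
      x$records$capture_start[1], "-", x$records$capture_end[1], "\n", sep = "")
  invisible(x)
}

#' Write a reference set to FASTA
#'
#' Headers are `species_id|species|genus|family`.
#'
#' @param refs A `reference_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_references_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$records$sequence)
  names(x) <- with(refs$records, paste(species_id, species, genus, family, sep = "|"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' Inverse of [write_references_fasta()]: headers
#' `species_id|species|genus|family` are parsed back into records and a
#' taxonomy is rebuilt from the lineages. Capture sites are located with
#' [locate_capture_site()]; species without one get an absent site.
#'
#' @param path FASTA path.
#' @param locate_sites Locate probe capture sites (default TRUE).
#' @return A `reference_set`.
#' @export
read_references_fasta <- function(path, locate_sites = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    stop("FASTA headers must be species_id|species|genus|family")
  }
  rec <- tibble(
    species_id = as.integer(vapply(parts, `[`, character(1), 1)),
    species = vapply(parts, `[`, character(1), 2),
    genus = vapply(parts, `[`, character(1), 3),
    family = vapply(parts, `[`, character(1), 4),
    sequence = unname(as.character(x)))
  fams <- sort(unique(rec$family))
  gens <- dplyr::distinct(rec[, c("genus", "family")])
  nodes <- dplyr::bind_rows(
    tibble(taxon_id = 1L, name = "root", rank = "root", parent_id = NA_integer_),
    tibble(taxon_id = 1L + seq_along(fams), name = fams, rank = "family",
           parent_id = 1L),
    tibble(taxon_id = 1L + length(fams) + seq_len(nrow(gens)),
           name = gens$genus, rank = "genus",
           parent_id = 1L + match(gens$family, fams)),
    tibble(taxon_id = 1L + length(fams) + nrow(gens) + seq_len(nrow(rec)),
           name = rec$species, rank = "species",
           parent_id = 1L + length(fams) + match(rec$genus, gens$genus)))
  # keep declared species ids where they do not collide with internal nodes
  tree <- taxonomy(nodes)
  sp_ids <- nodes$taxon_id[nodes$rank == "species"]
  id_map <- setNames(sp_ids, rec$species_id)
  rec$species_id <- unname(id_map[as.character(rec$species_id)])
  if (locate_sites) {
    sites <- lapply(rec$sequence, locate_capture_site)
    rec$capture_start <- vapply(sites, function(s)
      if (is.null(s)) NA_integer_ else s$start, integer(1))
    rec$capture_end <- vapply(sites, function(s)
      if (is.null(s)) NA_integer_ else s$end, integer(1))
  }
  structure(list(records = rec, taxonomy = tree, probe_expansion = NA),
            class = "reference_set")
}

# ---------------------------------------------------------------------------
# spatial count data with known model parameters

#' Parameters for the spatial count generator
#'
#' @param beta Long tibble with columns `taxon`, `condition`, `animal`,
#'   `mroi`, `beta`: the characteristic log-rate of each taxon in each MROI
#'   for each (condition, animal) cell.
#' @param alpha Spatial autocorrelation of the conditional autoregressive
#'   (CAR) field, in (0, 1).
#' @param tau Conditional precision of the CAR field (> 0).
#' @param sigma Spot-level noise standard deviation (>= 0).
#' @param theta Named vector of per-taxon dropout probabilities in \[0, 1\]
#'   (or a scalar recycled over taxa).
#' @param size_factors Scalar or tibble (`section_id`, `barcode`, `s`) of
#'   sequencing-depth size factors; default 1 for every spot.
#' @return List of class `spatial_params`.
#' @export
spatial_params <- function(beta, alpha = 0.7, tau = 2, sigma = 0.2,
                           theta = 0.1, size_factors = 1) {
  stopifnot(alpha > 0, alpha < 1, tau > 0, sigma >= 0,
            all(theta >= 0), all(theta <= 1))
  structure(list(beta = as_tibble(beta), alpha = alpha, tau = tau,
                 sigma = sigma, theta = theta, size_factors = size_factors),
            class = "spatial_params")
}

#' Simulate MROI-structured spatial count data
#'
#' Draws counts from the generative spatial model: per section, a spatial
#' field psi is sampled from the CAR prior on the 4-neighbour (rook) grid
#' adjacency of the annotated spots, spot noise eps is i.i.d. normal, the
#' rate is lambda = exp(B + psi + eps) with B the MROI/condition/animal
#' characteristic expression, and each count is zero-inflated Poisson:
#' 0 with probability theta, else Poisson(s * lambda). All latents are
#' stored so parameter-recovery tests can compare against the truth.
#'
#' @param layout An [array_layout()].
#' @param annotations Annotation tibble (`barcode`, `mroi`, `section_id`,
#'   `condition`, `animal_id`); must reference layout barcodes.
#' @param params A [spatial_params()].
#' @param seed Integer seed.
#' @return A `synthetic_tissue`: list with `counts` (long tibble: `taxon`,
#'   `section_id`, `barcode`, `count`), `latents` (long tibble incl. `B`,
#'   `psi`, `eps`, `lambda`, `s`), `layout`, `annotations`, `params`.
#' @export
make_spatial_dataset <- function(layout, annotations, params, seed = 1L) {
  annotations <- validate_annotations(annotations, layout)
  taxa <- unique(params$beta$taxon)
  theta <- params$theta
  if (length(theta) == 1L) theta <- setNames(rep(theta, length(taxa)), taxa)
  stopifnot(all(taxa %in% names(theta)))
  coords <- setNames(split(layout[, c("x", "y")], seq_len(nrow(layout))), layout$barcode)
  xy <- as.data.frame(layout[, c("barcode", "x", "y")])
  sections <- split(annotations, annotations$section_id)
  out_counts <- list(); out_lat <- list()
  withr::with_seed(seed, {
    for (sec in names(sections)) {
      ann <- sections[[sec]]
      sxy <- merge(ann, xy, by = "barcode", sort = FALSE)
      adj <- build_adjacency(sxy$x, sxy$y)
      Q <- car_precision(adj$K, adj$W, params$alpha, params$tau)
      U <- chol(as.matrix(Q))
      n <- nrow(sxy)
      s <- params$size_factors
      if (is.data.frame(s)) {
        key <- merge(sxy[, c("barcode", "section_id")], s,
                     by = c("barcode", "section_id"), sort = FALSE)
        svec <- key$s
      } else svec <- rep(s, n)
      cond <- ann$condition[1]; anim <- ann$animal_id[1]
      for (tx in taxa) {
        b <- params$beta[params$beta$taxon == tx &
                           params$beta$condition == cond &
                           params$beta$animal == anim, ]
        bmap <- setNames(b$beta, b$mroi)
        if (!all(sxy$mroi %in% names(bmap))) {
          stop("missing beta for some MROI of section ", sec, ", taxon ", tx)
        }
        B <- unname(bmap[sxy$mroi])
        psi <- backsolve(U, rnorm(n))
        eps <- rnorm(n, 0, params$sigma)
        lambda <- exp(B + psi + eps)
        gate <- rbinom(n, 1L, theta[[tx]])
        y <- ifelse(gate == 1L, 0L, rpois(n, svec * lambda))
        out_counts[[length(out_counts) + 1L]] <- tibble(
          taxon = tx, section_id = sec, barcode = sxy$barcode, count = as.integer(y))
        out_lat[[length(out_lat) + 1L]] <- tibble(
          taxon = tx, section_id = sec, barcode = sxy$barcode,
          mroi = sxy$mroi, B = B, psi = psi, eps = eps,
          lambda = lambda, s = svec)
      }
    }
  })
  structure(list(counts = dplyr::bind_rows(out_counts),
                 latents = dplyr::bind_rows(out_lat),
                 layout = layout, annotations = annotations, params = params,
                 seed = as.integer(seed)),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat("<synthetic_tissue> ", length(unique(x$counts$taxon)), " taxa x ",
      length(unique(x$annotations$section_id)), " section(s), ",
      nrow(x$annotations), " annotated spots\n", sep = "")
  invisible(x)
}

#' Extract one section of a synthetic tissue as a taxa-by-barcode matrix
#'
#' @param tissue A `synthetic_tissue`.
#' @param section_id Section to extract (default: first).
#' @return A [taxa_matrix()].
#' @export
tissue_counts_matrix <- function(tissue, section_id = NULL) {
  cts <- tissue$counts
  if (is.null(section_id)) section_id <- cts$section_id[1]
  cts <- cts[cts$section_id == section_id, ]
  wide <- tidyr::pivot_wider(cts[, c("taxon", "barcode", "count")],
                             names_from = "barcode", values_from = "count",
                             values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$taxon
  taxa_matrix(m)
}

# ---------------------------------------------------------------------------
# snRNA-seq-like cell-type signatures

#' Generate block-structured cell-type expression signatures
#'
#' Emulates cluster-averaged single-nucleus RNA-seq profiles: each cell type
#' has a dedicated block of marker genes with elevated mean expression, all
#' other genes share a low baseline; sampled cells add multiplicative
#' log-normal noise around the type mean.
#'
#' @param n_celltypes Number of cell types (default 30, the cluster count
#'   used for the mouse colon reference).
#' @param n_genes Number of genes.
#' @param cells_per_type Sampled cells per type.
#' @param marker_fold Fold elevation of marker-gene means.
#' @param noise_sd Log-normal noise sd for sampled cells.
#' @param seed Integer seed.
#' @return List with `means` (gene x type matrix), `cells` (gene x cell
#'   matrix), `cell_type` (per-cell labels), `markers` (tibble `gene`,
#'   `celltype`).
#' @export
make_celltype_signatures <- function(n_celltypes = 30L, n_genes = 600L,
                                     cells_per_type = 20L, marker_fold = 8,
                                     noise_sd = 0.3, seed = 1L) {
  stopifnot(n_celltypes >= 2L, n_genes >= n_celltypes)
  withr::with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    types <- sprintf("celltype_%02d", seq_len(n_celltypes))
    base <- matrix(stats::rgamma(n_genes * n_celltypes, shape = 2, rate = 2),
                   n_genes, n_celltypes, dimnames = list(genes, types))
    n_marked <- n_genes - (n_genes %% n_celltypes)
    marker_type <- rep(seq_len(n_celltypes), each = n_marked / n_celltypes)
    marker_gene <- seq_len(n_marked)
    means <- base
    for (i in seq_along(marker_gene)) {
      g <- marker_gene[i]; k <- marker_type[i]
      means[g, k] <- max(means[g, ]) * marker_fold
    }
    cells <- matrix(0, n_genes, n_celltypes * cells_per_type)
    lab <- character(ncol(cells))
    for (k in seq_len(n_celltypes)) {
      idx <- (k - 1L) * cells_per_type + seq_len(cells_per_type)
      noise <- matrix(exp(rnorm(n_genes * cells_per_type, 0, noise_sd)),
                      n_genes, cells_per_type)
      cells[, idx] <- means[, k] * noise
      lab[idx] <- types[k]
    }
    dimnames(cells) <- list(genes, sprintf("cell_%04d", seq_len(ncol(cells))))
  })
  list(means = means, cells = cells, cell_type = lab,
       markers = tibble(gene = genes[marker_gene], celltype = types[marker_type]))
}
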