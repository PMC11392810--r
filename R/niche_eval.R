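#' Standardize a matrix within genes
#'
#' Per-row (gene) z-scores using the sample (n-1) standard deviation.
#' Zero-variance rows are dropped with a warning.
#'
#' @param m Numeric matrix (genes x observations).
#' @return Standardized matrix (possibly fewer rows).
#' @export
standardize_genes <- function(m) {
  if (ncol(m) < 2) stop("need >= 2 observations to standardize")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  keep <- s > 0
  if (!any(keep)) stop("all genes have zero variance")
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance gene(s) dropped")
  }
  (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
}

#' Cell-to-spot similarity matrix
#'
#' Pearson correlation between every standardized cell expression vector and
#' every standardized spot expression vector, over their common genes.
#'
#' @param cell_mat Genes x cells matrix (e.g. snRNA-seq normalized counts).
#' @param spot_mat Genes x spots matrix (e.g. posterior mean rates).
#' @return Cells x spots correlation matrix in \[-1, 1\].
#' @export
cell_spot_similarity <- function(cell_mat, spot_mat) {
  common <- intersect(rownames(cell_mat), rownames(spot_mat))
  if (length(common) < 3) stop("fewer than 3 common genes")
  X <- standardize_genes(cell_mat[common, , drop = FALSE])
  L <- standardize_genes(spot_mat[common, , drop = FALSE])
  shared <- intersect(rownames(X), rownames(L))
  if (length(shared) < 3) stop("fewer than 3 common genes after standardization")
  cor(X[shared, , drop = FALSE], L[shared, , drop = FALSE])
}

#' Spatial co-expression modules
#'
#' Genes are clustered by their standardized spot-expression vectors:
#' hierarchical agglomerative clustering with average linkage on Manhattan
#' (L1) distance, cut into exactly `n_modules` flat clusters. Alternatively
#' (`similarity` given) the cell x spot similarity matrix rows are clustered,
#' the literal reading of clustering "the data P".
#'
#' @param spot_std Genes x spots standardized matrix.
#' @param n_modules Number of modules (default 28).
#' @param similarity Optional cells x spots similarity to cluster instead.
#' @return Tibble `gene` (or `cell`), `module`.
#' @export
cluster_modules <- function(spot_std, n_modules = 28L, similarity = NULL) {
  m <- if (is.null(similarity)) spot_std else similarity
  if (n_modules > nrow(m)) stop("n_modules exceeds number of genes")
  hc <- stats::hclust(stats::dist(m, method = "manhattan"), method = "average")
  lab <- stats::cutree(hc, k = n_modules)
  tibble(gene = rownames(m), module = as.integer(lab))
}

#' Cluster-mean expression scaled per gene
#'
#' Mean expression per cell-type cluster, each gene divided by its maximum
#' cluster mean. Genes whose pre-scaling mean across clusters falls below
#' `expression_floor` are removed (with `floor_rule = "scaled"`, the literal
#' alternative, the filter applies to the scaled averages instead).
#'
#' @param cells Genes x cells matrix.
#' @param labels Cell-type label per cell.
#' @param expression_floor Minimum expression (default 1).
#' @param floor_rule `"pre_scaling"` (default) or `"scaled"`.
#' @return Genes x cell-types scaled matrix.
#' @export
scale_celltype_means <- function(cells, labels, expression_floor = 1,
                                 floor_rule = c("pre_scaling", "scaled")) {
  floor_rule <- match.arg(floor_rule)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(cells))
  types <- sort(unique(labels))
  means <- vapply(types, function(k)
    rowMeans(cells[, labels == k, drop = FALSE]), numeric(nrow(cells)))
  rownames(means) <- rownames(cells)
  means <- means[rowSums(means) > 0, , drop = FALSE]
  if (floor_rule == "pre_scaling") {
    means <- means[rowMeans(means) >= expression_floor, , drop = FALSE]
    scaled <- means / apply(means, 1, max)
  } else {
    scaled <- means / apply(means, 1, max)
    scaled <- scaled[rowMeans(scaled) >= expression_floor, , drop = FALSE]
  }
  scaled
}

# cosine distance between matrix rows; zero rows get similarity 0
.cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  mn <- m / nrm
  d <- 1 - tcrossprod(mn)
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Partition a module into cell-type submodules
#'
#' Hierarchical clustering of the module's genes on cosine distance over
#' scaled cell-type means, average linkage, cut at `cutoff_frac` times the
#' maximum linkage height.
#'
#' @param scaled Genes x cell-types scaled matrix (the module's genes).
#' @param cutoff_frac Cut height as a fraction of the tree height
#'   (default 0.4).
#' @return Tibble `gene`, `submodule`.
#' @export
partition_submodules <- function(scaled, cutoff_frac = 0.4) {
  if (nrow(scaled) < 2) {
    return(tibble(gene = rownames(scaled),
                  submodule = rep(1L, nrow(scaled))))
  }
  hc <- stats::hclust(.cosine_dist(scaled), method = "average")
  h <- cutoff_frac * max(hc$height)
  lab <- stats::cutree(hc, h = h)
  tibble(gene = rownames(scaled), submodule = as.integer(lab))
}

#' Cell-type enrichment of a submodule
#'
#' Two-sided Wilcoxon signed-rank test, one cell type versus the mean of the
#' rest, on the scaled expression of the submodule's genes, with
#' Benjamini-Hochberg correction across cell types. Submodules below
#' `min_size` genes are reported untested.
#'
#' @param scaled Genes x cell-types scaled matrix.
#' @param genes Submodule gene names.
#' @param min_size Minimum testable submodule size (default 5).
#' @return Tibble `celltype`, `statistic`, `p`, `fdr`, `tested`.
#' @export
enrich_celltypes <- function(scaled, genes, min_size = 5L) {
  genes <- intersect(genes, rownames(scaled))
  types <- colnames(scaled)
  if (length(genes) < min_size) {
    return(tibble(celltype = types, statistic = NA_real_, p = NA_real_,
                  fdr = NA_real_, median_diff = NA_real_, tested = FALSE))
  }
  sub <- scaled[genes, , drop = FALSE]
  res <- lapply(seq_along(types), function(k) {
    x <- sub[, k]
    y <- rowMeans(sub[, -k, drop = FALSE])
    if (all(x == y)) return(c(NA_real_, 1, 0))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    c(unname(wt$statistic), wt$p.value, stats::median(x - y))
  })
  stat <- vapply(res, `[`, numeric(1), 1)
  p <- vapply(res, `[`, numeric(1), 2)
  p[is.na(p)] <- 1
  tibble(celltype = types, statistic = stat, p = p,
         fdr = stats::p.adjust(p, "BH"),
         median_diff = vapply(res, `[`, numeric(1), 3), tested = TRUE)
}

#' Gene-set (pathway) enrichment of a submodule
#'
#' One-tailed Fisher exact test (hypergeometric upper tail) of the overlap
#' between the submodule and each gene set within the universe, with
#' Benjamini-Hochberg correction across sets. Sets empty after intersection
#' with the universe are skipped.
#'
#' @param genes Submodule gene names.
#' @param gene_sets Named list of gene-name vectors (e.g. from [read_gmt()]).
#' @param universe Universe gene names (must cover the submodule).
#' @param fdr_threshold Threshold used to flag `significant` (default 0.05).
#' @return Tibble `set`, `overlap`, `set_size`, `odds_ratio`, `p`, `fdr`,
#'   `significant`.
#' @export
enrich_genesets <- function(genes, gene_sets, universe, fdr_threshold = 0.05) {
  genes <- intersect(genes, universe)
  sets <- lapply(gene_sets, intersect, universe)
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set overlaps the universe")
  N <- length(universe); k <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    m <- length(s)
    q <- length(intersect(genes, s))
    p <- stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    a <- q; b <- k - q; cc <- m - q; d <- (N - m) - b
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    tibble(set = nm, overlap = q, set_size = m, odds_ratio = or, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr_threshold
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then genes, tab-separated).
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[`, character(1), 1))
}

#' Transcripts-per-10,000 normalization
#'
#' Each cell's counts scaled to sum to 10,000; zero-total cells are dropped.
#'
#' @param counts Genes x cells matrix.
#' @return Normalized matrix.
#' @export
tp10k_normalize <- function(counts) {
  tot <- colSums(counts)
  counts <- counts[, tot > 0, drop = FALSE]
  sweep(counts, 2, colSums(counts), "/") * 1e4
}

#' Highly variable gene selection by binned CV residuals
#'
#' Per gene, the mean and coefficient of variation across cells are computed
#' and genes are placed in `n_bins` equal-frequency bins by mean; a LOESS fit
#' of log(CV) on log(mean) yields residuals, and the `n_top` genes with the
#' largest residuals are selected, sampled equally across the bins. With a
#' list of matrices (samples), per-sample selections are combined by
#' consensus recovery rate.
#'
#' @param normalized Genes x cells matrix, or a list of such matrices.
#' @param n_bins Equal-frequency mean bins (default 20).
#' @param n_top Number of genes to select (default 1500).
#' @return Character vector of selected genes.
#' @export
select_variable_genes <- function(normalized, n_bins = 20L, n_top = 1500L) {
  if (is.list(normalized) && !is.matrix(normalized)) {
    picks <- lapply(normalized, select_variable_genes,
                    n_bins = n_bins, n_top = n_top)
    rate <- sort(table(unlist(picks)), decreasing = TRUE)
    return(head(names(rate), n_top))
  }
  m <- normalized
  if (n_top > nrow(m)) stop("n_top exceeds the number of genes")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  ok <- mu > 0 & sdv > 0
  mu <- mu[ok]; cv <- sdv[ok] / mu
  genes <- rownames(m)[ok]
  if (n_top > length(genes)) stop("n_top exceeds the number of usable genes")
  bin <- ceiling(rank(mu, ties.method = "first") / (length(mu) / n_bins))
  fit <- stats::loess(log(cv) ~ log(mu), degree = 2,
                      control = stats::loess.control(surface = "direct"))
  resid <- log(cv) - stats::predict(fit, log(mu))
  per_bin <- ceiling(n_top / n_bins)
  picked <- unlist(lapply(split(seq_along(genes), bin), function(ix) {
    ix[order(resid[ix], decreasing = TRUE)][seq_len(min(per_bin, length(ix)))]
  }), use.names = FALSE)
  # trim/fill globally by residual to exactly n_top
  if (length(picked) > n_top) {
    picked <- picked[order(resid[picked], decreasing = TRUE)][seq_len(n_top)]
  } else if (length(picked) < n_top) {
    rest <- setdiff(order(resid, decreasing = TRUE), picked)
    picked <- c(picked, rest[seq_len(n_top - length(picked))])
  }
  genes[sort(picked)]
}

#' Filter nucleus profiles and genes
#'
#' Cells with more than `min_genes` detected genes are kept (strict), genes
#' detected in at least `min_cells_per_gene` cells are kept, and cells with a
#' flagged-signature (mitochondrial/rRNA) count fraction of
#' `max_flag_frac` or more are removed.
#'
#' @param counts Genes x cells matrix.
#' @param flagged_genes Mito/rRNA gene names.
#' @param min_genes Strict minimum detected genes per cell (default 800).
#' @param min_cells_per_gene Minimum cells per gene (default 10).
#' @param max_flag_frac Flagged-fraction cutoff (default 0.30).
#' @return Filtered matrix.
#' @export
filter_nuclei <- function(counts, flagged_genes = character(0),
                          min_genes = 800L, min_cells_per_gene = 10L,
                          max_flag_frac = 0.30) {
  detected <- colSums(counts > 0)
  m <- counts[, detected > min_genes, drop = FALSE]
  if (ncol(m)) {
    flag <- rownames(m) %in% flagged_genes
    frac <- colSums(m[flag, , drop = FALSE]) / pmax(colSums(m), 1)
    m <- m[, frac < max_flag_frac, drop = FALSE]
  }
  m <- m[rowSums(m > 0) >= min_cells_per_gene, , drop = FALSE]
  if (!nrow(m) || !ncol(m)) stop("no cells or genes survive filtering")
  m
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(u, v)) / (sum(u) + sum(v))` for nonnegative abundance
#' vectors.
#'
#' @param u,v Nonnegative numeric vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  if (any(u < 0) || any(v < 0)) stop("inputs must be nonnegative")
  stopifnot(length(u) == length(v))
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Classification benchmark report
#'
#' Micro accuracy (unclassified counts as incorrect), macro F1 over truth
#' classes, and the false-positive rate defined as misassigned classified
#' reads over total classified reads (so all-unclassified input has FPR 0).
#' Reads are pooled ("bulk-like").
#'
#' @param truth True genus per read.
#' @param predicted Predicted genus per read (NA = unclassified).
#' @return One-row tibble `accuracy`, `macro_f1`, `fpr`, `n`,
#'   `classified_fraction`, with a `per_genus` tibble attribute.
#' @export
classification_report <- function(truth, predicted) {
  if (!length(truth)) stop("empty input")
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  classified <- !is.na(predicted)
  acc <- sum(classified & predicted == truth) / length(truth)
  fpr <- if (!any(classified)) 0 else
    sum(predicted[classified] != truth[classified]) / sum(classified)
  classes <- sort(unique(truth))
  per <- lapply(classes, function(cl) {
    tp <- sum(classified & predicted == cl & truth == cl)
    fp <- sum(classified & predicted == cl & truth != cl)
    fn <- sum(truth == cl) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(genus = cl, n = sum(truth == cl), precision = prec,
           recall = rec, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  out <- tibble(accuracy = acc, macro_f1 = mean(per$f1), fpr = fpr,
                n = length(truth), classified_fraction = mean(classified))
  attr(out, "per_genus") <- per
  out
}

#' Spot-group abundance agreement
#'
#' Spots are randomly partitioned into groups of `group_size`; within each
#' group the relative genus abundances of truth and prediction are compared
#' (Pearson r or Bray-Curtis over the union of genera) and the mean across
#' groups is reported.
#'
#' @param reads Tibble with `barcode` and true genus column `genus`.
#' @param predicted Predicted genus per read (NA = unclassified, excluded
#'   from the predicted composition).
#' @param group_size Spots per group (default 1000).
#' @param metric `"pearson"` or `"bray_curtis"`.
#' @param seed Partition seed.
#' @return Mean metric across groups.
#' @export
spotwise_abundance_agreement <- function(reads, predicted, group_size = 1000L,
                                         metric = c("pearson", "bray_curtis"),
                                         seed = 1L) {
  metric <- match.arg(metric)
  spots <- unique(reads$barcode)
  if (length(spots) < group_size) {
    warning("fewer spots than group_size; using a single group")
    group_size <- length(spots)
  }
  withr::with_seed(seed, {
    spots <- sample(spots)
  })
  grp <- setNames(ceiling(seq_along(spots) / group_size), spots)
  genera <- sort(unique(c(reads$genus, stats::na.omit(predicted))))
  gidx <- grp[reads$barcode]
  vals <- vapply(sort(unique(grp)), function(g) {
    sel <- gidx == g
    tt <- table(factor(reads$genus[sel], levels = genera))
    pp <- table(factor(predicted[sel], levels = genera))
    tv <- as.numeric(tt) / max(sum(tt), 1)
    pv <- as.numeric(pp) / max(sum(pp), 1)
    if (metric == "pearson") {
      if (sd(tv) == 0 || sd(pv) == 0) return(NA_real_)
      cor(tv, pv)
    } else bray_curtis(tv, pv)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Region-matched resampling correlation of two spatial signals
#'
#' Per repetition, at most `max_per_region` coordinates are sampled from each
#' annotated region per sample in both signals, values are min-max scaled
#' within each sample, sampled coordinates are paired within (sample, region)
#' and the Spearman rank correlation of the pooled pairs is computed; the
#' mean over `n_reps` repetitions is returned. Regions present in only one
#' signal are excluded.
#'
#' @param a,b Tibbles with columns `sample`, `region`, `value` (one row per
#'   spatial coordinate).
#' @param max_per_region Coordinates sampled per region per sample
#'   (default 3).
#' @param n_reps Repetitions (default 1000).
#' @param seed Integer seed.
#' @return Mean Spearman rho across repetitions.
#' @export
region_resampling_correlation <- function(a, b, max_per_region = 3L,
                                          n_reps = 1000L, seed = 1L) {
  a <- as_tibble(a); b <- as_tibble(b)
  shared <- intersect(unique(a$region), unique(b$region))
  if (!length(shared)) stop("no shared regions between signals")
  a <- a[a$region %in% shared, ]
  b <- b[b$region %in% shared, ]
  scale01 <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  one_rep <- function() {
    xs <- ys <- numeric(0)
    for (smp in intersect(unique(a$sample), unique(b$sample))) {
      ai <- a[a$sample == smp, ]; bi <- b[b$sample == smp, ]
      av <- scale01(ai$value); bv <- scale01(bi$value)
      for (rg in intersect(unique(ai$region), unique(bi$region))) {
        ia <- which(ai$region == rg); ib <- which(bi$region == rg)
        if (length(ia) == length(ib)) {
          # same coordinate set in both signals: keep coordinates matched
          pick <- sample.int(length(ia), min(max_per_region, length(ia)))
          ia <- ia[pick]; ib <- ib[pick]
        } else {
          ia <- ia[sample.int(length(ia), min(max_per_region, length(ia)))]
          ib <- ib[sample.int(length(ib), min(max_per_region, length(ib)))]
        }
        npair <- min(length(ia), length(ib))
        xs <- c(xs, av[ia[seq_len(npair)]])
        ys <- c(ys, bv[ib[seq_len(npair)]])
      }
    }
    if (length(xs) < 3 || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys, method = "spearman")
  }
  withr::with_seed(seed, mean(vapply(seq_len(n_reps), function(i) one_rep(),
                                     numeric(1)), na.rm = TRUE))
}
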