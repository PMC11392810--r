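# reverse complement for plain character vectors (A/C/G/T/N)
.revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), character(1), USE.NAMES = FALSE)
}

# all k-mers of one sequence (character vector, may contain N)
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# canonical form: lexicographic min of k-mer and its reverse complement;
# batched through Biostrings for speed
.canonical <- function(kmers) {
  if (!length(kmers)) return(kmers)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Build an exact k-mer LCA index
#'
#' Every canonical k-mer occurring in the references maps to the lowest
#' common ancestor (LCA) of all species whose reference contains it; k-mers
#' containing N are skipped. No minimizers, spaced seeds or low-complexity
#' masking are used: at desk scale the contract is the LCA assignment
#' algorithm itself.
#'
#' @param refs A `reference_set` (records + taxonomy).
#' @param k Odd k-mer size, 15-35 (default 31).
#' @return A `kmer_index`: list with `k`, sorted `kmers`, parallel `taxon`
#'   ids, and the `taxonomy`.
#' @export
build_kmer_index <- function(refs, k = 31L) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 35L)
  rec <- refs$records
  if (!nrow(rec)) stop("empty reference set")
  tree <- refs$taxonomy
  km_list <- lapply(seq_len(nrow(rec)), function(i) {
    km <- .kmers(rec$sequence[i], k)
    km <- km[!grepl("N", km, fixed = TRUE)]
    unique(.canonical(km))
  })
  kmer <- unlist(km_list, use.names = FALSE)
  species <- rep(rec$species_id, lengths(km_list))
  o <- order(kmer)
  kmer <- kmer[o]; species <- species[o]
  grp <- cumsum(!duplicated(kmer))
  sets <- split(species, grp)
  ukmer <- kmer[!duplicated(kmer)]
  # LCA per distinct species set (memoized: most k-mers are species-unique)
  keys <- vapply(sets, function(s) paste(sort(unique(s)), collapse = ","),
                 character(1))
  uk <- unique(keys)
  lca_by_key <- setNames(vapply(uk, function(key) {
    ids <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    tax_lca(tree, ids)
  }, integer(1)), uk)
  structure(list(k = k, kmers = ukmer, taxon = unname(lca_by_key[keys]),
                 taxonomy = tree),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$kmers), " canonical k-mers\n",
      sep = "")
  invisible(x)
}

#' Serialize / load a k-mer index
#'
#' TSV with a `#k=<k> n_kmers=<n>` header line, then `kmer<TAB>taxon_id`.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @param taxonomy A [taxonomy()] (needed when loading).
#' @return `path` (write) or a `kmer_index` (read).
#' @export
write_kmer_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d n_kmers=%d", index$k, length(index$kmers)), con)
  writeLines(paste(index$kmers, index$taxon, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path, taxonomy) {
  header <- readLines(path, n = 1L)
  k <- as.integer(sub("^#k=(\\d+).*", "\\1", header))
  df <- readr::read_tsv(path, skip = 1L, col_names = c("kmer", "taxon"),
                        col_types = "ci")
  structure(list(k = k, kmers = df$kmer, taxon = df$taxon, taxonomy = taxonomy),
            class = "kmer_index")
}

# core scoring for one read's hit multiset; returns the chosen node after
# confidence coarsening, or NA
.lca_assign <- function(hit_taxa, total_kmers, tree, confidence) {
  if (!length(hit_taxa)) return(list(node = NA_integer_, confidence = 0))
  hits <- table(hit_taxa)
  hit_ids <- as.integer(names(hits))
  hit_n <- as.integer(hits)
  # clade support: hits at a node count toward all its ancestors
  clade <- new.env(parent = emptyenv())
  for (i in seq_along(hit_ids)) {
    for (a in tax_ancestors(tree, hit_ids[i])) {
      a_chr <- as.character(a)
      clade[[a_chr]] <- (if (is.null(clade[[a_chr]])) 0L else clade[[a_chr]]) + hit_n[i]
    }
  }
  # root-to-leaf path score: sum of hits on the path; candidate leaves are
  # species below any hit node
  sp <- tree$taxon_id[tree$rank == "species"]
  cand <- sp[vapply(sp, function(s)
    any(tax_ancestors(tree, s) %in% hit_ids), logical(1))]
  if (!length(cand)) cand <- hit_ids   # hits only above species level
  path_score <- vapply(cand, function(s)
    sum(hit_n[match(intersect(tax_ancestors(tree, s), hit_ids), hit_ids)]),
    integer(1))
  best <- cand[path_score == max(path_score)]
  node <- if (length(best) > 1L) tax_lca(tree, best) else best
  # confidence coarsening: move to parent while clade support is below the
  # threshold fraction of the read's k-mers
  parent <- setNames(tree$parent_id, tree$taxon_id)
  repeat {
    conf <- clade[[as.character(node)]]
    conf <- if (is.null(conf)) 0 else conf / total_kmers
    if (conf >= confidence || is.na(parent[[as.character(node)]])) break
    node <- parent[[as.character(node)]]
  }
  list(node = node, confidence = conf)
}

# map a final node to the reported genus (or NA when root/above genus)
.node_to_genus <- function(node, tree) {
  if (is.na(node)) return(NA_integer_)
  rk <- tax_rank(tree, node)
  if (rk == "genus") return(node)
  if (rk == "species") return(genus_of(tree, node))
  NA_integer_
}

#' Classify a single read with the k-mer LCA scheme
#'
#' Tallies which taxa the read's canonical k-mers map to, scores each
#' root-to-leaf path by summed hits, picks the maximal path (ties between
#' leaves resolve to their LCA), then coarsens up the tree while the chosen
#' clade's k-mer support is below `confidence` x (total k-mers in the read).
#' The genus-rank ancestor of the final node is reported; reads resolving to
#' the root or above genus rank are unclassified.
#'
#' @param sequence Read sequence.
#' @param index A `kmer_index`.
#' @param confidence Confidence threshold (default 0.01).
#' @return One-row tibble: `taxon_id`, `genus`, `confidence`, `status`
#'   (`classified`, `unclassified`, `no_hits` or `too_short`).
#' @export
classify_read <- function(sequence, index, confidence = 0.01) {
  classify_batch(tibble(read_id = "r1", sequence = sequence),
                 index, confidence)[, -1]
}

#' Classify a batch of reads
#'
#' Vectorized application of [classify_read()]; results are per-read and
#' independent of input order. The returned tibble carries a
#' `classified_fraction` attribute.
#'
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @param index A `kmer_index`.
#' @param confidence Confidence threshold.
#' @return Tibble: `read_id`, `taxon_id` (genus id or NA), `genus` (name or
#'   NA), `confidence`, `status`.
#' @export
classify_batch <- function(reads, index, confidence = 0.01) {
  tree <- index$taxonomy
  n <- nrow(reads)
  if (!n) {
    out <- tibble(read_id = character(), taxon_id = integer(),
                  genus = character(), confidence = double(),
                  status = character())
    attr(out, "classified_fraction") <- NA_real_
    return(out)
  }
  k <- index$k
  lens <- nchar(reads$sequence)
  n_km <- pmax(0L, lens - k + 1L)
  km_list <- lapply(reads$sequence, .kmers, k = k)
  all_km <- unlist(km_list, use.names = FALSE)
  ridx <- rep(seq_len(n), lengths(km_list))
  hit_taxon <- rep(NA_integer_, length(all_km))
  if (length(all_km)) {
    ok <- !grepl("N", all_km, fixed = TRUE)
    canon <- all_km
    canon[ok] <- .canonical(all_km[ok])
    m <- match(canon, index$kmers)
    m[!ok] <- NA_integer_
    hit_taxon <- index$taxon[m]
  }
  taxon_id <- rep(NA_integer_, n)
  conf_out <- numeric(n)
  status <- rep("unclassified", n)
  by_read <- split(hit_taxon, factor(ridx, levels = seq_len(n)))
  for (i in seq_len(n)) {
    if (lens[i] < k) { status[i] <- "too_short"; next }
    hits <- by_read[[i]]
    hits <- hits[!is.na(hits)]
    if (!length(hits)) { status[i] <- "no_hits"; next }
    res <- .lca_assign(hits, n_km[i], tree, confidence)
    conf_out[i] <- res$confidence
    g <- .node_to_genus(res$node, tree)
    if (!is.na(g)) { taxon_id[i] <- g; status[i] <- "classified" }
  }
  out <- tibble(read_id = reads$read_id, taxon_id = taxon_id,
                genus = ifelse(is.na(taxon_id), NA_character_,
                               tax_name(tree, taxon_id)),
                confidence = conf_out, status = status)
  attr(out, "classified_fraction") <- mean(status == "classified")
  out
}
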