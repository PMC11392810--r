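# mean Phred score of a Sanger-encoded quality string
.mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trim 3' adapter read-through
#'
#' Removes the longest read suffix matching an adapter prefix with at least
#' `min_overlap` nt of overlap and at most `max_mismatch` mismatches.
#' Qualities, when present, are trimmed alongside.
#'
#' @param reads Tibble with a `sequence` column (optionally `qualities`).
#' @param adapters Nonempty character vector of adapter sequences.
#' @param min_overlap Minimum suffix/prefix overlap (default 8).
#' @param max_mismatch Maximum mismatches in the overlap (default 1).
#' @return `reads` with trimmed `sequence`/`qualities`.
#' @export
trim_adapters <- function(reads, adapters, min_overlap = 8L, max_mismatch = 1L) {
  if (!length(adapters)) stop("adapter list is empty")
  seqs <- reads$sequence
  keep_len <- nchar(seqs)
  for (ad in adapters) {
    achars <- strsplit(ad, "", fixed = TRUE)[[1]]
    for (i in seq_along(seqs)) {
      n <- keep_len[i]
      s <- substr(seqs[i], 1L, n)
      best <- 0L
      max_ov <- min(n, length(achars))
      if (max_ov < min_overlap) next
      schars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (ov in max_ov:min_overlap) {     # longest first
        mm <- sum(schars[(n - ov + 1L):n] != achars[seq_len(ov)])
        if (mm <= max_mismatch) { best <- ov; break }
      }
      if (best > 0L) keep_len[i] <- n - best
    }
  }
  reads$sequence <- substr(seqs, 1L, keep_len)
  if ("qualities" %in% names(reads)) {
    reads$qualities <- substr(reads$qualities, 1L, keep_len)
  }
  reads
}

#' Mean-quality filter
#'
#' Keeps reads whose mean Phred score is at least `min_mean_q` (default 20).
#'
#' @param reads Tibble with `qualities`.
#' @param min_mean_q Mean-quality threshold.
#' @return Filtered tibble.
#' @export
quality_filter <- function(reads, min_mean_q = 20) {
  if (!nrow(reads)) return(reads)
  reads[.mean_phred(reads$qualities) >= min_mean_q, ]
}

#' Length filter
#'
#' Keeps reads strictly longer than `min_len` nt (default 100: a 100-nt read
#' is removed).
#'
#' @param reads Tibble with `sequence`.
#' @param min_len Strict minimum length.
#' @return Filtered tibble.
#' @export
length_filter <- function(reads, min_len = 100L) {
  reads[nchar(reads$sequence) > min_len, ]
}

#' Demultiplex observed spatial barcodes against a layout
#'
#' Candidate bank barcodes are retrieved by shared 6-mers with the observed
#' barcode; among candidates, the unique bank barcode within Hamming distance
#' `max_mismatch` is assigned. Ties (two candidates at equal minimal
#' distance) and observed barcodes with N at more than `max_mismatch`
#' positions are unassigned.
#'
#' @param reads Tibble with `read_id` and `barcode_obs` (18 nt).
#' @param layout An [array_layout()] (the barcode bank).
#' @param index_k k-mer size for candidate retrieval (default 6).
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return Tibble: `read_id`, `barcode` (assigned or NA), `distance`,
#'   `n_candidates`, `reason` (NA when assigned).
#' @export
demux <- function(reads, layout, index_k = 6L, max_mismatch = 2L) {
  bank <- layout$barcode
  bw <- nchar(bank[1])
  if (length(bank) >= 2 && length(bank) <= 200) {
    # small banks: verify the pairwise-separation precondition
    bm <- do.call(rbind, strsplit(bank, "", fixed = TRUE))
    dmin <- bw
    for (i in seq_len(length(bank) - 1L)) {
      d <- rowSums(bm[(i + 1L):length(bank), , drop = FALSE] !=
                     matrix(bm[i, ], length(bank) - i, bw, byrow = TRUE))
      dmin <- min(dmin, d)
    }
    if (dmin <= 2L * max_mismatch) {
      warning("bank barcodes closer than 2*max_mismatch + 1; ",
              "ties will be unassigned")
    }
  }
  # positional-free k-mer index over the bank
  nk <- bw - index_k + 1L
  bank_km <- lapply(bank, function(b) unique(substring(b, 1:nk, index_k:bw)))
  km2bank <- split(rep(seq_along(bank), lengths(bank_km)),
                   unlist(bank_km, use.names = FALSE))
  bank_mat <- do.call(rbind, strsplit(bank, "", fixed = TRUE))
  obs <- unique(reads$barcode_obs)
  assign_one <- function(ob) {
    if (nchar(ob) != bw) return(list(NA_integer_, NA_integer_, 0L, "bad_length"))
    chars <- strsplit(ob, "", fixed = TRUE)[[1]]
    if (sum(chars == "N") > max_mismatch) {
      return(list(NA_integer_, NA_integer_, 0L, "ambiguous_bases"))
    }
    km <- unique(substring(ob, 1:nk, index_k:bw))
    cand <- unique(unlist(km2bank[km], use.names = FALSE))
    if (!length(cand)) return(list(NA_integer_, NA_integer_, 0L, "no_candidates"))
    d <- rowSums(bank_mat[cand, , drop = FALSE] !=
                   matrix(chars, length(cand), bw, byrow = TRUE))
    dmin <- min(d)
    if (dmin > max_mismatch) {
      return(list(NA_integer_, NA_integer_, length(cand), "too_distant"))
    }
    hits <- cand[d == dmin]
    if (length(hits) > 1L) {
      return(list(NA_integer_, as.integer(dmin), length(cand), "ambiguous"))
    }
    list(hits, as.integer(dmin), length(cand), NA_character_)
  }
  res <- lapply(obs, assign_one)
  lut <- tibble(
    barcode_obs = obs,
    barcode = bank[vapply(res, function(r) r[[1]], integer(1))],
    distance = vapply(res, function(r) r[[2]], integer(1)),
    n_candidates = vapply(res, function(r) r[[3]], integer(1)),
    reason = vapply(res, function(r) r[[4]], character(1)))
  out <- dplyr::left_join(reads[, c("read_id", "barcode_obs")], lut,
                          by = "barcode_obs")
  out[, c("read_id", "barcode", "distance", "n_candidates", "reason")]
}

#' Host k-mer screen
#'
#' Flags a read as host when at least `hit_fraction` of its k-mers occur in
#' the host k-mer set (canonical form). An empty host set is a no-op.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param host_kmers Character vector of canonical host k-mers (may be empty).
#' @param k k-mer size (default 31; must match the host set).
#' @param hit_fraction Host-call threshold (default 0.5).
#' @return `reads` with a logical `host` column.
#' @export
host_screen <- function(reads, host_kmers, k = 31L, hit_fraction = 0.5) {
  if (!length(host_kmers) || !nrow(reads)) {
    reads$host <- rep(FALSE, nrow(reads))
    return(reads)
  }
  frac <- vapply(reads$sequence, function(s) {
    km <- .kmers(s, k)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (!length(km)) return(0)
    mean(.canonical(km) %in% host_kmers)
  }, numeric(1), USE.NAMES = FALSE)
  reads$host <- frac >= hit_fraction
  reads
}

#' Canonical k-mer set of host sequences
#'
#' @param sequences Host nucleotide sequences.
#' @param k k-mer size (default 31).
#' @return Character vector of unique canonical k-mers.
#' @export
host_kmer_set <- function(sequences, k = 31L) {
  km <- unlist(lapply(sequences, .kmers, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  unique(.canonical(km))
}

#' Two-stage taxonomic classification
#'
#' First pass: k-mer LCA assignment at genus rank. Reads it leaves
#' unclassified (or resolved above genus) are routed to the deep classifier.
#' The output records which stage produced each call.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param index A `kmer_index`.
#' @param model A fitted `deep_taxa_model` (or NULL to run stage 1 only).
#' @param confidence First-pass confidence threshold (default 0.01).
#' @return Tibble: `read_id`, `genus`, `confidence`/`probability`, `stage`
#'   (`"kmer"`, `"deep"` or NA when both stages fail).
#' @export
classify_two_stage <- function(reads, index, model = NULL, confidence = 0.01) {
  stage1 <- classify_batch(reads, index, confidence)
  out <- tibble(read_id = stage1$read_id, genus = stage1$genus,
                score = stage1$confidence,
                stage = ifelse(stage1$status == "classified", "kmer", NA_character_))
  todo <- is.na(out$stage)
  if (!is.null(model) && any(todo)) {
    vocab1 <- sort(tax_name(index$taxonomy,
                            index$taxonomy$taxon_id[index$taxonomy$rank == "genus"]))
    if (!all(model$classes %in% vocab1)) {
      stop("genus vocabulary mismatch between classifier stages")
    }
    pred <- predict_genus(model, reads$sequence[todo])
    out$genus[todo] <- pred$genus
    out$score[todo] <- pred$probability
    out$stage[todo] <- "deep"
  }
  out
}

#' Collapse UMIs into molecules
#'
#' Within each (barcode, genus) group, UMIs at Hamming distance <= 1 are
#' connected and each connected component counts as one molecule (directional
#' single-linkage clustering at threshold 1). The representative UMI is the
#' most frequent in the component.
#'
#' @param assignments Tibble with `read_id`, `barcode`, `genus`, `umi`
#'   (7 nt); rows with NA barcode or genus are ignored.
#' @return Tibble of molecules: `barcode`, `genus`, `umi`, `n_reads`.
#' @export
collapse_umis <- function(assignments) {
  df <- assignments[!is.na(assignments$barcode) & !is.na(assignments$genus), ]
  if (!nrow(df)) {
    return(tibble(barcode = character(), genus = character(),
                  umi = character(), n_reads = integer()))
  }
  if (any(nchar(df$umi) != 7L)) stop("UMIs must be 7 nt")
  groups <- split(df$umi, paste(df$barcode, df$genus, sep = "\r"))
  res <- lapply(names(groups), function(key) {
    umis <- groups[[key]]
    cnt <- table(umis)
    u <- names(cnt)
    nu <- length(u)
    comp <- seq_len(nu)
    if (nu > 1L) {
      mat <- do.call(rbind, strsplit(u, "", fixed = TRUE))
      # union-find over pairs at Hamming distance <= 1
      find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
      for (i in seq_len(nu - 1L)) {
        for (j in (i + 1L):nu) {
          if (sum(mat[i, ] != mat[j, ]) <= 1L) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) comp[rj] <- ri
          }
        }
      }
      comp <- vapply(seq_len(nu), find, integer(1))
    }
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    by_comp <- split(seq_len(nu), comp)
    tibble(
      barcode = parts[1], genus = parts[2],
      umi = unname(vapply(by_comp, function(ix) u[ix][which.max(cnt[ix])],
                          character(1))),
      n_reads = unname(vapply(by_comp, function(ix) sum(cnt[ix]), integer(1))))
  })
  dplyr::bind_rows(res)
}

#' Molecule table to taxa-by-barcode matrix
#'
#' @param molecules Tibble from [collapse_umis()].
#' @param layout An [array_layout()]; all barcodes must exist in it. Columns
#'   cover only barcodes with at least one molecule.
#' @return A [taxa_matrix()] of molecule counts (all-zero when empty).
#' @export
to_taxa_matrix <- function(molecules, layout) {
  unknown <- setdiff(molecules$barcode, layout$barcode)
  if (length(unknown)) stop("barcode(s) not in layout: ", unknown[1])
  if (!nrow(molecules)) {
    m <- matrix(integer(0), nrow = 0, ncol = 0,
                dimnames = list(character(0), character(0)))
    return(taxa_matrix(m))
  }
  tab <- table(molecules$genus, molecules$barcode)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  taxa_matrix(m)
}

#' Run the spatial bacterial read-processing pipeline
#'
#' Stage order: adapter trim, mean-quality filter, length filter, barcode
#' demultiplexing, host k-mer screen, two-stage classification, UMI
#' collapsing, matrix emission. The QC report gives exact per-stage read
#' accounting (kept + removed = input at every stage).
#'
#' @param reads Tibble from [read_fastq_pairs()] (or a `readset$reads` with
#'   `barcode` renamed to `barcode_obs`).
#' @param layout An [array_layout()].
#' @param index A `kmer_index`.
#' @param model Optional fitted `deep_taxa_model` for the fallback stage.
#' @param adapters Adapter sequences for 3' trimming (default none).
#' @param host_kmers Canonical host k-mer set (default empty = no-op).
#' @param min_mean_q,min_len,confidence,max_mismatch Stage thresholds.
#' @return List of class `shmseq_run`: `matrix` ([taxa_matrix()]),
#'   `molecules`, `assignments`, `qc` (per-stage counts tibble, plus
#'   `classified_fraction` attribute).
#' @export
run_pipeline <- function(reads, layout, index, model = NULL,
                         adapters = character(0), host_kmers = character(0),
                         min_mean_q = 20, min_len = 100L, confidence = 0.01,
                         max_mismatch = 2L) {
  qc <- list()
  n0 <- nrow(reads)
  if (length(adapters)) reads <- trim_adapters(reads, adapters)
  qc$input <- tibble(stage = "input", kept = n0, removed = 0L)
  r1 <- quality_filter(reads, min_mean_q)
  qc$quality <- tibble(stage = "quality_filter", kept = nrow(r1),
                       removed = nrow(reads) - nrow(r1))
  r2 <- length_filter(r1, min_len)
  qc$length <- tibble(stage = "length_filter", kept = nrow(r2),
                      removed = nrow(r1) - nrow(r2))
  dm <- demux(r2, layout, max_mismatch = max_mismatch)
  r3 <- dplyr::inner_join(r2, dm[!is.na(dm$barcode), c("read_id", "barcode")],
                          by = "read_id")
  qc$demux <- tibble(stage = "demux", kept = nrow(r3),
                     removed = nrow(r2) - nrow(r3))
  r4 <- host_screen(r3, host_kmers)
  r5 <- r4[!r4$host, ]
  qc$host <- tibble(stage = "host_screen", kept = nrow(r5),
                    removed = nrow(r4) - nrow(r5))
  cls <- classify_two_stage(r5, index, model, confidence)
  asg <- dplyr::inner_join(r5[, c("read_id", "barcode", "umi")],
                           cls[!is.na(cls$genus),
                               c("read_id", "genus", "stage", "score")],
                           by = "read_id")
  qc$classify <- tibble(stage = "classify", kept = nrow(asg),
                        removed = nrow(r5) - nrow(asg))
  mol <- collapse_umis(asg)
  mat <- to_taxa_matrix(mol, layout)
  qc_tbl <- dplyr::bind_rows(qc)
  attr(qc_tbl, "classified_fraction") <-
    if (nrow(r5)) nrow(asg) / nrow(r5) else NA_real_
  structure(list(matrix = mat, molecules = mol, assignments = asg,
                 demux = dm, qc = qc_tbl),
            class = "shmseq_run")
}

#' @export
print.shmseq_run <- function(x, ...) {
  cat("<shmseq_run> ", nrow(x$matrix), " taxa x ", ncol(x$matrix),
      " barcodes, ", sum(x$matrix), " molecules\n", sep = "")
  print(x$qc)
  invisible(x)
}

#' Genus relative abundances of a pipeline run
#'
#' @param run A `shmseq_run` (or a [taxa_matrix()]).
#' @return Tibble `genus`, `molecules`, `abundance`.
#' @export
genus_abundances <- function(run) {
  m <- if (inherits(run, "shmseq_run")) run$matrix else run
  tot <- rowSums(m)
  tibble(genus = rownames(m), molecules = as.integer(tot),
         abundance = as.numeric(tot / sum(tot)))
}
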