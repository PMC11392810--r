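#' The 16S surface-probe recognition segment
#'
#' The capture probe is 5'-GGATTAGATACCCBDGTAGTCGAGATNB-(A20)-3'. The 20-nt
#' poly(A) tail is the capture handle and is excluded from alignment; the
#' degenerate 28-nt recognition segment returned here (IUPAC codes B, D, N)
#' is what is aligned against reference sequences to locate the capture site.
#'
#' @return The degenerate recognition segment as a character scalar.
#' @export
shm_probe <- function() "GGATTAGATACCCBDGTAGTCGAGATNB"

# IUPAC expansion of a degenerate nucleotide string
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Expand a degenerate IUPAC nucleotide string
#'
#' @param probe Character scalar over the IUPAC alphabet.
#' @return Character vector of all concrete expansions.
#' @export
expand_degenerate <- function(probe) {
  chars <- strsplit(toupper(probe), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.iupac))
  if (length(bad)) stop("non-IUPAC character(s): ", paste(bad, collapse = ", "))
  sets <- .iupac[chars]
  n <- prod(lengths(sets))
  if (n > 1e5) stop("probe too degenerate to expand (", n, " expansions)")
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# one expansion drawn uniformly (uses the current RNG stream)
.expand_degenerate_one <- function(probe) {
  chars <- strsplit(toupper(probe), "", fixed = TRUE)[[1]]
  paste(vapply(.iupac[chars], function(s) s[sample.int(length(s), 1L)],
               character(1)), collapse = "")
}

#' Locate the probe capture site on a reference sequence
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, gap -2) of every
#' concrete expansion of the degenerate probe against the reference. The
#' best-scoring interval wins; ties are broken by highest score, then
#' leftmost start. Sites scoring below `floor_frac` of the maximum attainable
#' score (probe length) are reported absent, mirroring exclusion of species
#' whose reference lacks the 16S capture flank.
#'
#' @param reference Reference nucleotide string.
#' @param probe Degenerate probe (default [shm_probe()]).
#' @param floor_frac Score floor as a fraction of the probe length.
#' @return List `(start, end, score)` (1-based, inclusive) or `NULL` when no
#'   alignment clears the floor.
#' @export
locate_capture_site <- function(reference, probe = shm_probe(), floor_frac = 0.8) {
  key <- paste0("probe_", probe)
  if (is.null(.shmseq_cache[[key]])) {
    .shmseq_cache[[key]] <- Biostrings::DNAStringSet(expand_degenerate(probe))
  }
  pats <- .shmseq_cache[[key]]
  subj <- Biostrings::DNAString(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  scores <- Biostrings::score(aln)
  starts <- Biostrings::start(Biostrings::subject(aln))
  ends <- Biostrings::end(Biostrings::subject(aln))
  best <- order(-scores, starts)[1]
  if (scores[best] < floor_frac * nchar(probe)) return(NULL)
  list(start = starts[best], end = ends[best], score = scores[best])
}

#' Fragment length model
#'
#' Fragment lengths are drawn from Normal(mean, sd), rounded to the nearest
#' integer, truncated below at 1 and above at the available upstream span;
#' the sequenced read keeps the `trim_to` bases adjacent to the capture site.
#'
#' @param mean,sd Normal parameters in bp.
#' @param trim_to Read-length cap in bp.
#' @return List of class `length_model`.
#' @export
length_model <- function(mean = 400, sd = 44, trim_to = 150L) {
  stopifnot(mean > 0, sd >= 0, trim_to > 0)
  structure(list(mean = mean, sd = sd, trim_to = as.integer(trim_to)),
            class = "length_model")
}

#' Sample a probe-anchored fragment
#'
#' Draws a length from the model and takes that many bases immediately
#' upstream of the capture site, then trims to `trim_to` bases keeping the
#' end adjacent to the site (the captured end).
#'
#' @param reference Reference sequence.
#' @param site Capture site as returned by [locate_capture_site()].
#' @param model A [length_model()].
#' @return List `(sequence, start, end)` with the 1-based fragment interval
#'   on the reference.
#' @export
sample_fragment <- function(reference, site, model = length_model()) {
  span <- site$start - 1L
  if (span < 1L) stop("capture site at reference start: zero-length fragment")
  L <- max(1L, round(rnorm(1L, model$mean, model$sd)))
  L <- min(L, span)
  start <- site$start - L
  frag <- substr(reference, start, site$start - 1L)
  if (L > model$trim_to) {
    start <- site$start - model$trim_to
    frag <- substr(reference, start, site$start - 1L)
  }
  list(sequence = frag, start = start, end = site$start - 1L)
}

# vectorized uniform substitution: each base substituted (to a different
# base, uniform over the other three) with probability `rate`
.substitute_uniform <- function(sequences, rate) {
  if (rate <= 0) return(sequences)
  bases <- c("A", "C", "G", "T")
  vapply(sequences, function(s) {
    n <- nchar(s)
    if (n == 0L) return(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    cur <- match(chars[hit], bases)          # NA for N: substitute uniformly
    step <- sample.int(3L, length(hit), replace = TRUE)
    new <- ifelse(is.na(cur), bases[sample.int(4L, length(hit), replace = TRUE)],
                  bases[(cur - 1L + step) %% 4L + 1L])
    chars[hit] <- new
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Introduce single-point mutations
#'
#' Each base is independently substituted, to a different base chosen
#' uniformly, with probability `rate` (biological divergence of the
#' simulated community, applied before shortening).
#'
#' @param sequences Character vector of sequences.
#' @param rate Per-base substitution probability in \[0, 1\].
#' @return Mutated sequences.
#' @export
mutate_sequence <- function(sequences, rate) {
  stopifnot(rate >= 0, rate <= 1)
  .substitute_uniform(sequences, rate)
}

#' Introduce sequencing errors
#'
#' Same uniform substitution process as [mutate_sequence()], with its own
#' rate, applied after fragment shortening (emulating per-base sequencer
#' miscalls).
#'
#' @inheritParams mutate_sequence
#' @return Sequences with errors.
#' @export
add_sequencing_error <- function(sequences, rate) {
  stopifnot(rate >= 0, rate <= 1)
  .substitute_uniform(sequences, rate)
}

# fast random fixed-width oligos
.random_oligos <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a labeled, spatially barcoded 16S read set
#'
#' Species are drawn by abundance among species with a locatable capture
#' site; a probe-anchored fragment is sampled per read (length model, point
#' mutations, then sequencing errors); reads are topped up so every genus
#' appears at least `min_per_genus` times; each read receives a random layout
#' barcode and a random 7-nt UMI.
#'
#' @param refs A `reference_set` from [make_references()] (recorded capture
#'   sites are used when present; otherwise sites are located with
#'   [locate_capture_site()], and species without a site are excluded).
#' @param n_reads Number of reads drawn by abundance (top-up reads for rare
#'   genera are appended, so the output can be slightly larger).
#' @param abundances Named vector of species relative abundances (names =
#'   `species_id`); default uniform. Must sum to 1 over included species.
#' @param model A [length_model()]; default 400 +/- 44 bp trimmed to 150 bp.
#' @param mutation_rate Point-mutation rate before shortening (default 0.001).
#' @param error_rate Sequencing-error rate after shortening (default 0).
#' @param min_per_genus Minimum reads per genus (default 100).
#' @param layout An [array_layout()] supplying spatial barcodes.
#' @param seed Integer seed.
#' @return List of class `readset`: `reads` (tibble: `read_id`, `barcode`,
#'   `umi`, `sequence`, `qualities`, `species_id`, `species`, `genus`,
#'   `ref_id`, `frag_start`, `frag_end`), `abundances`, `excluded_species`.
#' @export
simulate_readset <- function(refs, n_reads, abundances = NULL,
                             model = length_model(),
                             mutation_rate = 0.001, error_rate = 0,
                             min_per_genus = 100L, layout = default_layout(),
                             seed = 1L) {
  rec <- refs$records
  withr::with_seed(seed, {
    if (!("capture_start" %in% names(rec)) || anyNA(rec$capture_start)) {
      sites <- lapply(rec$sequence, locate_capture_site)
      has_site <- !vapply(sites, is.null, logical(1))
      excluded <- rec$species[!has_site]
      rec <- rec[has_site, ]
      rec$capture_start <- vapply(sites[has_site], `[[`, integer(1), "start")
      rec$capture_end <- vapply(sites[has_site], `[[`, integer(1), "end")
    } else excluded <- character(0)
    if (!nrow(rec)) stop("no species with a locatable capture site")
    if (is.null(abundances)) {
      abundances <- setNames(rep(1 / nrow(rec), nrow(rec)),
                             as.character(rec$species_id))
    }
    ab <- abundances[as.character(rec$species_id)]
    ab[is.na(ab)] <- 0
    if (abs(sum(ab) - 1) > 1e-8) {
      stop("abundances must sum to 1 over species with a capture site")
    }
    genera <- unique(rec$genus)
    if (min_per_genus > 0L && n_reads < length(genera) * min_per_genus) {
      stop("n_reads smaller than n_genera * min_per_genus")
    }
    idx <- sample.int(nrow(rec), n_reads, replace = TRUE, prob = ab)
    # top up deficient genera
    if (min_per_genus > 0L) {
      cnt <- table(factor(rec$genus[idx], levels = genera))
      for (g in genera[cnt < min_per_genus]) {
        need <- min_per_genus - cnt[[g]]
        pool <- which(rec$genus == g)
        w <- ab[pool]
        if (sum(w) == 0) w <- rep(1, length(pool))
        idx <- c(idx, sample(pool, need, replace = TRUE, prob = w))
      }
    }
    n <- length(idx)
    site_start <- rec$capture_start[idx]
    span <- site_start - 1L
    L <- pmax(1L, as.integer(round(rnorm(n, model$mean, model$sd))))
    L <- pmin(L, span)                      # clamp to available upstream span
    Lkeep <- pmin(L, model$trim_to)         # keep the end adjacent to the site
    frag_start <- site_start - Lkeep
    frag <- substr(rec$sequence[idx], frag_start, site_start - 1L)
    frag <- mutate_sequence(frag, mutation_rate)
    frag <- add_sequencing_error(frag, error_rate)
    reads <- tibble(
      read_id = sprintf("read_%07d", seq_len(n)),
      barcode = sample(layout$barcode, n, replace = TRUE),
      umi = .random_oligos(n, 7L),
      sequence = frag,
      qualities = strrep("I", nchar(frag)),
      species_id = rec$species_id[idx],
      species = rec$species[idx],
      genus = rec$genus[idx],
      ref_id = rec$species_id[idx],
      frag_start = frag_start,
      frag_end = site_start - 1L
    )
  })
  structure(list(reads = reads, abundances = abundances,
                 excluded_species = excluded, model = model, seed = seed),
            class = "readset")
}

#' @export
print.readset <- function(x, ...) {
  cat("<readset> ", nrow(x$reads), " reads, ",
      length(unique(x$reads$genus)), " genera\n", sep = "")
  invisible(x)
}

#' Write a simulated read set as FASTQ pair plus truth table
#'
#' R1 = barcode + UMI (25 nt), R2 = fragment; the truth TSV maps `read_id`
#' to species/genus and the fragment interval; a JSON manifest records the
#' seed and parameters.
#'
#' @param readset A `readset` from [simulate_readset()].
#' @param r1_path,r2_path,truth_path,manifest_path Output paths
#'   (`manifest_path` optional).
#' @return Invisibly, the paths.
#' @export
write_readset <- function(readset, r1_path, r2_path, truth_path,
                          manifest_path = NULL) {
  write_fastq_pairs(readset$reads, r1_path, r2_path)
  readr::write_tsv(readset$reads[, c("read_id", "species_id", "species",
                                     "genus", "ref_id", "frag_start",
                                     "frag_end")], truth_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(list(seed = readset$seed, model = unclass(readset$model),
                              n_reads = nrow(readset$reads)),
                         manifest_path, auto_unbox = TRUE)
  }
  invisible(list(r1 = r1_path, r2 = r2_path, truth = truth_path))
}
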