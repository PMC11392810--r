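#' Morphological region-of-interest (MROI) tag vocabulary
#'
#' The 16 histology-derived spot annotation tags used for the mouse colon:
#' epithelium (E), epithelium + muscle + submucosa (ALL), epithelium +
#' mucosae + submucosa (EMMSUB), epithelium + mucosae (EMM), muscle +
#' submucosa (MSUB), crypt base (BASE), muscularis externa + interna (MEI),
#' externa (ME), interna (MI), mucosae + interna (MMI), mucosa + pellet
#' (MUPE), crypt mid (MID), crypt apex + mucosa (APEXMU), crypt apex + mid
#' (UPPERMID), Peyer's patch (PP) and pellet (PE).
#'
#' @return Character vector of the 16 tags.
#' @export
mroi_tags <- function() {
  c("E", "ALL", "EMMSUB", "EMM", "MSUB", "BASE", "MEI", "ME",
    "MI", "MMI", "MUPE", "MID", "APEXMU", "UPPERMID", "PP", "PE")
}

# grid constants of the printed capture array: 35 x 33 positions at 200 um
# pitch, 100 um spot diameter
.GRID_NX <- 35L
.GRID_NY <- 33L
.PITCH_UM <- 200
.DIAMETER_UM <- 100

#' Construct a spatial array layout
#'
#' An `array_layout` holds the barcoded capture-spot geometry: one row per
#' printed spot with its 18-nt spatial barcode and 1-based grid coordinates
#' on the 35 x 33 printing frame (200-um pitch, 100-um spots). Grid positions
#' that are part of the frame but not printed are recorded as reserved.
#'
#' @param spots Tibble/data frame with columns `spot_id`, `barcode` (18-nt),
#'   `x` (1..35), `y` (1..33).
#' @param reserved Optional tibble with columns `x`, `y` of unprinted grid
#'   positions.
#' @return An object of class `array_layout`: the spot tibble with a
#'   `reserved` attribute and pitch/diameter constants.
#' @export
array_layout <- function(spots, reserved = NULL) {
  spots <- as_tibble(spots)
  req <- c("spot_id", "barcode", "x", "y")
  if (!all(req %in% names(spots))) {
    stop("layout requires columns: ", paste(req, collapse = ", "))
  }
  spots$x <- as.integer(spots$x)
  spots$y <- as.integer(spots$y)
  bad <- which(spots$x < 1L | spots$x > .GRID_NX | spots$y < 1L | spots$y > .GRID_NY)
  if (length(bad)) {
    stop("spot row ", bad[1], " (spot_id ", spots$spot_id[bad[1]],
         ") lies outside the ", .GRID_NX, "x", .GRID_NY, " grid")
  }
  if (anyDuplicated(spots$barcode)) {
    stop("duplicate barcodes in layout: ",
         paste(unique(spots$barcode[duplicated(spots$barcode)]), collapse = ", "))
  }
  if (any(nchar(spots$barcode) != 18L)) stop("barcodes must be 18 nt")
  if (anyDuplicated(spots[, c("x", "y")])) stop("duplicate grid positions in layout")
  if (is.null(reserved)) reserved <- tibble(x = integer(), y = integer())
  reserved <- as_tibble(reserved)
  if (nrow(spots) + nrow(reserved) > .GRID_NX * .GRID_NY) {
    stop("spots plus reserved positions exceed the ", .GRID_NX * .GRID_NY,
         "-position frame")
  }
  structure(spots,
            reserved = reserved,
            pitch_um = .PITCH_UM,
            diameter_um = .DIAMETER_UM,
            class = c("array_layout", class(spots)))
}

#' @export
print.array_layout <- function(x, ...) {
  cat("<array_layout> ", nrow(x), " spots on a ", .GRID_NX, "x", .GRID_NY,
      " grid (", nrow(attr(x, "reserved")), " reserved positions), pitch ",
      .PITCH_UM, " um\n", sep = "")
  NextMethod()
}

# Deterministic generation of n barcodes of given length; seeded locally so
# the bundled layout is identical across sessions. Greedy rejection keeps the
# bank pairwise Hamming distance > min_sep, the separation demultiplexing at
# two mismatches requires.
.make_barcodes <- function(n, width = 18L, seed = 104729L, min_sep = 4L) {
  withr::with_seed(seed, {
    kept <- matrix(0L, n, width)
    out <- character(n)
    got <- 0L
    bases <- c("A", "C", "G", "T")
    while (got < n) {
      cand <- sample.int(4L, width, replace = TRUE)
      if (got > 0L) {
        d <- rowSums(kept[seq_len(got), , drop = FALSE] !=
                       matrix(cand, got, width, byrow = TRUE))
        if (min(d) <= min_sep) next
      }
      got <- got + 1L
      kept[got, ] <- cand
      out[got] <- paste(bases[cand], collapse = "")
    }
    out
  })
}

#' The bundled default array layout
#'
#' The printing frame has 35 columns and 33 rows (1,155 grid positions) of
#' which 1,007 carry barcoded capture spots. The 148 unprinted positions are
#' fixed deterministically as the outer border ring (132 positions) plus the
#' 4 x 4 interior block at x in 2..5, y in 2..5 (16 positions, a fiducial
#' corner block). Barcodes are generated deterministically and are pairwise
#' well separated (Hamming distance > 4), as required for demultiplexing at
#' up to two mismatches.
#'
#' @return An [array_layout()] with exactly 1,007 spots.
#' @export
default_layout <- function() {
  if (!is.null(.shmseq_cache$default_layout)) return(.shmseq_cache$default_layout)
  grid <- expand.grid(x = seq_len(.GRID_NX), y = seq_len(.GRID_NY))
  border <- grid$x == 1L | grid$x == .GRID_NX | grid$y == 1L | grid$y == .GRID_NY
  corner <- grid$x >= 2L & grid$x <= 5L & grid$y >= 2L & grid$y <= 5L
  reserved <- grid[border | corner, ]
  printed <- grid[!(border | corner), ]
  n <- nrow(printed)
  stopifnot(n == 1007L)
  spots <- tibble(
    spot_id = sprintf("spot_%04d", seq_len(n)),
    barcode = .make_barcodes(n),
    x = as.integer(printed$x),
    y = as.integer(printed$y)
  )
  layout <- array_layout(spots, reserved = as_tibble(reserved))
  .shmseq_cache$default_layout <- layout
  layout
}

#' Read a layout TSV
#'
#' @param path TSV file with columns `spot_id`, `barcode`, `x`, `y`.
#' @return An [array_layout()].
#' @export
load_layout <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    spot_id = readr::col_character(), barcode = readr::col_character(),
    x = readr::col_integer(), y = readr::col_integer()))
  array_layout(df)
}

#' Write a layout TSV
#'
#' @param layout An [array_layout()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(as_tibble(as.data.frame(layout)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTQ reading: R1 = 18-nt spatial barcode + 7-nt UMI, R2 = 16S fragment

#' Read paired spatial FASTQ files
#'
#' R1 carries the 18-nt spatial barcode (positions 1-18) and the 7-nt UMI
#' (positions 19-25); R2 carries the captured 16S fragment. Records must be
#' in matched order. R1 records shorter than 25 nt cannot yield a barcode and
#' UMI; they are counted and skipped.
#'
#' @param r1_path,r2_path FASTQ paths (Sanger quality encoding).
#' @return A tibble with columns `read_id`, `barcode_obs`, `umi`, `sequence`,
#'   `qualities`, carrying an `n_invalid` attribute with the number of
#'   skipped records.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("R1 and R2 record counts differ (", length(r1), " vs ", length(r2), ")")
  }
  ids <- unname(sub("\\s.*$", "", names(r1)))
  s1 <- unname(as.character(r1))
  s2 <- unname(as.character(r2))
  q2 <- unname(as.character(S4Vectors::mcols(r2)$qualities))
  valid <- nchar(s1) >= 25L
  out <- tibble(
    read_id = ids[valid],
    barcode_obs = substr(s1[valid], 1L, 18L),
    umi = substr(s1[valid], 19L, 25L),
    sequence = s2[valid],
    qualities = q2[valid]
  )
  attr(out, "n_invalid") <- sum(!valid)
  out
}

#' Write paired spatial FASTQ files
#'
#' Inverse of [read_fastq_pairs()]: R1 is the barcode followed by the UMI,
#' R2 the fragment sequence. Missing qualities are written as uniform "I"
#' (Phred 40).
#'
#' @param reads Tibble with columns `read_id`, `barcode_obs` (or `barcode`),
#'   `umi`, `sequence` and optionally `qualities`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  bc <- if ("barcode_obs" %in% names(reads)) reads$barcode_obs else reads$barcode
  s1 <- paste0(bc, reads$umi)
  q2 <- if ("qualities" %in% names(reads)) reads$qualities else
    strrep("I", nchar(reads$sequence))
  x1 <- Biostrings::DNAStringSet(s1)
  names(x1) <- reads$read_id
  x2 <- Biostrings::DNAStringSet(reads$sequence)
  names(x2) <- reads$read_id
  Biostrings::writeXStringSet(x1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(strrep("I", nchar(s1))))
  Biostrings::writeXStringSet(x2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(q2))
  invisible(list(r1 = r1_path, r2 = r2_path))
}

# ---------------------------------------------------------------------------
# taxa-by-barcode count matrices

#' Construct a taxa-by-barcode count matrix
#'
#' A plain integer matrix (taxa or genes in rows, spatial barcodes in
#' columns) with validation: nonnegative integer counts and unique labels.
#'
#' @param counts Matrix-like object with row and column names.
#' @return Validated integer matrix of class `taxa_matrix`.
#' @export
taxa_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (length(m) && (is.null(rownames(m)) || is.null(colnames(m)))) {
    stop("taxa_matrix requires row (taxa) and column (barcode) names")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("taxa_matrix labels must be unique")
  }
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(m != round(m))) stop("counts must be integers")
  storage.mode(m) <- "integer"
  class(m) <- c("taxa_matrix", class(m))
  m
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' TSV format: first column `taxon`, remaining columns one per barcode.
#' MTX format: MatrixMarket file plus `<path>.rows` / `<path>.cols` sidecar
#' label files. Round-trips through [read_matrix()] bit-exactly.
#'
#' @param matrix A [taxa_matrix()] or plain named matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- unclass(matrix)
  if (format == "tsv") {
    df <- as.data.frame(m, check.names = FALSE)
    df <- cbind(taxon = rownames(m), df)
    readr::write_tsv(as_tibble(df), path)
  } else {
    sm <- Matrix::Matrix(m, sparse = TRUE)
    Matrix::writeMM(sm, path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read a count matrix written by [write_matrix()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"mtx"`.
#' @return A [taxa_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      taxon = readr::col_character(), .default = readr::col_integer()))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$taxon
    # a header-only file reads back as 0 rows; keep declared columns
  } else {
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    rownames(m) <- readLines(paste0(path, ".rows"))
    colnames(m) <- readLines(paste0(path, ".cols"))
  }
  taxa_matrix(m)
}

# ---------------------------------------------------------------------------
# spot annotations

#' Read a spot annotation TSV
#'
#' Columns: `barcode`, `mroi` (one of [mroi_tags()]), `section_id`,
#' `condition` (SPF/GF/ASF) and `animal_id`. Every annotated barcode must
#' exist in the layout.
#'
#' @param path Annotation TSV path.
#' @param layout Optional [array_layout()] to validate barcodes against.
#' @return Tibble of annotations.
#' @export
load_annotations <- function(path, layout = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_annotations(df, layout)
}

#' Validate a spot annotation table
#'
#' @param annotations Data frame with columns `barcode`, `mroi`,
#'   `section_id`, `condition`, `animal_id`.
#' @param layout Optional [array_layout()]; annotated barcodes must exist in it.
#' @return The validated tibble.
#' @export
validate_annotations <- function(annotations, layout = NULL) {
  df <- as_tibble(annotations)
  req <- c("barcode", "mroi", "section_id", "condition", "animal_id")
  if (!all(req %in% names(df))) {
    stop("annotations require columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(df$mroi), mroi_tags())
  if (length(bad)) stop("unknown MROI tag(s): ", paste(bad, collapse = ", "))
  if (!is.null(layout)) {
    missing <- setdiff(df$barcode, layout$barcode)
    if (length(missing)) {
      stop(length(missing), " annotated barcode(s) absent from layout, e.g. ",
           missing[1])
    }
  }
  df
}
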