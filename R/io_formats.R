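#' @title Genomic interval tables and coordinate conventions
#'
#' @description All intervals inside the package are 0-based, half-open
#' (BED convention). Annotation exports in the wild are frequently
#' 1-based inclusive, so every reader takes a `coord_convention` flag and
#' converts on entry; there is no silent guessing.
#'
#' @name coordinates
#' @keywords internal
NULL

.coord_conventions <- c("bed0", "one_based_inclusive")

gsc_states <- c("constructive", "reactive", "invasive")

element_types <- c("promoter", "enhancer")

# -- interval validation -------------------------------------------------

#' Validate a chrom/start/end interval data frame
#'
#' Checks the internal interval invariants: non-empty chromosome names,
#' integer start >= 0 and end > start (0-based half-open).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly, with start/end as integers.
#' @keywords internal
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(what, ": non-integer start/end coordinates", call. = FALSE)
  }
  if (any(!nzchar(df$chrom)) || any(is.na(df$chrom))) {
    stop(what, ": empty chromosome name", call. = FALSE)
  }
  if (any(df$start < 0L)) {
    stop(what, ": negative start coordinate (internal coordinates are 0-based)",
         call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(what, ": end <= start at row(s) ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Convert external coordinates to the internal convention
#'
#' `bed0` input is already 0-based half-open and passes through unchanged;
#' `one_based_inclusive` input is converted by `start - 1` with `end`
#' unchanged (a 1-based closed interval \[s, e\] equals the 0-based
#' half-open interval \[s-1, e)).
#'
#' @param df data.frame with `start`, `end` columns.
#' @param convention `"bed0"` or `"one_based_inclusive"`.
#' @return `df` in internal coordinates.
#' @export
convert_coords <- function(df, convention = c("bed0", "one_based_inclusive")) {
  convention <- match.arg(convention)
  if (convention == "one_based_inclusive") df$start <- df$start - 1L
  df
}

#' Convert internal coordinates back to an external convention
#'
#' Inverse of [convert_coords()]: round-tripping
#' external -> internal -> external recovers the original values.
#'
#' @inheritParams convert_coords
#' @return `df` in the requested external convention.
#' @export
to_external_coords <- function(df, convention = c("bed0", "one_based_inclusive")) {
  convention <- match.arg(convention)
  if (convention == "one_based_inclusive") df$start <- df$start + 1L
  df
}

# -- PeakCountDataset ----------------------------------------------------

#' Construct a peak-by-cell count dataset
#'
#' Bundles ATAC peaks (intervals), cell barcodes and the sparse
#' peak-by-cell raw count matrix, validating that dimensions agree,
#' counts are non-negative and barcodes are unique.
#'
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`),
#'   internal 0-based half-open coordinates.
#' @param barcodes character vector of unique cell identifiers.
#' @param counts peak x cell matrix of non-negative integer counts
#'   (anything coercible to `Matrix::dgCMatrix`).
#' @return An object of class `peak_count_dataset`: a list with elements
#'   `peaks`, `barcodes`, `counts`.
#' @export
#' @examples
#' peaks <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 900L))
#' counts <- Matrix::Matrix(matrix(0:3, 2, 2), sparse = TRUE)
#' peak_count_dataset(peaks, c("AAAC", "AAAG"), counts)
peak_count_dataset <- function(peaks, barcodes, counts) {
  peaks <- validate_intervals(as.data.frame(peaks), "peaks")
  barcodes <- as.character(barcodes)
  if (anyDuplicated(barcodes)) {
    stop("barcodes are not unique: e.g. ",
         barcodes[duplicated(barcodes)][1], call. = FALSE)
  }
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (nrow(counts) != nrow(peaks)) {
    stop("count matrix has ", nrow(counts), " rows but ", nrow(peaks),
         " peaks", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("count matrix has ", ncol(counts), " columns but ",
         length(barcodes), " barcodes", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  colnames(counts) <- barcodes
  structure(list(peaks = peaks, barcodes = barcodes, counts = counts),
            class = "peak_count_dataset")
}

#' @exportS3Method base::print
print.peak_count_dataset <- function(x, ...) {
  cat("peak_count_dataset: ", nrow(x$peaks), " peaks x ",
      length(x$barcodes), " cells; ",
      format(sum(x$counts), big.mark = ","), " total counts\n", sep = "")
  invisible(x)
}

#' Read a peak/barcode/count scATAC-seq bundle
#'
#' Reads the three files of a GEO-style scATAC deposition: a BED3 peak
#' file (extra columns, e.g. strand, are read and discarded — the
#' downstream midpoint test is strand-agnostic), a plain-text barcode
#' file (one barcode per line) and a MatrixMarket integer triplet count
#' matrix with rows = peaks and columns = cells (`transpose = TRUE` for
#' the opposite orientation).
#'
#' @param peaks_path BED3 file of peak intervals.
#' @param barcodes_path one barcode per line.
#' @param counts_path MatrixMarket (.mtx) file, peaks x cells.
#' @param coord_convention coordinate convention of the BED file;
#'   `"bed0"` (default, standard BED) or `"one_based_inclusive"`.
#' @param transpose set `TRUE` if the matrix is stored cells x peaks.
#' @return A validated [peak_count_dataset()].
#' @export
read_peak_count_bundle <- function(peaks_path, barcodes_path, counts_path,
                                   coord_convention = c("bed0", "one_based_inclusive"),
                                   transpose = FALSE) {
  coord_convention <- match.arg(coord_convention)
  peaks <- read.table(peaks_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  if (ncol(peaks) < 3) {
    stop("peak file ", peaks_path, " is not BED3 (needs >= 3 columns)",
         call. = FALSE)
  }
  peaks <- peaks[, 1:3]
  names(peaks) <- c("chrom", "start", "end")
  peaks <- convert_coords(peaks, coord_convention)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  counts <- Matrix::readMM(counts_path)
  if (transpose) counts <- Matrix::t(counts)
  if (nrow(counts) != nrow(peaks)) {
    stop("count matrix ", counts_path, " has ", nrow(counts),
         " rows but peak file ", peaks_path, " has ", nrow(peaks),
         " peaks", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("count matrix ", counts_path, " has ", ncol(counts),
         " columns but barcode file ", barcodes_path, " has ",
         length(barcodes), " barcodes", call. = FALSE)
  }
  peak_count_dataset(peaks, barcodes, counts)
}

#' Write a peak/barcode/count bundle to a directory
#'
#' Inverse of [read_peak_count_bundle()]; always writes internal (bed0)
#' coordinates.
#'
#' @param dataset a [peak_count_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written (peaks.bed, barcodes.txt, counts.mtx).
#' @export
write_peak_count_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "peak_count_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("peaks.bed", "barcodes.txt", "counts.mtx"))
  write.table(dataset$peaks, paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(dataset$barcodes, paths[2])
  Matrix::writeMM(dataset$counts, paths[3])
  invisible(paths)
}

# -- GeneRegionTable -----------------------------------------------------

#' Construct/validate a gene region table
#'
#' One row per regulatory element: the gene it is associated with, the
#' element's interval, whether it is a promoter or an enhancer, and a
#' non-negative gene-association score quantifying the strength of the
#' gene-element functional link (GeneHancer-style).
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `element_type`, `association_score` (internal coordinates).
#' @return The validated data.frame with class `gene_region_table`.
#' @export
gene_region_table <- function(df) {
  req <- c("gene_id", "chrom", "start", "end", "element_type",
           "association_score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("gene region table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, req]
  df$gene_id <- as.character(df$gene_id)
  df <- validate_intervals(df, "gene regions")
  bad <- which(!df$element_type %in% element_types)
  if (length(bad)) {
    stop("invalid element_type ", sQuote(df$element_type[bad[1]]),
         " at row ", bad[1], " (must be promoter or enhancer)",
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$association_score))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad)) {
    stop("non-numeric association_score at row ", bad[1], call. = FALSE)
  }
  if (any(score < 0)) {
    stop("negative association_score at row ", which(score < 0)[1],
         call. = FALSE)
  }
  df$association_score <- score
  key <- do.call(paste, c(df[c("gene_id", "chrom", "start", "end",
                               "element_type")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate gene region rows: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("gene_region_table", "data.frame")
  df
}

#' Read a gene region annotation table
#'
#' TSV with header `gene_id, chrom, start, end, element_type,
#' association_score`. `element_type` must be `promoter` or `enhancer`;
#' association scores must be non-negative numbers.
#'
#' @param path TSV file.
#' @inheritParams read_peak_count_bundle
#' @return A validated [gene_region_table()] in internal coordinates.
#' @export
read_gene_regions <- function(path,
                              coord_convention = c("bed0", "one_based_inclusive")) {
  coord_convention <- match.arg(coord_convention)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_region_table(convert_coords(df, coord_convention))
}

#' Write a gene region table (internal/bed0 coordinates)
#' @param regions a [gene_region_table()].
#' @param path output TSV path.
#' @export
write_gene_regions <- function(regions, path) {
  write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# -- StateSignatureTable -------------------------------------------------

#' Read a cell-state signature gene table
#'
#' TSV with header `state, gene_id`, one row per signature gene per
#' state; duplicate (state, gene) pairs are rejected.
#'
#' @param path TSV file.
#' @return data.frame with columns `state`, `gene_id`.
#' @export
read_state_signatures <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  state_signature_table(df)
}

#' Validate a state signature table
#' @param df data.frame with columns `state`, `gene_id`.
#' @return validated data.frame.
#' @export
state_signature_table <- function(df) {
  stopifnot(all(c("state", "gene_id") %in% names(df)))
  df <- as.data.frame(df)[, c("state", "gene_id")]
  df$state <- as.character(df$state)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df)) {
    stop("duplicate (state, gene_id) pairs in signature table", call. = FALSE)
  }
  df
}

#' Write a state signature table
#' @param signatures data.frame with `state`, `gene_id`.
#' @param path output TSV path.
#' @export
write_state_signatures <- function(signatures, path) {
  write.table(signatures, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- GscRegionTable ------------------------------------------------------

#' Read GSC-state discriminating regions
#'
#' BED3 plus a fourth column naming the glioma stem-cell functional state
#' each region discriminates: one of `constructive`, `reactive`,
#' `invasive`.
#'
#' @param path BED file with a 4th state column.
#' @inheritParams read_peak_count_bundle
#' @return data.frame `chrom`, `start`, `end`, `gsc_state` (internal
#'   coordinates), class `gsc_region_table`.
#' @export
read_gsc_regions <- function(path,
                             coord_convention = c("bed0", "one_based_inclusive")) {
  coord_convention <- match.arg(coord_convention)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop("GSC region file ", path, " needs 4 columns (chrom, start, end, state)",
         call. = FALSE)
  }
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gsc_state")
  gsc_region_table(convert_coords(df, coord_convention))
}

#' Validate a GSC region table
#' @param df data.frame `chrom`, `start`, `end`, `gsc_state`.
#' @return validated data.frame with class `gsc_region_table`.
#' @export
gsc_region_table <- function(df) {
  df <- validate_intervals(as.data.frame(df), "GSC regions")
  bad <- which(!df$gsc_state %in% gsc_states)
  if (length(bad)) {
    stop("invalid gsc_state ", sQuote(df$gsc_state[bad[1]]), " at row ",
         bad[1], " (must be one of ", paste(gsc_states, collapse = ", "),
         ")", call. = FALSE)
  }
  class(df) <- c("gsc_region_table", "data.frame")
  df
}

#' Write GSC regions as BED + state column
#' @param regions a [gsc_region_table()].
#' @param path output path.
#' @export
write_gsc_regions <- function(regions, path) {
  write.table(as.data.frame(regions)[, c("chrom", "start", "end", "gsc_state")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# -- scores --------------------------------------------------------------

#' Write a per-cell stemness result table
#'
#' TSV with columns `barcode, raw_score, norm_score, stemness_class` and,
#' when present, `neftel_state` and `gsc_state`. Floats are written at
#' full precision so the table round-trips losslessly through
#' [read_scores()].
#'
#' @param result a `stemness_result` data.frame (see [stemness_result()]).
#' @param path output TSV path.
#' @export
write_scores <- function(result, path) {
  stopifnot(inherits(result, "data.frame"))
  req <- c("barcode", "raw_score", "norm_score", "stemness_class")
  stopifnot(all(req %in% names(result)))
  cols <- c(req, intersect(c("neftel_state", "gsc_state"), names(result)))
  out <- as.data.frame(result)[, cols, drop = FALSE]
  for (col in c("raw_score", "norm_score")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stemness score table written by [write_scores()]
#' @param path TSV path.
#' @return a `stemness_result` data.frame.
#' @export
read_scores <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(barcode = "character"))
  df$raw_score <- as.numeric(df$raw_score)
  df$norm_score <- as.numeric(df$norm_score)
  class(df) <- c("stemness_result", "data.frame")
  df
}

# -- gene importance table i/o ------------------------------------------

#' Write a gene importance table
#' @param table data.frame from [run_consensus()] (possibly several
#'   learners' rows bound together).
#' @param path output TSV path.
#' @export
write_importance_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene importance table
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `learner`, `vote_count`,
#'   `mean_importance`, `selected`.
#' @export
read_importance_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$selected <- as.logical(df$selected)
  df
}
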