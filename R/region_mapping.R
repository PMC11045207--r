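#' Midpoint of a genomic interval
#'
#' Floor of `(start + end) / 2` in internal 0-based coordinates. For a
#' half-open interval the midpoint always lies inside the interval.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return integer vector of midpoint positions.
#' @export
#' @examples
#' midpoint(100, 200)  # 150
#' midpoint(100, 201)  # 150 (floor)
midpoint <- function(start, end) {
  stopifnot(all(end > start))
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Map promoter/enhancer regions to ATAC peaks by the midpoint test
#'
#' A region is linked to a peak iff they are on the same chromosome and
#' the region's midpoint `m` satisfies `peak.start <= m < peak.end`.
#' Strand plays no role. When peaks overlap, every peak containing the
#' midpoint is recorded. Overlap search is delegated to
#' `GenomicRanges::findOverlaps()` on width-1 midpoint ranges.
#'
#' @param regions a [gene_region_table()].
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`),
#'   internal coordinates — typically `dataset$peaks`.
#' @return A `region_peak_map`: data.frame with columns `gene_id`,
#'   `region_index` (row in `regions`), `peak_index` (row in `peaks`).
#' @export
map_regions_to_peaks <- function(regions, peaks) {
  peaks <- validate_intervals(as.data.frame(peaks), "peaks")
  regions <- as.data.frame(regions)
  mids <- midpoint(regions$start, regions$end)
  # internal 0-based position m -> 1-based width-1 range [m+1, m+1]
  mid_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = mids + 1L, width = 1L))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hits <- GenomicRanges::findOverlaps(mid_gr, peak_gr, type = "within")
  map <- data.frame(
    gene_id = regions$gene_id[S4Vectors::queryHits(hits)],
    region_index = S4Vectors::queryHits(hits),
    peak_index = S4Vectors::subjectHits(hits),
    stringsAsFactors = FALSE)
  map <- map[order(map$region_index, map$peak_index), , drop = FALSE]
  rownames(map) <- NULL
  if (nrow(map) == 0L) {
    warning("no region midpoint falls inside any peak", call. = FALSE)
  }
  class(map) <- c("region_peak_map", "data.frame")
  map
}

#' Aggregate peak counts into a gene-by-cell accessibility matrix
#'
#' For each gene, the raw accessibility of a cell is the sum of that
#' cell's counts over the distinct peaks mapped to the gene. A peak
#' reached through several regions of the same gene (e.g. its promoter
#' and an enhancer both having midpoints in one broad peak) is counted
#' once. Genes in `gene_set` with no mapped peak get an all-zero row
#' with a warning.
#'
#' @param map a `region_peak_map` from [map_regions_to_peaks()].
#' @param dataset a [peak_count_dataset()].
#' @param gene_set character vector of genes to aggregate; defaults to
#'   all genes present in `map`.
#' @return A [gene_cell_matrix()] at stage `"raw"`.
#' @export
aggregate_gene_counts <- function(map, dataset, gene_set = NULL) {
  stopifnot(inherits(dataset, "peak_count_dataset"))
  if (is.null(gene_set)) gene_set <- sort(unique(map$gene_id))
  gene_set <- as.character(gene_set)
  stopifnot(!anyDuplicated(gene_set))
  sub <- map[map$gene_id %in% gene_set, c("gene_id", "peak_index")]
  sub <- unique(sub)  # de-duplicate shared peaks within a gene
  unmapped <- setdiff(gene_set, sub$gene_id)
  if (length(unmapped)) {
    warning(length(unmapped), " gene(s) have no mapped peak and get zero rows: ",
            paste(head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  n_genes <- length(gene_set)
  gi <- match(sub$gene_id, gene_set)
  # genes x peaks membership indicator, then one sparse product
  memb <- Matrix::sparseMatrix(i = gi, j = sub$peak_index, x = 1,
                               dims = c(n_genes, nrow(dataset$counts)))
  values <- as.matrix(memb %*% dataset$counts)
  dimnames(values) <- list(gene_set, dataset$barcodes)
  gene_cell_matrix(values, stage = "raw")
}

#' Gene-by-cell accessibility matrix with a processing stage
#'
#' A dense numeric matrix (genes in rows, cells in columns) tagged with
#' the processing stage it has reached: `raw` (aggregated counts),
#' `filtered` (after [zscore_filter()]) or `logged` (after
#' [log_transform()]). Stages only ever advance raw -> filtered -> logged
#' and all values are non-negative at every stage.
#'
#' @param values numeric matrix with gene rownames and barcode colnames.
#' @param stage one of `"raw"`, `"filtered"`, `"logged"`.
#' @return the matrix with class `gene_cell_matrix` and a `stage`
#'   attribute.
#' @export
gene_cell_matrix <- function(values, stage = c("raw", "filtered", "logged")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative accessibility values", call. = FALSE)
  structure(values, stage = stage, class = c("gene_cell_matrix", "matrix",
                                             "array"))
}

#' @exportS3Method base::print
print.gene_cell_matrix <- function(x, ...) {
  cat("gene_cell_matrix [", attr(x, "stage"), "]: ", nrow(x), " genes x ",
      ncol(x), " cells\n", sep = "")
  invisible(x)
}

matrix_stage <- function(x) attr(x, "stage")

#' Zero out lowly accessible cells per gene (z-score filter)
#'
#' For each gene row, values are standardized across cells (mean `mu`,
#' standard deviation `sigma` with denominator `n - 1`) and entries with
#' `(x - mu) / sigma < z_cutoff` are set to zero. The default cutoff of
#' -1 zeroes cells lying below mu - 1*sigma, so lowly accessible genes
#' contribute nothing to the downstream score. Constant rows
#' (`sigma = 0`) are left unchanged. With `filter_axis = "cell"` the
#' standardization instead runs within each cell across genes.
#'
#' @param matrix a raw-stage [gene_cell_matrix()] with at least 2 cells.
#' @param z_cutoff z-score threshold below which values are zeroed
#'   (default -1; `-Inf` disables filtering).
#' @param filter_axis `"gene"` (default: standardize each gene across
#'   cells) or `"cell"`.
#' @return A [gene_cell_matrix()] at stage `"filtered"`.
#' @export
zscore_filter <- function(matrix, z_cutoff = -1, filter_axis = c("gene", "cell")) {
  filter_axis <- match.arg(filter_axis)
  stopifnot(inherits(matrix, "gene_cell_matrix"))
  if (matrix_stage(matrix) != "raw") {
    stop("zscore_filter expects a raw-stage matrix, got stage ",
         sQuote(matrix_stage(matrix)), call. = FALSE)
  }
  if (ncol(matrix) < 2L) stop("z-score filter needs >= 2 cells", call. = FALSE)
  x <- unclass(matrix)
  attr(x, "stage") <- NULL
  if (filter_axis == "cell") {
    x <- t(.zero_below(t(x), z_cutoff))
  } else {
    x <- .zero_below(x, z_cutoff)
  }
  gene_cell_matrix(x, stage = "filtered")
}

# rowwise: zero entries with (x - mean) / sd < cutoff; sd denominator n-1
.zero_below <- function(x, cutoff) {
  mu <- rowMeans(x)
  sigma <- apply(x, 1L, sd)
  keep_row <- sigma == 0 | !is.finite(sigma)
  z <- (x - mu) / sigma
  mask <- !keep_row & (z < cutoff)
  mask[is.na(mask)] <- FALSE
  x[mask] <- 0
  x
}

#' Mean gene-association power over a gene's mapped regions
#'
#' The gene-association score differs between a gene's promoter and each
#' of its enhancers; the per-gene association power is the mean of the
#' scores over the (region, peak) records of [map_regions_to_peaks()],
#' so a region mapping into two overlapping peaks contributes twice.
#' Genes with no mapped record are dropped with a warning.
#'
#' @param regions the [gene_region_table()] used to build `map`.
#' @param map a `region_peak_map`.
#' @return named numeric vector: gene_id -> mean association score.
#' @export
average_association <- function(regions, map) {
  regions <- as.data.frame(regions)
  if (nrow(map) == 0L) {
    warning("empty region-peak map: no association power defined",
            call. = FALSE)
    return(setNames(numeric(0), character(0)))
  }
  score <- regions$association_score[map$region_index]
  out <- tapply(score, map$gene_id, mean)
  setNames(as.numeric(out), names(out))[sort(names(out))]
}

#' log2(x + 1) transform of a filtered accessibility matrix
#'
#' @param matrix a filtered-stage [gene_cell_matrix()].
#' @return A [gene_cell_matrix()] at stage `"logged"`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "gene_cell_matrix"))
  if (matrix_stage(matrix) != "filtered") {
    stop("log_transform expects a filtered-stage matrix, got stage ",
         sQuote(matrix_stage(matrix)), call. = FALSE)
  }
  x <- unclass(matrix)
  attr(x, "stage") <- NULL
  gene_cell_matrix(log2(x + 1), stage = "logged")
}
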