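#' Build per-gene score weights from importance and association power
#'
#' The weight of gene *i* is the product of two factors: one derived
#' from its machine-learning importance and one from its mean
#' gene-association power. In the default `"scale"` mode each factor is
#' standardized across the scored gene set (centered, divided by the
#' sd with denominator n-1, i.e. `scale()`), making the two scales
#' commensurable; centered factors can be negative, and two negative
#' factors multiply to a positive weight, so the count of negative final
#' weights is reported. In `"minmax"` mode each factor is instead
#' rescaled to \[0, 1\] (`(x - min) / (max - min)`), which preserves the
#' ranking of both factors and guarantees non-negative weights.
#'
#' @param importance named numeric vector of per-gene importance (e.g.
#'   combined weights from [combine_models()]).
#' @param association named numeric vector of per-gene association power
#'   from [average_association()].
#' @param gene_set genes to score; must have at least 2 elements, all
#'   present in both vectors.
#' @param mode `"scale"` (centered standardization, default) or
#'   `"minmax"`.
#' @return data.frame with columns `gene_id`, `importance_std`,
#'   `association_std`, `weight`, class `gene_weights`.
#' @export
compute_weights <- function(importance, association, gene_set,
                            mode = c("scale", "minmax")) {
  mode <- match.arg(mode)
  gene_set <- as.character(gene_set)
  if (length(gene_set) < 2L) {
    stop("weight standardization needs >= 2 genes", call. = FALSE)
  }
  missing_imp <- setdiff(gene_set, names(importance))
  missing_assoc <- setdiff(gene_set, names(association))
  if (length(missing_imp) || length(missing_assoc)) {
    stop("genes missing from importance (",
         paste(head(missing_imp, 5), collapse = ", "),
         ") or association (", paste(head(missing_assoc, 5), collapse = ", "),
         ")", call. = FALSE)
  }
  imp <- importance[gene_set]
  assoc <- association[gene_set]
  std <- function(v, label) {
    if (sd(v) == 0) {
      stop("zero variance in ", label, " across the scored gene set: ",
           "standardization is undefined (all values ", v[1], ")",
           call. = FALSE)
    }
    if (mode == "scale") (v - mean(v)) / sd(v)
    else (v - min(v)) / (max(v) - min(v))
  }
  out <- data.frame(
    gene_id = gene_set,
    importance_std = unname(std(imp, "gene importance")),
    association_std = unname(std(assoc, "association power")),
    stringsAsFactors = FALSE)
  out$weight <- out$importance_std * out$association_std
  n_neg <- sum(out$weight < 0)
  if (n_neg > 0) {
    message(n_neg, " of ", nrow(out), " gene weights are negative")
  }
  class(out) <- c("gene_weights", "data.frame")
  out
}

#' Raw chromatin stemness score: weighted sum over scored genes
#'
#' The raw score of cell *c* is the inner product of the gene weights
#' with the cell's log-transformed gene accessibilities,
#' `sum_i w_i * x_ic` over the scored gene set.
#'
#' @param weights a `gene_weights` data.frame from [compute_weights()].
#' @param matrix a logged-stage [gene_cell_matrix()] whose rows cover the
#'   weighted gene set.
#' @return named numeric vector of raw scores, one per cell.
#' @export
raw_scores <- function(weights, matrix) {
  stopifnot(inherits(matrix, "gene_cell_matrix"))
  if (matrix_stage(matrix) != "logged") {
    stop("raw_scores expects a logged-stage matrix, got stage ",
         sQuote(matrix_stage(matrix)), call. = FALSE)
  }
  missing_genes <- setdiff(weights$gene_id, rownames(matrix))
  if (length(missing_genes)) {
    stop("gene(s) absent from the accessibility matrix: ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  x <- unclass(matrix)[weights$gene_id, , drop = FALSE]
  drop(crossprod(x, weights$weight))[colnames(matrix)]
}

#' Min-max normalize raw scores to \[0, 1\]
#'
#' `(x - min) / (max - min)`. When all raw scores are equal the range is
#' degenerate; all cells get 0 with a warning.
#'
#' @param raw numeric vector of raw scores (length >= 1).
#' @return numeric vector in \[0, 1\], same names as `raw`.
#' @export
minmax_normalize <- function(raw) {
  stopifnot(length(raw) >= 1L, is.numeric(raw))
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw scores equal (", rng[1],
            "): degenerate range, normalized scores set to 0", call. = FALSE)
    return(setNames(rep(0, length(raw)), names(raw)))
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Classify cells as low/high stemness at a score cutoff
#'
#' A cell is `high` iff its normalized score is strictly greater than
#' the cutoff; a score exactly at the cutoff is `low`.
#'
#' @param norm numeric vector of normalized scores in \[0, 1\].
#' @param cutoff classification threshold (default 0.5).
#' @return character vector of `"low"` / `"high"`, names preserved.
#' @export
classify_stemness <- function(norm, cutoff = 0.5) {
  stopifnot(all(norm >= 0 & norm <= 1))
  setNames(ifelse(norm > cutoff, "high", "low"), names(norm))
}

#' Assemble a per-cell stemness result table
#'
#' @param barcodes cell identifiers.
#' @param raw_score raw weighted-sum scores.
#' @param norm_score min-max normalized scores in \[0, 1\].
#' @param stemness_class `"low"` / `"high"` per cell.
#' @param neftel_state,gsc_state optional state labels (`NA` where
#'   unassigned).
#' @return data.frame with class `stemness_result`.
#' @export
stemness_result <- function(barcodes, raw_score, norm_score, stemness_class,
                            neftel_state = NULL, gsc_state = NULL) {
  n <- length(barcodes)
  stopifnot(length(raw_score) == n, length(norm_score) == n,
            length(stemness_class) == n,
            all(norm_score >= 0 & norm_score <= 1),
            all(stemness_class %in% c("low", "high")))
  df <- data.frame(barcode = as.character(barcodes),
                   raw_score = as.numeric(raw_score),
                   norm_score = as.numeric(norm_score),
                   stemness_class = as.character(stemness_class),
                   stringsAsFactors = FALSE)
  if (!is.null(neftel_state)) {
    stopifnot(length(neftel_state) == n)
    df$neftel_state <- as.character(neftel_state)
  }
  if (!is.null(gsc_state)) {
    stopifnot(length(gsc_state) == n)
    stopifnot(all(is.na(gsc_state) | gsc_state %in% gsc_states))
    df$gsc_state <- as.character(gsc_state)
  }
  class(df) <- c("stemness_result", "data.frame")
  df
}

#' Score cells end to end from weights and a peak-count dataset
#'
#' Convenience wrapper chaining [map_regions_to_peaks()],
#' [aggregate_gene_counts()], [zscore_filter()], [log_transform()],
#' [average_association()], [compute_weights()], [raw_scores()],
#' [minmax_normalize()] and [classify_stemness()]. Genes in
#' `gene_importance` that have no mapped peak are dropped from the
#' scored set with a warning (both weight factors require mapped peaks).
#'
#' @param dataset a [peak_count_dataset()].
#' @param regions a [gene_region_table()].
#' @param gene_importance named numeric vector: consensus genes ->
#'   combined importance (see [combine_models()]).
#' @param z_cutoff z-score filtering threshold, see [zscore_filter()].
#' @param cutoff low/high classification threshold on the normalized
#'   score.
#' @param weight_mode `"scale"` or `"minmax"`, see [compute_weights()].
#' @return A [stemness_result()] for every cell in `dataset`, with the
#'   `gene_weights` table attached as attribute `"weights"`.
#' @export
score_stemness <- function(dataset, regions, gene_importance,
                           z_cutoff = -1, cutoff = 0.5,
                           weight_mode = c("scale", "minmax")) {
  weight_mode <- match.arg(weight_mode)
  genes <- names(gene_importance)
  stopifnot(length(genes) > 0)
  reg_sub <- regions[regions$gene_id %in% genes, , drop = FALSE]
  map <- map_regions_to_peaks(reg_sub, dataset$peaks)
  mapped_genes <- sort(unique(map$gene_id))
  dropped <- setdiff(genes, mapped_genes)
  if (length(dropped)) {
    warning(length(dropped), " consensus gene(s) have no mapped peak ",
            "and are dropped from the score: ",
            paste(head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  if (length(mapped_genes) < 2L) {
    stop("fewer than 2 consensus genes map to peaks; score undefined",
         call. = FALSE)
  }
  gcm <- aggregate_gene_counts(map, dataset, mapped_genes)
  gcm <- log_transform(zscore_filter(gcm, z_cutoff = z_cutoff))
  assoc <- average_association(reg_sub, map)
  weights <- compute_weights(gene_importance[mapped_genes], assoc,
                             mapped_genes, mode = weight_mode)
  raw <- raw_scores(weights, gcm)
  norm <- minmax_normalize(raw)
  res <- stemness_result(dataset$barcodes, raw, norm,
                         classify_stemness(norm, cutoff))
  attr(res, "weights") <- weights
  res
}
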