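#' Signature-gene accessibility matrix for one cellular state
#'
#' Restricts the gene-region table to one state's signature genes
#' (promoter regions by default), maps those regions to peaks by the
#' midpoint test, aggregates counts per gene and cell, and returns the
#' log2(x+1)-transformed matrix. No z-score filter is applied here —
#' state labeling works on the plain logged accessibilities.
#'
#' @param signatures state signature table (`state`, `gene_id`).
#' @param regions a [gene_region_table()].
#' @param dataset a [peak_count_dataset()].
#' @param state the state whose signature to use.
#' @param elements which element types to use: `"promoter"` (default)
#'   or both `c("promoter", "enhancer")`.
#' @return A logged-stage [gene_cell_matrix()] (signature genes with at
#'   least one mapped peak x all cells).
#' @export
signature_accessibility <- function(signatures, regions, dataset, state,
                                    elements = "promoter") {
  stopifnot(all(elements %in% element_types))
  sig_genes <- signatures$gene_id[signatures$state == state]
  if (length(sig_genes) == 0L) {
    stop("state ", sQuote(state), " absent from the signature table",
         call. = FALSE)
  }
  reg_sub <- regions[regions$gene_id %in% sig_genes &
                       regions$element_type %in% elements, , drop = FALSE]
  map <- if (nrow(reg_sub)) {
    suppressWarnings(map_regions_to_peaks(reg_sub, dataset$peaks))
  } else {
    data.frame(gene_id = character(0), region_index = integer(0),
               peak_index = integer(0))
  }
  mapped <- sort(unique(map$gene_id))
  if (length(mapped) == 0L) {
    stop("no signature gene of state ", sQuote(state),
         " maps to any peak; genes: ",
         paste(head(sig_genes, 10), collapse = ", "), call. = FALSE)
  }
  gcm <- aggregate_gene_counts(map, dataset, mapped)
  # skip the z-filter: promote raw -> filtered unchanged, then log
  log_transform(gene_cell_matrix(unclass(gcm), stage = "filtered"))
}

#' Hierarchically cluster cells on a signature accessibility matrix
#'
#' Agglomerative clustering of the cells (columns), cut at `k`
#' clusters. Defaults are Ward linkage on Euclidean distances — the
#' usual convention of clustered heatmaps. Deterministic for fixed
#' input.
#'
#' @param matrix a [gene_cell_matrix()].
#' @param k number of clusters (2 <= k <= n_cells).
#' @param linkage_method linkage passed to [stats::hclust()]
#'   (`"ward.D2"` is Ward on Euclidean distances).
#' @param distance_metric metric passed to [stats::dist()].
#' @return list of class `cluster_result`: `cluster_id` (named integer
#'   per cell, in 1..k), `k`, `linkage_method`, `distance_metric`.
#' @export
cluster_cells <- function(matrix, k, linkage_method = "ward.D2",
                          distance_metric = "euclidean") {
  stopifnot(inherits(matrix, "gene_cell_matrix"), k >= 2L)
  if (k > ncol(matrix)) {
    stop("k = ", k, " exceeds the number of cells (", ncol(matrix), ")",
         call. = FALSE)
  }
  d <- dist(t(unclass(matrix)), method = distance_metric)
  hc <- hclust(d, method = linkage_method)
  cl <- cutree(hc, k = k)
  structure(list(cluster_id = cl, k = as.integer(k),
                 linkage_method = linkage_method,
                 distance_metric = distance_metric),
            class = "cluster_result")
}

#' Flag the cells of the highest-accessibility cluster as a state's cells
#'
#' Operationalizes "cells with high chromatin accessibility at the
#' state's marker genes": the cluster with the highest mean logged
#' accessibility (over genes and member cells) is flagged as belonging
#' to the state; ties go to the smaller cluster id.
#'
#' @param clusters a `cluster_result` from [cluster_cells()].
#' @param matrix the [gene_cell_matrix()] the clustering was computed
#'   on.
#' @return logical vector per cell (`TRUE` = member of the flagged
#'   cluster), with attributes `"flagged_cluster"` and
#'   `"cluster_means"`.
#' @export
assign_neftel_state <- function(clusters, matrix) {
  stopifnot(inherits(clusters, "cluster_result"),
            identical(names(clusters$cluster_id), colnames(matrix)))
  means <- vapply(seq_len(clusters$k), function(cl) {
    mean(unclass(matrix)[, clusters$cluster_id == cl, drop = FALSE])
  }, numeric(1))
  flagged <- which.max(means)  # ties -> smallest index
  out <- clusters$cluster_id == flagged
  attr(out, "flagged_cluster") <- flagged
  attr(out, "cluster_means") <- means
  out
}

#' Label every cell with its cellular state from signature accessibility
#'
#' Runs [signature_accessibility()], [cluster_cells()] and
#' [assign_neftel_state()] once per state in the signature table. A cell
#' flagged by several states receives the state under which its own mean
#' signature accessibility is largest; a cell flagged by none stays
#' `NA`.
#'
#' @inheritParams signature_accessibility
#' @param k number of clusters per state (chosen by the user, e.g. from
#'   heatmap inspection or [suggest_k()]).
#' @param linkage_method,distance_metric see [cluster_cells()].
#' @return named character vector: barcode -> state or `NA`.
#' @export
label_neftel_states <- function(signatures, regions, dataset, k,
                                elements = "promoter",
                                linkage_method = "ward.D2",
                                distance_metric = "euclidean") {
  states <- sort(unique(signatures$state))
  flags <- matrix(FALSE, length(dataset$barcodes), length(states),
                  dimnames = list(dataset$barcodes, states))
  strength <- matrix(-Inf, length(dataset$barcodes), length(states),
                     dimnames = list(dataset$barcodes, states))
  for (st in states) {
    gcm <- signature_accessibility(signatures, regions, dataset, st,
                                   elements = elements)
    cl <- cluster_cells(gcm, k = k, linkage_method = linkage_method,
                        distance_metric = distance_metric)
    flags[, st] <- assign_neftel_state(cl, gcm)
    strength[, st] <- colMeans(unclass(gcm))
  }
  out <- rep(NA_character_, nrow(flags))
  names(out) <- rownames(flags)
  any_flag <- rowSums(flags) > 0
  if (any(any_flag)) {
    masked <- strength
    masked[!flags] <- -Inf
    out[any_flag] <- states[max.col(masked[any_flag, , drop = FALSE],
                                    ties.method = "first")]
  }
  out
}

#' Suggest a cluster count by mean silhouette width
#'
#' Scans candidate `k` values and returns the one maximizing the mean
#' silhouette width of the Ward/Euclidean clustering — a starting point
#' only; `k` remains a user decision.
#'
#' @param matrix a [gene_cell_matrix()].
#' @param k_range candidate cluster counts.
#' @return the suggested `k`, with the per-k mean silhouette widths as
#'   attribute `"widths"`.
#' @export
suggest_k <- function(matrix, k_range = 2:6) {
  x <- t(unclass(matrix))
  d <- as.matrix(dist(x))
  widths <- vapply(k_range, function(k) {
    cl <- cutree(hclust(dist(x), method = "ward.D2"), k = k)
    mean(.silhouette_widths(d, cl))
  }, numeric(1))
  out <- k_range[which.max(widths)]
  attr(out, "widths") <- setNames(widths, k_range)
  out
}

.silhouette_widths <- function(dmat, cl) {
  n <- length(cl)
  vapply(seq_len(n), function(i) {
    own <- cl[i]
    a_idx <- which(cl == own)
    a_idx <- a_idx[a_idx != i]
    if (!length(a_idx)) return(0)
    a <- mean(dmat[i, a_idx])
    b <- min(vapply(setdiff(unique(cl), own), function(g) {
      mean(dmat[i, cl == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Assign high-stemness cells to a GSC functional state
#'
#' Cells below the stemness cutoff stay unassigned. For the remaining
#' cells, the per-state signal is the sum of counts over the peaks whose
#' midpoint falls inside any of that state's discriminating regions,
#' divided by the state's region count; the cell is assigned the argmax
#' state, and exact ties leave it unassigned with a warning.
#'
#' @param dataset a [peak_count_dataset()].
#' @param gsc_regions a [gsc_region_table()] with at least one region
#'   per state present.
#' @param stemness a [stemness_result()] covering the dataset's cells.
#' @param cutoff minimum normalized stemness score for assignment
#'   (default 0.5).
#' @param signal how the per-state signal is normalized:
#'   `"per_region_mean"` (default, sum / number of state regions),
#'   `"total_sum"`, or `"per_base_mean"` (sum / total state region
#'   length).
#' @return named character vector: barcode -> GSC state or `NA`.
#' @export
assign_gsc_state <- function(dataset, gsc_regions, stemness, cutoff = 0.5,
                             signal = c("per_region_mean", "total_sum",
                                        "per_base_mean")) {
  signal <- match.arg(signal)
  stopifnot(inherits(dataset, "peak_count_dataset"),
            inherits(gsc_regions, "gsc_region_table"))
  norm <- setNames(stemness$norm_score, stemness$barcode)[dataset$barcodes]
  if (any(is.na(norm))) {
    stop("stemness result does not cover all dataset barcodes", call. = FALSE)
  }
  peaks <- dataset$peaks
  peak_mids <- midpoint(peaks$start, peaks$end)
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(peak_mids + 1L,
                                                    width = 1L))
  states <- sort(unique(gsc_regions$gsc_state))
  sig <- matrix(0, length(dataset$barcodes), length(states),
                dimnames = list(dataset$barcodes, states))
  for (st in states) {
    reg <- gsc_regions[gsc_regions$gsc_state == st, , drop = FALSE]
    reg_gr <- GenomicRanges::GRanges(reg$chrom,
                                     IRanges::IRanges(reg$start + 1L,
                                                      reg$end))
    in_state <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(mid_gr, reg_gr, type = "within")))
    total <- if (length(in_state)) {
      Matrix::colSums(dataset$counts[in_state, , drop = FALSE])
    } else {
      numeric(length(dataset$barcodes))
    }
    denom <- switch(signal,
                    per_region_mean = nrow(reg),
                    total_sum = 1,
                    per_base_mean = sum(reg$end - reg$start))
    sig[, st] <- total / denom
  }
  eligible <- norm >= cutoff
  out <- rep(NA_character_, length(norm))
  names(out) <- dataset$barcodes
  if (any(eligible)) {
    sub <- sig[eligible, , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    top <- sub[cbind(seq_len(nrow(sub)), best)]
    tied <- rowSums(sub == top) > 1L
    lab <- states[best]
    lab[tied] <- NA_character_
    if (any(tied)) {
      warning(sum(tied), " cell(s) with tied GSC signal left unassigned",
              call. = FALSE)
    }
    out[eligible] <- lab
  }
  out
}

#' Summarize normalized stemness scores per state group
#'
#' One row per combination of GSC state and cellular state (including
#' the unassigned `NA` levels observed in the data), with the group
#' size and the mean/median/min/max of the normalized score. Groups with
#' no cells get `n = 0` and `NA` statistics.
#'
#' @param stemness a [stemness_result()] whose `neftel_state` /
#'   `gsc_state` columns are populated (see [stemness_result()]).
#' @return data.frame `gsc_state`, `neftel_state`, `n`, `mean`,
#'   `median`, `min`, `max`.
#' @export
summarize_groups <- function(stemness) {
  stopifnot(inherits(stemness, "data.frame"),
            all(c("norm_score", "neftel_state", "gsc_state") %in%
                  names(stemness)))
  gsc_levels <- sort(unique(stemness$gsc_state), na.last = TRUE)
  nef_levels <- sort(unique(stemness$neftel_state), na.last = TRUE)
  grid <- expand.grid(gsc_state = gsc_levels, neftel_state = nef_levels,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  stats <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- (stemness$gsc_state %in% grid$gsc_state[i] |
              (is.na(grid$gsc_state[i]) & is.na(stemness$gsc_state))) &
      (stemness$neftel_state %in% grid$neftel_state[i] |
         (is.na(grid$neftel_state[i]) & is.na(stemness$neftel_state)))
    s <- stemness$norm_score[sel]
    if (length(s) == 0L) {
      data.frame(n = 0L, mean = NA_real_, median = NA_real_,
                 min = NA_real_, max = NA_real_)
    } else {
      data.frame(n = length(s), mean = mean(s), median = median(s),
                 min = min(s), max = max(s))
    }
  })
  out <- cbind(grid, do.call(rbind, stats))
  rownames(out) <- NULL
  out
}
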