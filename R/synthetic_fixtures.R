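#' Simulation settings for the synthetic pipeline inputs
#'
#' Declares the conditions a synthetic experiment is generated under.
#' Both modalities use negative-binomial count noise with a common
#' dispersion; informative genes carry a `fold_effect` mean shift in one
#' designated scRNA-seq state, and in the scATAC-seq bundle the planted
#' stem-like cells carry the same fold shift at peaks of informative
#' genes. Baseline means are shared across genes/peaks so that noise
#' genes are exchangeable and a shuffled-label control is a genuine
#' null.
#'
#' @param n_states number of scRNA-seq cell states (>= 2; 4 states get
#'   the neural-lineage names qNSC, aNSC_low, aNSC_high, NPC).
#' @param cells_per_state scRNA-seq cells per state.
#' @param n_genes total genes.
#' @param n_informative_genes genes carrying planted state signal
#'   (<= `n_genes`).
#' @param fold_effect multiplicative mean shift of informative genes
#'   (>= 1; 1 means no signal).
#' @param n_peaks total ATAC peaks (>= one per gene region).
#' @param n_atac_cells cells in the scATAC-seq bundle.
#' @param stem_fraction fraction of ATAC cells planted as stem-like
#'   (in (0, 1)).
#' @param noise_dispersion negative-binomial size parameter (> 0;
#'   smaller = noisier).
#' @param base_mean_rna baseline scRNA-seq mean count per gene.
#' @param base_mean_atac baseline scATAC-seq mean count per peak.
#' @param seed integer seed; all generator stages derive their seeds
#'   from it.
#' @return validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_states = 4L, cells_per_state = 100L,
                            n_genes = 500L, n_informative_genes = 20L,
                            fold_effect = 8, n_peaks = 5000L,
                            n_atac_cells = 1000L, stem_fraction = 0.2,
                            noise_dispersion = 2, base_mean_rna = 5,
                            base_mean_atac = 0.5, seed = 1L) {
  spec <- list(n_states = as.integer(n_states),
               cells_per_state = as.integer(cells_per_state),
               n_genes = as.integer(n_genes),
               n_informative_genes = as.integer(n_informative_genes),
               fold_effect = fold_effect, n_peaks = as.integer(n_peaks),
               n_atac_cells = as.integer(n_atac_cells),
               stem_fraction = stem_fraction,
               noise_dispersion = noise_dispersion,
               base_mean_rna = base_mean_rna,
               base_mean_atac = base_mean_atac, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_states >= 2L, cells_per_state >= 2L, n_genes >= 1L,
              n_atac_cells >= 2L, n_peaks >= 1L,
              fold_effect >= 1, noise_dispersion > 0,
              stem_fraction > 0, stem_fraction < 1,
              base_mean_rna > 0, base_mean_atac > 0)
  })
  if (spec$n_informative_genes > spec$n_genes) {
    stop("n_informative_genes (", spec$n_informative_genes,
         ") exceeds n_genes (", spec$n_genes, ")", call. = FALSE)
  }
  class(spec) <- "simulation_spec"
  spec
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

sim_state_names <- function(n_states) {
  if (n_states == 4L) c("qNSC", "aNSC_low", "aNSC_high", "NPC")
  else sprintf("state%02d", seq_len(n_states))
}

#' Simulate a labeled scRNA-seq expression matrix
#'
#' Counts are negative-binomial with a common baseline mean; the
#' `n_informative_genes` informative genes have their mean multiplied by
#' `fold_effect` in exactly one designated state (the last one), making
#' them the ground-truth marker genes a selection method should recover.
#' Deterministic given the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `expression` (genes x cells integer matrix),
#'   `labels` (character per cell) and `truth` (list:
#'   `informative_gene_ids`, `boosted_state`, `true_state_per_cell`).
#' @export
simulate_scrnaseq <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  states <- sim_state_names(spec$n_states)
  boosted <- states[spec$n_states]
  genes <- sim_gene_ids(spec$n_genes)
  informative <- genes[seq_len(spec$n_informative_genes)]
  n_cells <- spec$n_states * spec$cells_per_state
  cells <- sprintf("RNA_%05d", seq_len(n_cells))
  labels <- rep(states, each = spec$cells_per_state)
  mu <- matrix(spec$base_mean_rna, spec$n_genes, n_cells,
               dimnames = list(genes, cells))
  mu[informative, labels == boosted] <-
    mu[informative, labels == boosted] * spec$fold_effect
  expression <- with_local_seed(derive_seed(spec$seed, 1L), {
    matrix(rnbinom(length(mu), mu = as.vector(mu),
                   size = spec$noise_dispersion),
           nrow = spec$n_genes, dimnames = dimnames(mu))
  })
  list(expression = expression, labels = setNames(labels, cells),
       truth = list(informative_gene_ids = informative,
                    boosted_state = boosted,
                    true_state_per_cell = setNames(labels, cells)))
}

#' Simulate promoter/enhancer regions with association scores
#'
#' Each gene receives one promoter (width 500-2000 bp) and 0-3 enhancers
#' (width 200-1500 bp), placed uniformly on a small synthetic genome;
#' association scores are gamma-distributed (shape 2, scale 5, mean 10),
#' emulating the right-skew of gene-element association scores in
#' annotation databases. Deterministic given `seed`.
#'
#' @param gene_ids unique gene identifiers.
#' @param genome_sizes named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @return a [gene_region_table()] in internal coordinates.
#' @export
simulate_gene_regions <- function(gene_ids,
                                  genome_sizes = c(chr1 = 2e8, chr2 = 1.5e8,
                                                   chr3 = 1e8),
                                  seed = 1L) {
  stopifnot(!anyDuplicated(gene_ids), all(genome_sizes > 1e4))
  with_local_seed(seed, {
    rows <- lapply(gene_ids, function(g) {
      n_enh <- sample(0:3, 1L)
      widths <- c(sample(500:2000, 1L),
                  if (n_enh > 0) sample(200:1500, n_enh, replace = TRUE))
      chrom <- sample(names(genome_sizes), n_enh + 1L, replace = TRUE)
      start <- vapply(seq_along(widths), function(i) {
        sample.int(as.integer(genome_sizes[chrom[i]]) - widths[i], 1L) - 1L
      }, integer(1))
      data.frame(gene_id = g, chrom = chrom, start = start,
                 end = start + widths,
                 element_type = c("promoter",
                                  rep("enhancer", n_enh)),
                 association_score = rgamma(n_enh + 1L, shape = 2,
                                            scale = 5),
                 stringsAsFactors = FALSE)
    })
    gene_region_table(do.call(rbind, rows))
  })
}

#' Simulate a scATAC-seq peak/barcode/count bundle with planted stem cells
#'
#' One peak is generated around every gene region so that the region's
#' midpoint is guaranteed to fall inside it; the remaining peaks (up to
#' `n_peaks`) are decoys placed so that they contain no region midpoint.
#' Counts are negative-binomial around a common baseline mean; a random
#' `stem_fraction` of cells is flagged stem-like and receives a
#' `fold_effect` mean shift at the peaks of informative genes —
#' operationalizing the premise that stemness manifests as elevated
#' accessibility at state-predictive genes. Deterministic given the
#' spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @param gene_regions a [gene_region_table()] (non-empty).
#' @param informative_gene_ids genes whose peaks carry the stem signal.
#' @return list with `dataset` (a [peak_count_dataset()]) and `truth`
#'   (list: `stem_cell_barcodes`, `informative_peak_indices`,
#'   `region_peak_indices` — the generated peak of each region row).
#' @export
simulate_scatac_bundle <- function(spec, gene_regions, informative_gene_ids) {
  stopifnot(inherits(spec, "simulation_spec"), nrow(gene_regions) >= 1L)
  regions <- as.data.frame(gene_regions)
  n_region_peaks <- nrow(regions)
  if (spec$n_peaks < n_region_peaks) {
    stop("n_peaks (", spec$n_peaks, ") is smaller than the number of gene ",
         "regions (", n_region_peaks, ")", call. = FALSE)
  }
  mids <- midpoint(regions$start, regions$end)
  with_local_seed(derive_seed(spec$seed, 2L), {
    width <- sample(400:1000, n_region_peaks, replace = TRUE)
    offset <- vapply(width, function(w) sample.int(w, 1L) - 1L, integer(1))
    start <- pmax(0L, mids - offset)
    region_peaks <- data.frame(chrom = regions$chrom, start = start,
                               end = start + width,
                               stringsAsFactors = FALSE)
    n_decoys <- spec$n_peaks - n_region_peaks
    decoys <- .sample_decoy_peaks(n_decoys, regions, mids)
    peaks <- rbind(region_peaks, decoys)
    n_cells <- spec$n_atac_cells
    barcodes <- sprintf("CELL_%05d", seq_len(n_cells))
    n_stem <- max(1L, floor(spec$stem_fraction * n_cells))
    stem <- sort(sample(barcodes, n_stem))
    informative_peaks <-
      which(regions$gene_id %in% informative_gene_ids)
    mu <- matrix(spec$base_mean_atac, nrow(peaks), n_cells)
    mu[informative_peaks, barcodes %in% stem] <-
      mu[informative_peaks, barcodes %in% stem] * spec$fold_effect
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = spec$noise_dispersion),
                     nrow = nrow(peaks))
    dataset <- peak_count_dataset(peaks, barcodes,
                                  Matrix::Matrix(counts, sparse = TRUE))
    list(dataset = dataset,
         truth = list(stem_cell_barcodes = stem,
                      informative_peak_indices = informative_peaks,
                      region_peak_indices = seq_len(n_region_peaks)))
  })
}

# decoy peaks must contain no region midpoint, so downstream mapping
# touches only the constructed region peaks
.sample_decoy_peaks <- function(n, regions, mids) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  chroms <- sort(unique(regions$chrom))
  span <- vapply(chroms, function(ch) {
    max(regions$end[regions$chrom == ch]) + 1e6
  }, numeric(1))
  mid_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(mids + 1L, width = 1L))
  out <- NULL
  need <- n
  for (attempt in 1:50) {
    chrom <- sample(chroms, need, replace = TRUE)
    width <- sample(300:900, need, replace = TRUE)
    start <- vapply(seq_len(need), function(i) {
      sample.int(as.integer(span[chrom[i]]), 1L) - 1L
    }, integer(1))
    cand <- data.frame(chrom = chrom, start = start, end = start + width,
                       stringsAsFactors = FALSE)
    cand_gr <- GenomicRanges::GRanges(cand$chrom,
                                      IRanges::IRanges(cand$start + 1L,
                                                       cand$end))
    clean <- !(seq_len(need) %in%
                 S4Vectors::subjectHits(
                   GenomicRanges::findOverlaps(mid_gr, cand_gr)))
    out <- rbind(out, cand[clean, , drop = FALSE])
    need <- n - nrow(out)
    if (need == 0L) break
  }
  if (need > 0L) {
    stop("could not place ", need, " decoy peaks clear of region midpoints",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate six-state signature gene lists
#'
#' Emulates glioblastoma cellular-state marker lists (NPC-like 1/2,
#' OPC-like, AC-like, MES-like 1/2). The MES-like 2 list is exactly the
#' planted informative genes — the state whose accessibility signal the
#' stem-like cells carry — while the other five states draw disjoint
#' random samples of non-informative genes.
#'
#' @param gene_ids all gene identifiers.
#' @param informative_gene_ids the planted informative genes.
#' @param genes_per_state signature length for the five null states;
#'   default 20, shrunk to a fifth of the non-informative gene pool for
#'   small simulations.
#' @param seed integer seed.
#' @return data.frame `state`, `gene_id` (a state signature table).
#' @export
simulate_state_signatures <- function(gene_ids, informative_gene_ids,
                                      genes_per_state = NULL, seed = 1L) {
  states <- c("NPC1", "NPC2", "OPC", "AC", "MES1")
  pool <- setdiff(gene_ids, informative_gene_ids)
  if (is.null(genes_per_state)) {
    genes_per_state <- max(1L, min(20L, length(pool) %/% length(states)))
  }
  stopifnot(length(pool) >= genes_per_state * length(states))
  with_local_seed(seed, {
    picks <- sample(pool, genes_per_state * length(states))
    df <- data.frame(
      state = rep(states, each = genes_per_state),
      gene_id = picks, stringsAsFactors = FALSE)
    rbind(df, data.frame(state = "MES2", gene_id = informative_gene_ids,
                         stringsAsFactors = FALSE))
  })
}

#' Simulate GSC-state discriminating regions
#'
#' The `constructive` state's regions are copies of informative-gene
#' peaks (so planted stem-like cells show the highest constructive
#' signal), while `reactive` and `invasive` regions are copies of decoy
#' peaks carrying baseline counts only.
#'
#' @param dataset the [peak_count_dataset()] from
#'   [simulate_scatac_bundle()].
#' @param truth the matching ground-truth list.
#' @param regions_per_state regions per GSC state.
#' @param seed integer seed.
#' @return a [gsc_region_table()].
#' @export
simulate_gsc_regions <- function(dataset, truth, regions_per_state = 20L,
                                 seed = 1L) {
  peaks <- dataset$peaks
  informative <- truth$informative_peak_indices
  decoys <- setdiff(seq_len(nrow(peaks)),
                    seq_len(max(truth$region_peak_indices)))
  stopifnot(length(informative) >= 1L,
            length(decoys) >= 2L * regions_per_state)
  with_local_seed(seed, {
    cons <- sample(informative, min(regions_per_state, length(informative)))
    others <- sample(decoys, 2L * regions_per_state)
    df <- rbind(
      cbind(peaks[cons, , drop = FALSE], gsc_state = "constructive"),
      cbind(peaks[others[seq_len(regions_per_state)], , drop = FALSE],
            gsc_state = "reactive"),
      cbind(peaks[others[regions_per_state + seq_len(regions_per_state)], ,
                  drop = FALSE], gsc_state = "invasive"))
    rownames(df) <- NULL
    gsc_region_table(df)
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates every pipeline input under one spec and writes them as the
#' plain-text formats the readers expect: `peaks.bed`, `barcodes.txt`,
#' `counts.mtx`, `regions.tsv`, `signatures.tsv`, `gsc_regions.bed`,
#' `expression.tsv`, `labels.tsv` and the ground truth (`truth.tsv`:
#' per-cell stem flag; `informative_genes.txt`).
#'
#' @param dir output directory (created).
#' @param spec a [simulation_spec()].
#' @return Invisibly, a list with the in-memory objects (`rna`,
#'   `regions`, `atac`, `signatures`, `gsc_regions`) and `paths`.
#' @export
write_simulation_bundle <- function(dir, spec = simulation_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rna <- simulate_scrnaseq(spec)
  regions <- simulate_gene_regions(rownames(rna$expression),
                                   seed = derive_seed(spec$seed, 3L))
  atac <- simulate_scatac_bundle(spec, regions,
                                 rna$truth$informative_gene_ids)
  signatures <- simulate_state_signatures(rownames(rna$expression),
                                          rna$truth$informative_gene_ids,
                                          seed = derive_seed(spec$seed, 4L))
  gsc <- simulate_gsc_regions(atac$dataset, atac$truth,
                              seed = derive_seed(spec$seed, 5L))
  paths <- list(
    peaks = file.path(dir, "peaks.bed"),
    barcodes = file.path(dir, "barcodes.txt"),
    counts = file.path(dir, "counts.mtx"),
    regions = file.path(dir, "regions.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    gsc_regions = file.path(dir, "gsc_regions.bed"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.tsv"),
    informative_genes = file.path(dir, "informative_genes.txt"))
  write_peak_count_bundle(atac$dataset, dir)
  write_gene_regions(regions, paths$regions)
  write_state_signatures(signatures, paths$signatures)
  write_gsc_regions(gsc, paths$gsc_regions)
  write.table(data.frame(gene_id = rownames(rna$expression),
                         rna$expression, check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = colnames(rna$expression),
                         label = unname(rna$labels)),
              paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(
    barcode = atac$dataset$barcodes,
    is_stem = atac$dataset$barcodes %in% atac$truth$stem_cell_barcodes),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(rna$truth$informative_gene_ids, paths$informative_genes)
  invisible(list(rna = rna, regions = regions, atac = atac,
                 signatures = signatures, gsc_regions = gsc, paths = paths))
}

#' Read a genes-x-cells expression TSV written by
#' [write_simulation_bundle()]
#'
#' @param expression_path TSV with a `gene_id` column followed by one
#'   column per cell.
#' @param labels_path TSV with columns `cell_id`, `label`.
#' @return list with `expression` matrix and `labels` named character
#'   vector, aligned.
#' @export
read_expression_bundle <- function(expression_path, labels_path) {
  df <- read.table(expression_path, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  lab <- read.table(labels_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  labels <- setNames(as.character(lab$label), lab$cell_id)
  if (!identical(sort(colnames(mat)), sort(names(labels)))) {
    stop("expression columns and label cell_ids disagree", call. = FALSE)
  }
  list(expression = mat, labels = labels[colnames(mat)])
}
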