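# planted two-population dataset: `hot` cells have boosted counts at the
# peaks of one state's signature genes
planted_state_data <- function(n_cells = 60, hot_frac = 0.3, fold = 8,
                               seed = 2) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:12)
  regions <- gene_region_table(data.frame(
    gene_id = genes, chrom = "chr1",
    start = seq(0L, by = 2000L, length.out = 12),
    end = seq(0L, by = 2000L, length.out = 12) + 1000L,
    element_type = "promoter",
    association_score = runif(12, 5, 15), stringsAsFactors = FALSE))
  peaks <- data.frame(chrom = "chr1", start = regions$start,
                      end = regions$end)
  sig <- data.frame(state = rep(c("MES2", "AC"), each = 6),
                    gene_id = genes, stringsAsFactors = FALSE)
  hot <- seq_len(round(hot_frac * n_cells))
  mu <- matrix(1, 12, n_cells)
  mu[1:6, hot] <- fold  # MES2 gene peaks boosted in hot cells
  counts <- matrix(rnbinom(12 * n_cells, mu = mu, size = 5), 12, n_cells)
  ds <- peak_count_dataset(peaks, sprintf("BC%03d", 1:n_cells),
                           Matrix::Matrix(counts, sparse = TRUE))
  list(dataset = ds, regions = regions, signatures = sig,
       hot = sprintf("BC%03d", hot))
}

test_that("signature accessibility equals the composed map-aggregate-log chain", {
  d <- planted_state_data()
  gcm <- signature_accessibility(d$signatures, d$regions, d$dataset, "MES2")
  expect_equal(attr(gcm, "stage"), "logged")
  sig_genes <- d$signatures$gene_id[d$signatures$state == "MES2"]
  reg <- d$regions[d$regions$gene_id %in% sig_genes &
                     d$regions$element_type == "promoter", ]
  map <- map_regions_to_peaks(reg, d$dataset$peaks)
  manual <- log2(oracle_aggregate(map, d$dataset$counts,
                                  sort(unique(map$gene_id))) + 1)
  expect_equal(unclass(gcm), manual, ignore_attr = "stage")
})

test_that("unknown states and unmappable signatures fail loudly", {
  d <- planted_state_data()
  expect_error(signature_accessibility(d$signatures, d$regions, d$dataset,
                                       "OPC"), "absent")
  far <- d$regions
  far$start <- far$start + 10000000L
  far$end <- far$end + 10000000L
  expect_error(
    suppressWarnings(signature_accessibility(d$signatures, far, d$dataset,
                                             "MES2")), "maps to any peak")
})

test_that("hierarchical clustering recovers planted blobs and handles edge k", {
  set.seed(8)
  genes <- c("gA", "gB")
  x <- cbind(matrix(rnorm(20, 0, 0.1), 2, 10),
             matrix(rnorm(20, 5, 0.1), 2, 10))
  dimnames(x) <- list(genes, sprintf("c%02d", 1:20))
  gcm <- gene_cell_matrix(abs(x), stage = "logged")
  cl <- cluster_cells(gcm, k = 2)
  expect_length(unique(cl$cluster_id[1:10]), 1)
  expect_length(unique(cl$cluster_id[11:20]), 1)
  expect_false(cl$cluster_id[1] == cl$cluster_id[11])
  # duplicate columns always co-cluster
  dup <- gene_cell_matrix(gcm[, c(1, 1, 2, 11, 12, 11), drop = FALSE],
                          stage = "logged")
  colnames(dup) <- paste0("d", 1:6)
  cl2 <- cluster_cells(gene_cell_matrix(unclass(dup), "logged"), k = 2)
  expect_equal(cl2$cluster_id[["d1"]], cl2$cluster_id[["d2"]])
  expect_equal(cl2$cluster_id[["d4"]], cl2$cluster_id[["d6"]])
  # k = n_cells gives singletons; k > n_cells is an error
  singles <- cluster_cells(gcm, k = 20)
  expect_length(unique(singles$cluster_id), 20)
  expect_error(cluster_cells(gcm, k = 21), "exceeds")
})

test_that("the highest-mean cluster is flagged, ties to the smaller id", {
  x <- gene_cell_matrix(
    matrix(c(0.2, 0.2, 3.1, 3.1, 0.4, 0.4), 1,
           dimnames = list("g", paste0("c", 1:6))), "logged")
  cl <- structure(list(cluster_id = setNames(c(1L, 1L, 2L, 2L, 3L, 3L),
                                             paste0("c", 1:6)),
                       k = 3L, linkage_method = "ward.D2",
                       distance_metric = "euclidean"),
                  class = "cluster_result")
  flag <- assign_neftel_state(cl, x)
  expect_equal(attr(flag, "flagged_cluster"), 2L)
  expect_equal(unname(flag), c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
               ignore_attr = TRUE)
  tied <- gene_cell_matrix(
    matrix(rep(c(1, 1, 1), each = 2), 1,
           dimnames = list("g", paste0("c", 1:6))), "logged")
  expect_equal(attr(assign_neftel_state(cl, tied), "flagged_cluster"), 1L)
})

test_that("planted high-accessibility cells are recovered as the hot state", {
  d <- planted_state_data(n_cells = 100, fold = 8)
  labels <- label_neftel_states(d$signatures, d$regions, d$dataset, k = 2)
  called_hot <- names(labels)[!is.na(labels) & labels == "MES2"]
  agreement <- length(intersect(called_hot, d$hot)) /
    length(union(called_hot, d$hot))
  expect_gte(agreement, 0.95)
})

test_that("GSC assignment filters low-stemness cells and takes the argmax state", {
  # worked example: constructive 10 counts / 5 regions = 2,
  # invasive 3/2 = 1.5, reactive 0 -> constructive
  peaks <- data.frame(chrom = "chr1",
                      start = c(100L, 300L, 500L),
                      end = c(200L, 400L, 600L))
  counts <- Matrix::Matrix(matrix(c(10, 3, 0,   # cell 1
                                    10, 3, 0),  # cell 2
                                  nrow = 3), sparse = TRUE)
  ds <- peak_count_dataset(peaks, c("hi", "lo"), counts)
  gsc <- gsc_region_table(data.frame(
    chrom = "chr1",
    start = c(100L, 1000L, 1100L, 1200L, 1300L, 300L, 1400L, 500L),
    end = c(200L, 1010L, 1110L, 1210L, 1310L, 400L, 1410L, 600L),
    gsc_state = c(rep("constructive", 5), rep("invasive", 2), "reactive")))
  res <- stemness_result(c("hi", "lo"), c(1, 0), c(0.9, 0.3),
                         c("high", "low"))
  out <- assign_gsc_state(ds, gsc, res, cutoff = 0.5)
  expect_equal(unname(out), c("constructive", NA))
})

test_that("GSC assignment equals the brute-force oracle on random instances", {
  set.seed(300)
  for (i in 1:30) {
    n_peaks <- sample(10:40, 1)
    n_cells <- sample(2:10, 1)
    ds <- rand_dataset(n_peaks, n_cells)
    gsc <- rand_peaks(sample(6:15, 1))
    gsc$gsc_state <- sample(c("constructive", "reactive", "invasive"),
                            nrow(gsc), replace = TRUE)
    # ensure all three states present
    gsc$gsc_state[1:3] <- c("constructive", "reactive", "invasive")
    gsc <- gsc_region_table(gsc)
    norm <- runif(n_cells)
    res <- stemness_result(ds$barcodes, norm, norm,
                           ifelse(norm > 0.5, "high", "low"))
    got <- suppressWarnings(assign_gsc_state(ds, gsc, res, cutoff = 0.5))
    want <- oracle_gsc(ds$peaks, ds$counts, gsc, norm, 0.5)
    expect_equal(unname(got), want)
  }
})

test_that("no cell below the cutoff ever carries a GSC state", {
  set.seed(17)
  ds <- rand_dataset(30, 20)
  gsc <- rand_peaks(9)
  gsc$gsc_state <- rep(c("constructive", "reactive", "invasive"), 3)
  gsc <- gsc_region_table(gsc)
  norm <- runif(20)
  res <- stemness_result(ds$barcodes, norm, norm,
                         ifelse(norm > 0.5, "high", "low"))
  out <- suppressWarnings(assign_gsc_state(ds, gsc, res, cutoff = 0.5))
  expect_true(all(is.na(out[norm < 0.5])))
})

test_that("group summaries have correct statistics and n = 0 rows", {
  res <- stemness_result(c("a", "b", "c"), c(1, 2, 3), c(0.7, 0.9, 0.2),
                         c("high", "high", "low"),
                         neftel_state = c("MES2", "MES2", "AC"),
                         gsc_state = c("constructive", "constructive", NA))
  summ <- summarize_groups(res)
  row <- summ[!is.na(summ$gsc_state) & summ$gsc_state == "constructive" &
                summ$neftel_state == "MES2", ]
  expect_equal(row$n, 2L)
  expect_equal(row$mean, 0.8)
  expect_equal(row$min, 0.7)
  empty <- summ[!is.na(summ$gsc_state) & summ$gsc_state == "constructive" &
                  summ$neftel_state == "AC", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
  # permutation invariance
  perm <- res[c(3, 1, 2), ]
  expect_equal(summarize_groups(perm), summ)
})
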