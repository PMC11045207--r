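test_that("midpoint uses floor division on half-open intervals", {
  expect_equal(midpoint(100, 200), 150L)
  expect_equal(midpoint(100, 201), 150L)
  expect_equal(midpoint(0, 1), 0L)
})

test_that("midpoint containment respects half-open peak boundaries", {
  regions <- gene_region_table(data.frame(
    gene_id = "g", chrom = "chr1", start = 120L, end = 180L,  # mid 150
    element_type = "promoter", association_score = 1))
  hit_at_start <- data.frame(chrom = "chr1", start = 150L, end = 160L)
  miss_at_end <- data.frame(chrom = "chr1", start = 140L, end = 150L)
  inside <- data.frame(chrom = "chr1", start = 140L, end = 160L)
  expect_equal(map_regions_to_peaks(regions, inside)$peak_index, 1L)
  expect_equal(map_regions_to_peaks(regions, hit_at_start)$peak_index, 1L)
  expect_warning(m <- map_regions_to_peaks(regions, miss_at_end), "no region")
  expect_equal(nrow(m), 0L)
})

test_that("mapping and aggregation match the tiny worked example", {
  map <- map_regions_to_peaks(tiny_regions(), tiny_dataset()$peaks)
  # gA's promoter and enhancer midpoints both fall in peaks 1 and 2
  expect_equal(map$peak_index[map$gene_id == "gA"], c(1L, 2L, 1L, 2L))
  gcm <- aggregate_gene_counts(map, tiny_dataset())
  # shared peaks counted once per gene: 3 + 4 = 7
  expect_equal(unclass(gcm)["gA", ], c(AAA = 7, CCC = 1))
  expect_equal(unclass(gcm)["gB", ], c(AAA = 0, CCC = 2))
  expect_equal(attr(gcm, "stage"), "raw")
})

test_that("genes without mapped peaks get zero rows with a warning", {
  map <- map_regions_to_peaks(tiny_regions(), tiny_dataset()$peaks)
  expect_warning(gcm <- aggregate_gene_counts(map, tiny_dataset(),
                                              c("gA", "gZ")), "gZ")
  expect_equal(unname(unclass(gcm)["gZ", ]), c(0, 0))
})

test_that("mapping and aggregation equal the brute-force oracle on random instances", {
  set.seed(421)
  for (i in 1:30) {
    n_peaks <- sample(20:200, 1)
    n_regions <- sample(5:50, 1)
    n_cells <- sample(2:30, 1)
    ds <- rand_dataset(n_peaks, n_cells)
    regions <- rand_regions(n_regions, sprintf("g%02d", 1:8))
    expected <- oracle_map(as.data.frame(regions), ds$peaks)
    got <- suppressWarnings(map_regions_to_peaks(regions, ds$peaks))
    expect_equal(got$region_index, expected$region_index)
    expect_equal(got$peak_index, expected$peak_index)
    if (nrow(got)) {
      gene_set <- sort(unique(got$gene_id))
      agg <- aggregate_gene_counts(got, ds, gene_set)
      expect_equal(unclass(agg),
                   oracle_aggregate(got, ds$counts, gene_set),
                   ignore_attr = "stage")
    }
  }
})

test_that("z-score filter zeroes sub-threshold cells per gene (sd with n-1)", {
  x <- gene_cell_matrix(matrix(c(1, 10, 10, 10, 10), 1,
                               dimnames = list("g1", paste0("c", 1:5))),
                        stage = "raw")
  # mu = 8.2, sd = 4.0249, z(1) = -1.789 < -1 -> zeroed
  filt <- zscore_filter(x, z_cutoff = -1)
  expect_equal(unname(unclass(filt)[1, ]), c(0, 10, 10, 10, 10))
  expect_equal(attr(filt, "stage"), "filtered")
})

test_that("z-score filter leaves constant rows alone and is a no-op at -Inf", {
  const <- gene_cell_matrix(matrix(5, 1, 3, dimnames = list("g", 1:3)), "raw")
  expect_equal(unname(unclass(zscore_filter(const))[1, ]), c(5, 5, 5))
  set.seed(1)
  x <- gene_cell_matrix(matrix(rpois(50, 4), 5, 10,
                               dimnames = list(paste0("g", 1:5), 1:10)),
                        "raw")
  expect_equal(unclass(zscore_filter(x, z_cutoff = -Inf)), unclass(x),
               ignore_attr = "stage")
  expect_error(zscore_filter(zscore_filter(x)), "raw-stage")
  one_cell <- gene_cell_matrix(matrix(1, 2, 1, dimnames = list(c("a", "b"),
                                                               "c1")), "raw")
  expect_error(zscore_filter(one_cell), ">= 2 cells")
})

test_that("association power is the mean score over mapped records", {
  map <- map_regions_to_peaks(tiny_regions(), tiny_dataset()$peaks)
  ap <- average_association(tiny_regions(), map)
  # gA: promoter 10 and enhancer 20 each map to 2 peaks -> mean 15
  expect_equal(ap[["gA"]], 15)
  expect_equal(ap[["gB"]], 7)
})

test_that("association power equals a brute-force group mean on random instances", {
  set.seed(77)
  for (i in 1:20) {
    ds <- rand_dataset(80, 3)
    regions <- rand_regions(30, sprintf("g%02d", 1:6))
    map <- suppressWarnings(map_regions_to_peaks(regions, ds$peaks))
    if (!nrow(map)) next
    ap <- average_association(regions, map)
    scores <- regions$association_score[map$region_index]
    for (g in names(ap)) {
      expect_equal(ap[[g]], mean(scores[map$gene_id == g]))
    }
  }
})

test_that("log transform is log2(x+1) and only accepts filtered matrices", {
  x <- gene_cell_matrix(matrix(c(0, 1, 7, 3), 2, 2,
                               dimnames = list(c("a", "b"), c("c1", "c2"))),
                        stage = "filtered")
  lg <- log_transform(x)
  expect_equal(unname(unclass(lg)), matrix(c(0, 1, 3, 2), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(lg, "stage"), "logged")
  raw <- gene_cell_matrix(unclass(x), stage = "raw")
  expect_error(log_transform(raw), "filtered-stage")
})

test_that("cell-column permutation permutes outputs identically", {
  set.seed(5)
  ds <- rand_dataset(60, 12)
  regions <- rand_regions(25, sprintf("g%02d", 1:5))
  map <- suppressWarnings(map_regions_to_peaks(regions, ds$peaks))
  expect_gt(nrow(map), 0)
  perm <- sample(length(ds$barcodes))
  ds_perm <- peak_count_dataset(ds$peaks, ds$barcodes[perm],
                                ds$counts[, perm])
  g <- sort(unique(map$gene_id))
  a <- log_transform(zscore_filter(aggregate_gene_counts(map, ds, g)))
  b <- log_transform(zscore_filter(aggregate_gene_counts(map, ds_perm, g)))
  expect_equal(unclass(b), unclass(a)[, perm], ignore_attr = TRUE)
})
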