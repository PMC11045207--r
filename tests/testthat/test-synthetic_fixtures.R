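small_spec <- function(...) {
  args <- modifyList(list(n_states = 4L, cells_per_state = 20L,
                          n_genes = 60L, n_informative_genes = 8L,
                          fold_effect = 8, n_peaks = 400L,
                          n_atac_cells = 80L, stem_fraction = 0.2,
                          seed = 7L), list(...))
  do.call(simulation_spec, args)
}

test_that("infeasible simulation settings are rejected", {
  expect_error(small_spec(n_informative_genes = 100L), "exceeds n_genes")
  expect_error(small_spec(stem_fraction = 0), "stem_fraction")
  expect_error(small_spec(fold_effect = 0.5), "fold_effect")
})

test_that("scRNA-seq simulation is deterministic and plants the stated fold effect", {
  spec <- small_spec(cells_per_state = 50L, fold_effect = 8)
  a <- simulate_scrnaseq(spec)
  b <- simulate_scrnaseq(spec)
  expect_identical(a$expression, b$expression)
  inf <- a$truth$informative_gene_ids
  boosted <- a$labels == a$truth$boosted_state
  ratio <- mean(a$expression[inf, boosted]) / mean(a$expression[inf, !boosted])
  # sample mean ratio close to the planted fold effect
  expect_gt(ratio, 6)
  expect_lt(ratio, 10)
  # and informative means exceed every other state's mean
  for (st in setdiff(unique(a$labels), a$truth$boosted_state)) {
    expect_gt(mean(a$expression[inf, boosted]),
              mean(a$expression[inf, a$labels == st]))
  }
})

test_that("a null simulation (fold_effect = 1) has no differential genes", {
  spec <- small_spec(fold_effect = 1, cells_per_state = 50L)
  sim <- simulate_scrnaseq(spec)
  inf <- sim$truth$informative_gene_ids
  boosted <- sim$labels == sim$truth$boosted_state
  ratio <- mean(sim$expression[inf, boosted]) / mean(sim$expression[inf, !boosted])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("gene regions simulation yields valid, reproducible tables", {
  regions <- simulate_gene_regions(c("gX", "gY"), seed = 3)
  expect_s3_class(regions, "gene_region_table")
  expect_true(all(c("gX", "gY") %in% regions$gene_id))
  # every gene has a promoter
  expect_true(all(tapply(regions$element_type, regions$gene_id,
                         function(e) "promoter" %in% e)))
  expect_identical(regions, simulate_gene_regions(c("gX", "gY"), seed = 3))
  genome <- c(chr1 = 2e8, chr2 = 1.5e8, chr3 = 1e8)
  expect_true(all(regions$end > regions$start))
  expect_true(all(regions$end <= genome[regions$chrom]))
})

test_that("every gene-region peak contains its region's midpoint", {
  spec <- small_spec()
  rna <- simulate_scrnaseq(spec)
  regions <- simulate_gene_regions(rownames(rna$expression), seed = 11)
  atac <- simulate_scatac_bundle(spec, regions, rna$truth$informative_gene_ids)
  peaks <- atac$dataset$peaks
  mids <- midpoint(regions$start, regions$end)
  idx <- atac$truth$region_peak_indices
  expect_equal(length(idx), nrow(regions))
  expect_true(all(peaks$chrom[idx] == regions$chrom))
  expect_true(all(peaks$start[idx] <= mids & mids < peaks$end[idx]))
})

test_that("decoy peaks contain no region midpoint", {
  spec <- small_spec()
  rna <- simulate_scrnaseq(spec)
  regions <- simulate_gene_regions(rownames(rna$expression), seed = 11)
  atac <- simulate_scatac_bundle(spec, regions, rna$truth$informative_gene_ids)
  decoys <- atac$dataset$peaks[-atac$truth$region_peak_indices, ]
  hits <- oracle_map(as.data.frame(regions), decoys)
  expect_equal(nrow(hits), 0L)
})

test_that("stem cells carry the planted fold effect at informative peaks", {
  spec <- small_spec(n_atac_cells = 500L)
  rna <- simulate_scrnaseq(spec)
  regions <- simulate_gene_regions(rownames(rna$expression), seed = 13)
  atac <- simulate_scatac_bundle(spec, regions, rna$truth$informative_gene_ids)
  cnt <- as.matrix(atac$dataset$counts)
  ip <- atac$truth$informative_peak_indices
  stem <- atac$dataset$barcodes %in% atac$truth$stem_cell_barcodes
  ratio <- mean(cnt[ip, stem]) / mean(cnt[ip, !stem])
  expect_gt(ratio, 6.5)
  expect_lt(ratio, 9.5)
  # non-informative region peaks show no stem effect
  np <- setdiff(atac$truth$region_peak_indices, ip)
  ratio0 <- mean(cnt[np, stem]) / mean(cnt[np, !stem])
  expect_gt(ratio0, 0.9)
  expect_lt(ratio0, 1.1)
})

test_that("the written bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  bundle <- write_simulation_bundle(dir, spec)
  ds <- read_peak_count_bundle(file.path(dir, "peaks.bed"),
                               file.path(dir, "barcodes.txt"),
                               file.path(dir, "counts.mtx"))
  expect_equal(ds$peaks, bundle$atac$dataset$peaks)
  expect_equal(as.matrix(ds$counts), as.matrix(bundle$atac$dataset$counts))
  regions <- read_gene_regions(file.path(dir, "regions.tsv"))
  expect_equal(as.data.frame(regions), as.data.frame(bundle$regions))
  rna <- read_expression_bundle(file.path(dir, "expression.tsv"),
                                file.path(dir, "labels.tsv"))
  expect_equal(rna$expression, bundle$rna$expression)
  expect_equal(rna$labels, bundle$rna$labels)
  sig <- read_state_signatures(file.path(dir, "signatures.tsv"))
  expect_equal(sig, bundle$signatures)
  gsc <- read_gsc_regions(file.path(dir, "gsc_regions.bed"))
  expect_equal(as.data.frame(gsc), as.data.frame(bundle$gsc_regions))
})
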