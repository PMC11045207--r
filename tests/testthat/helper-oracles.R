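# Brute-force reference implementations and random-instance builders.
# The oracles deliberately share no code with the package: plain double
# loops over all pairs, naive arithmetic.

# all-pairs midpoint-in-peak scan
oracle_map <- function(regions, peaks) {
  out <- list()
  for (r in seq_len(nrow(regions))) {
    m <- floor((regions$start[r] + regions$end[r]) / 2)
    for (p in seq_len(nrow(peaks))) {
      if (regions$chrom[r] == peaks$chrom[p] &&
          peaks$start[p] <= m && m < peaks$end[p]) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = regions$gene_id[r], region_index = r, peak_index = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), region_index = integer(0),
                      peak_index = integer(0)))
  }
  do.call(rbind, out)
}

# per gene: sum counts over the distinct mapped peaks, cell by cell
oracle_aggregate <- function(map, counts, gene_set) {
  counts <- as.matrix(counts)
  out <- matrix(0, length(gene_set), ncol(counts),
                dimnames = list(gene_set, colnames(counts)))
  for (g in gene_set) {
    peaks <- unique(map$peak_index[map$gene_id == g])
    for (cell in seq_len(ncol(counts))) {
      s <- 0
      for (p in peaks) s <- s + counts[p, cell]
      out[g, cell] <- s
    }
  }
  out
}

# naive standardize-multiply-sum-normalize score
oracle_score <- function(importance, association, genes, logged) {
  std <- function(v) (v - mean(v)) / sd(v)
  w <- std(importance[genes]) * std(association[genes])
  raw <- numeric(ncol(logged))
  for (cell in seq_len(ncol(logged))) {
    s <- 0
    for (i in seq_along(genes)) s <- s + w[i] * logged[genes[i], cell]
    raw[cell] <- s
  }
  norm <- (raw - min(raw)) / (max(raw) - min(raw))
  list(raw = setNames(raw, colnames(logged)),
       norm = setNames(norm, colnames(logged)))
}

# per-state region-normalized signal, argmax; ties/low-score unassigned
oracle_gsc <- function(peaks, counts, gsc_regions, norm_score, cutoff) {
  counts <- as.matrix(counts)
  states <- sort(unique(gsc_regions$gsc_state))
  out <- rep(NA_character_, ncol(counts))
  for (cell in seq_len(ncol(counts))) {
    if (norm_score[cell] < cutoff) next
    sig <- setNames(numeric(length(states)), states)
    for (st in states) {
      reg <- gsc_regions[gsc_regions$gsc_state == st, ]
      total <- 0
      for (p in seq_len(nrow(peaks))) {
        m <- floor((peaks$start[p] + peaks$end[p]) / 2)
        hit <- FALSE
        for (r in seq_len(nrow(reg))) {
          if (reg$chrom[r] == peaks$chrom[p] &&
              reg$start[r] <= m && m < reg$end[r]) hit <- TRUE
        }
        if (hit) total <- total + counts[p, cell]
      }
      sig[st] <- total / nrow(reg)
    }
    best <- which(sig == max(sig))
    if (length(best) == 1L) out[cell] <- states[best]
  }
  out
}

# rank-statistic AUROC (Mann-Whitney form)
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# -- random small instances ---------------------------------------------

rand_peaks <- function(n, chroms = c("chr1", "chr2")) {
  start <- sample.int(10000L, n, replace = TRUE)
  width <- sample(50:400, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width, stringsAsFactors = FALSE)
}

rand_regions <- function(n, genes, chroms = c("chr1", "chr2")) {
  start <- sample.int(10000L, n, replace = TRUE)
  width <- sample(20:300, n, replace = TRUE)
  gene_region_table(data.frame(
    gene_id = sample(genes, n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    element_type = sample(c("promoter", "enhancer"), n, replace = TRUE),
    association_score = round(runif(n, 0, 20), 3),
    stringsAsFactors = FALSE))
}

rand_dataset <- function(n_peaks, n_cells, chroms = c("chr1", "chr2")) {
  counts <- matrix(rpois(n_peaks * n_cells, 1.5), n_peaks, n_cells)
  peak_count_dataset(rand_peaks(n_peaks, chroms),
                     sprintf("BC%03d", seq_len(n_cells)),
                     Matrix::Matrix(counts, sparse = TRUE))
}

# tiny deterministic dataset used across io/mapping tests
tiny_dataset <- function() {
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(100L, 140L, 0L),
                      end = c(200L, 160L, 50L))
  counts <- Matrix::Matrix(matrix(c(3, 4, 0,
                                    1, 0, 2), nrow = 3), sparse = TRUE)
  peak_count_dataset(peaks, c("AAA", "CCC"), counts)
}

tiny_regions <- function() {
  gene_region_table(data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(120L, 100L, 10L),
    end = c(180L, 201L, 30L),
    element_type = c("promoter", "enhancer", "promoter"),
    association_score = c(10, 20, 7),
    stringsAsFactors = FALSE))
}

# shuffle under a fixed seed (label-permutation null)
with_seed_sample <- function(seed, x) {
  set.seed(seed)
  sample(x)
}
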