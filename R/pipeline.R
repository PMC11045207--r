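#' Pipeline configuration
#'
#' Assembles and validates the parameters of a full pipeline run. The
#' defaults encode the reference protocol: 100 repetitions, 50-vote
#' threshold, top-100 per-repetition lists, 70/30 stratified splits,
#' z-score filter cutoff -1 and a 0.5 stemness cutoff.
#'
#' Input paths may be omitted when `simulate = TRUE`, in which case a
#' synthetic bundle is generated under the output directory.
#'
#' @param input_dir directory holding `expression.tsv`, `labels.tsv`,
#'   `peaks.bed`, `barcodes.txt`, `counts.mtx`, `regions.tsv`,
#'   `signatures.tsv`, `gsc_regions.bed` (layout of
#'   [write_simulation_bundle()]).
#' @param simulate generate the inputs synthetically instead of reading
#'   them from `input_dir`.
#' @param models character vector of learners to run
#'   (subset of `rf`, `gb`, `xgb`).
#' @param reps,min_votes,top_k,train_frac consensus protocol, see
#'   [run_consensus()].
#' @param combine_mode `"intersection"` or `"union"`, see
#'   [combine_models()].
#' @param z_cutoff z-score filter threshold, see [zscore_filter()].
#' @param stemness_cutoff low/high classification and GSC filtering
#'   threshold.
#' @param k_clusters cluster count for state labeling.
#' @param weight_mode `"scale"` or `"minmax"`, see [compute_weights()].
#' @param coord_convention coordinate convention of region/peak inputs.
#' @param seed single top-level seed; every stage derives its own seed
#'   from it.
#' @param sim named list of [simulation_spec()] overrides used when
#'   `simulate = TRUE`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = is.null(input_dir),
                            models = c("rf", "gb", "xgb"), reps = 100L,
                            min_votes = 50L, top_k = 100L, train_frac = 0.7,
                            combine_mode = "intersection", z_cutoff = -1,
                            stemness_cutoff = 0.5, k_clusters = 2L,
                            weight_mode = "minmax",
                            coord_convention = "bed0", seed = 1L,
                            sim = list()) {
  cfg <- list(input_dir = input_dir, simulate = isTRUE(simulate),
              models = models, reps = as.integer(reps),
              min_votes = as.integer(min_votes), top_k = as.integer(top_k),
              train_frac = train_frac, combine_mode = combine_mode,
              z_cutoff = z_cutoff, stemness_cutoff = stemness_cutoff,
              k_clusters = as.integer(k_clusters),
              weight_mode = weight_mode,
              coord_convention = coord_convention, seed = as.integer(seed),
              sim = sim)
  .check <- function(ok, field, msg) {
    if (!ok) stop("config field ", sQuote(field), " invalid: ", msg,
                  call. = FALSE)
  }
  .check(all(cfg$models %in% c("rf", "gb", "xgb")) && length(cfg$models) >= 1,
         "models", "must be a non-empty subset of rf, gb, xgb")
  .check(cfg$reps >= 1L, "reps", "must be >= 1")
  .check(cfg$min_votes >= 1L && cfg$min_votes <= cfg$reps, "min_votes",
         paste0("must be in [1, reps] = [1, ", cfg$reps, "]"))
  .check(cfg$top_k >= 1L, "top_k", "must be >= 1")
  .check(cfg$train_frac > 0 && cfg$train_frac < 1, "train_frac",
         "must be in (0, 1)")
  .check(cfg$combine_mode %in% c("intersection", "union"), "combine_mode",
         "must be intersection or union")
  .check(cfg$stemness_cutoff >= 0 && cfg$stemness_cutoff <= 1,
         "stemness_cutoff", "must be in [0, 1]")
  .check(cfg$k_clusters >= 2L, "k_clusters", "must be >= 2")
  .check(cfg$weight_mode %in% c("scale", "minmax"), "weight_mode",
         "must be scale or minmax")
  .check(cfg$coord_convention %in% .coord_conventions, "coord_convention",
         "must be bed0 or one_based_inclusive")
  if (!cfg$simulate) {
    .check(!is.null(cfg$input_dir) && dir.exists(cfg$input_dir), "input_dir",
           "directory does not exist (and simulate is FALSE)")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline config from a flat key = value text file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. `models` takes a comma-separated list; `sim.*` keys override
#' [simulation_spec()] fields (e.g. `sim.n_genes = 200`).
#'
#' @param path config file.
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("config line not of the form key = value: ", sQuote(lines[bad[1]]),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  args <- list()
  sim <- list()
  num_keys <- c("reps", "min_votes", "top_k", "train_frac", "z_cutoff",
                "stemness_cutoff", "k_clusters", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "sim.")) {
      sim[[sub("^sim\\.", "", k)]] <- as.numeric(v)
    } else if (k == "models") {
      args$models <- trimws(strsplit(v, ",")[[1]])
    } else if (k == "simulate") {
      args$simulate <- tolower(v) %in% c("true", "yes", "1")
    } else if (k %in% num_keys) {
      args[[k]] <- as.numeric(v)
    } else {
      args[[k]] <- v
    }
  }
  if (length(sim)) args$sim <- sim
  do.call(pipeline_config, args)
}

#' Run the full stemness pipeline
#'
#' Executes (optionally) simulate -> select-genes -> map-regions ->
#' score -> label-states, writing every artifact plus a JSON run
#' manifest under `out_dir`. All randomness flows through seeds derived
#' from the config's single seed, so rerunning an identical config
#' reproduces byte-identical tables.
#'
#' Artifacts: `importance.tsv` (all learners' consensus tables),
#' `scores.tsv` (per-cell scores + state labels), `group_summary.tsv`,
#' `manifest.json`, and — when simulating — the complete input bundle.
#'
#' @param config a [pipeline_config()] or path to a config file.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with `scores` (the final
#'   [stemness_result()]), `summary`, `consensus`, `manifest`.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("stemscore")),
                   seed = config$seed,
                   parameters = config[c("models", "reps", "min_votes",
                                         "top_k", "train_frac",
                                         "combine_mode", "z_cutoff",
                                         "stemness_cutoff", "k_clusters",
                                         "weight_mode")],
                   stage_seeds = list(), counts = list())

  # -- stage: inputs ----------------------------------------------------
  if (config$simulate) {
    sim_seed <- derive_seed(config$seed, 10L)
    spec <- do.call(simulation_spec, modifyList(config$sim,
                                                list(seed = sim_seed)))
    input_dir <- file.path(out_dir, "input")
    bundle <- write_simulation_bundle(input_dir, spec)
    manifest$stage_seeds$simulate <- sim_seed
  } else {
    input_dir <- config$input_dir
  }
  rna <- read_expression_bundle(file.path(input_dir, "expression.tsv"),
                                file.path(input_dir, "labels.tsv"))
  dataset <- read_peak_count_bundle(file.path(input_dir, "peaks.bed"),
                                    file.path(input_dir, "barcodes.txt"),
                                    file.path(input_dir, "counts.mtx"),
                                    coord_convention = config$coord_convention)
  regions <- read_gene_regions(file.path(input_dir, "regions.tsv"),
                               coord_convention = config$coord_convention)
  signatures <- read_state_signatures(file.path(input_dir, "signatures.tsv"))
  gsc_regions <- read_gsc_regions(file.path(input_dir, "gsc_regions.bed"),
                                  coord_convention = config$coord_convention)
  manifest$counts$genes <- nrow(rna$expression)
  manifest$counts$rna_cells <- ncol(rna$expression)
  manifest$counts$peaks <- nrow(dataset$peaks)
  manifest$counts$atac_cells <- length(dataset$barcodes)

  # -- stage: select-genes ---------------------------------------------
  tables <- list()
  for (m in config$models) {
    m_seed <- derive_seed(config$seed, 20L + match(m, c("rf", "gb", "xgb")))
    manifest$stage_seeds[[paste0("consensus_", m)]] <- m_seed
    tables[[m]] <- run_consensus(rna$expression, rna$labels, learner = m,
                                 n_reps = config$reps, top_k = config$top_k,
                                 min_votes = config$min_votes,
                                 train_frac = config$train_frac,
                                 seed = m_seed)
    message("learner ", m, ": ", sum(tables[[m]]$selected),
            " genes selected; mean held-out accuracy ",
            round(mean(attr(tables[[m]], "accuracy")), 3))
  }
  write_importance_table(do.call(rbind, tables),
                         file.path(out_dir, "importance.tsv"))
  consensus <- combine_models(tables, mode = config$combine_mode)
  manifest$counts$consensus_genes <- length(consensus$genes)
  if (length(consensus$genes) < 2L) {
    stop("pipeline stage score: consensus gene set too small (",
         length(consensus$genes), " genes); scoring is undefined",
         call. = FALSE)
  }

  # -- stage: map-regions + score --------------------------------------
  scores <- score_stemness(dataset, regions, consensus$importance,
                           z_cutoff = config$z_cutoff,
                           cutoff = config$stemness_cutoff,
                           weight_mode = config$weight_mode)
  manifest$counts$scored_genes <- nrow(attr(scores, "weights"))
  manifest$counts$high_stemness_cells <-
    sum(scores$stemness_class == "high")

  # -- stage: label-states ---------------------------------------------
  neftel <- label_neftel_states(signatures, regions, dataset,
                                k = config$k_clusters)
  gsc <- assign_gsc_state(dataset, gsc_regions, scores,
                          cutoff = config$stemness_cutoff)
  scores$neftel_state <- unname(neftel[scores$barcode])
  scores$gsc_state <- unname(gsc[scores$barcode])
  manifest$counts$gsc_assigned_cells <- sum(!is.na(scores$gsc_state))
  write_scores(scores, file.path(out_dir, "scores.tsv"))
  summary <- summarize_groups(scores)
  write.table(summary, file.path(out_dir, "group_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scores = scores, summary = summary,
                 consensus = consensus, manifest = manifest))
}
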