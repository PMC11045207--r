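#' Tree-ensemble learner specifications
#'
#' Three multiclass tree-ensemble learners are supported, each with a
#' fixed hyperparameter preset:
#'
#' * `rf` — random forest (randomForest engine): 500 trees, features
#'   tried per split = floor(sqrt(n_genes)), impurity (Gini) importance.
#' * `gb` — gradient boosting (xgboost engine): 2500 trees, learning
#'   rate 0.001, tree depth 5, minimum of 5 observations in terminal
#'   nodes.
#' * `xgb` — extreme gradient boosting (xgboost engine): 2500 boosting
#'   rounds, maximum depth 15, learning rate 0.01, half of the features
#'   subsampled per tree.
#'
#' Any preset entry can be overridden through `hyperparameters`, e.g.
#' `learner_spec("gb", list(nrounds = 500))` for a faster protocol.
#'
#' @param name one of `"rf"`, `"gb"`, `"xgb"`.
#' @param hyperparameters named list of overrides merged over the
#'   preset.
#' @return list with elements `name` and `hyperparameters`, class
#'   `learner_spec`.
#' @export
learner_spec <- function(name = c("rf", "gb", "xgb"), hyperparameters = list()) {
  name <- match.arg(name)
  presets <- list(
    rf  = list(ntree = 500L),
    gb  = list(nrounds = 2500L, eta = 0.001, max_depth = 5L,
               min_child_weight = 5),
    xgb = list(nrounds = 2500L, eta = 0.01, max_depth = 15L,
               colsample_bytree = 0.5))
  hp <- modifyList(presets[[name]], as.list(hyperparameters))
  structure(list(name = name, hyperparameters = hp), class = "learner_spec")
}

as_learner_spec <- function(x) {
  if (inherits(x, "learner_spec")) x else learner_spec(x)
}

#' Stratified train/test split of labeled cells
#'
#' Cells are split class by class so the class proportions of the full
#' data are preserved in both halves: each class contributes
#' `round(train_frac * class size)` cells to the training set and the
#' remainder to the test set. The split is random but deterministic
#' given `seed`.
#'
#' @param expression genes x cells matrix (used only for dimension
#'   checks; the split acts on columns).
#' @param labels factor/character vector of per-cell class labels,
#'   length `ncol(expression)`; every class needs >= 2 cells.
#' @param train_frac fraction of each class used for training
#'   (default 0.7).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`, disjoint and
#'   jointly exhaustive over `seq_len(ncol(expression))`.
#' @export
stratified_split <- function(expression, labels, train_frac = 0.7, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(ncol(expression) == length(labels),
            train_frac > 0, train_frac < 1)
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("class(es) with < 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  train <- integer(0)
  with_local_seed(seed, {
    for (cls in sort(names(sizes))) {
      idx <- which(labels == cls)
      n_train <- round(train_frac * length(idx))
      n_train <- max(1L, min(length(idx) - 1L, n_train))
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit one learner and rank genes by importance
#'
#' Fits the requested tree-ensemble multiclass classifier on the
#' training cells and returns the `top_k` genes ranked by the learner's
#' native (impurity/gain) feature importance, descending; genes the
#' model never used get importance 0 and ties are broken by gene id in
#' C-locale lexicographic order. Deterministic given `seed`.
#'
#' @param expression genes x cells numeric matrix with gene rownames.
#' @param labels per-cell class labels (>= 2 classes).
#' @param learner a [learner_spec()] or one of `"rf"`, `"gb"`, `"xgb"`.
#' @param top_k number of top genes to return (default all genes).
#' @param seed integer seed.
#' @return data.frame `gene_id`, `importance`, ordered by decreasing
#'   importance; attribute `"model"` holds the fitted model.
#' @export
fit_and_rank <- function(expression, labels, learner = "rf",
                         top_k = nrow(expression), seed = 1L) {
  learner <- as_learner_spec(learner)
  stopifnot(top_k >= 1L, top_k <= nrow(expression),
            !is.null(rownames(expression)))
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    stop("training set is degenerate: a single class (",
         levels(y), ")", call. = FALSE)
  }
  x <- t(expression)
  hp <- learner$hyperparameters
  model <- NULL
  imp <- with_local_seed(seed, {
    if (learner$name == "rf") {
      model <- randomForest::randomForest(
        x = x, y = y, ntree = hp$ntree,
        mtry = max(1L, floor(sqrt(nrow(expression)))))
      randomForest::importance(model, type = 2)[, 1]
    } else {
      params <- hp[setdiff(names(hp), "nrounds")]
      params$objective <- "multi:softprob"
      params$num_class <- nlevels(y)
      params$nthread <- 1L
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      model <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = hp$nrounds, verbose = 0)
      full <- setNames(rep(0, nrow(expression)), rownames(expression))
      it <- xgboost::xgb.importance(model = model)
      full[it$Feature] <- it$Gain
      full
    }
  })
  gene_id <- rownames(expression)
  ord <- order(-imp[gene_id], gene_id, method = "radix")
  out <- data.frame(gene_id = gene_id[ord],
                    importance = unname(imp[gene_id][ord]),
                    stringsAsFactors = FALSE)[seq_len(top_k), ]
  rownames(out) <- NULL
  attr(out, "model") <- model
  attr(out, "classes") <- levels(y)
  out
}

#' Consensus gene selection by repeated split-fit-rank voting
#'
#' The repetition/voting protocol for one learner: in each of
#' `n_reps` repetitions a fresh stratified 70/30 split is drawn (seed
#' `seed + r` for repetition `r`), the learner is fitted on the training
#' cells, and the `top_k` genes by importance are recorded. A gene's
#' vote count is the number of repetitions whose top list contains it;
#' genes with at least `min_votes` votes are selected. The held-out
#' accuracy of each repetition is recorded (attribute `"accuracy"`) but
#' plays no role in selection.
#'
#' Setting `permute_labels = TRUE` turns the run into a permutation
#' null: each repetition shuffles the cell labels afresh (under its own
#' derived seed) before splitting and fitting, so votes are independent
#' across repetitions and the expected selection count at
#' `min_votes = n_reps / 2` is essentially zero. Note that shuffling the
#' labels *once* and running the ordinary protocol is not a null in the
#' same sense: each gene then keeps a fixed chance association with the
#' fixed permuted labels, repetitions (which share most of their
#' training cells) vote for the same chance genes, and selection
#' concentrates far above the independent-vote expectation.
#'
#' @inheritParams fit_and_rank
#' @param n_reps number of repetitions (default 100).
#' @param top_k per-repetition list length (default 100).
#' @param min_votes votes needed for selection (default 50).
#' @param train_frac training fraction per class (default 0.7).
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @param permute_labels re-shuffle labels within every repetition
#'   (permutation null control; default `FALSE`).
#' @return data.frame `gene_id`, `learner`, `vote_count`,
#'   `mean_importance` (mean over the repetitions where the gene made
#'   the top list; 0 if never), `selected`; one row per gene, ordered by
#'   decreasing vote count. Attribute `"accuracy"`: per-repetition
#'   held-out accuracy.
#' @export
run_consensus <- function(expression, labels, learner = "rf", n_reps = 100L,
                          top_k = 100L, min_votes = 50L, train_frac = 0.7,
                          seed = 1L, permute_labels = FALSE) {
  learner <- as_learner_spec(learner)
  stopifnot(n_reps >= 1L, min_votes <= n_reps, min_votes >= 1L)
  gene_id <- rownames(expression)
  votes <- setNames(integer(length(gene_id)), gene_id)
  imp_sum <- setNames(numeric(length(gene_id)), gene_id)
  accuracy <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    labels_r <- if (permute_labels) {
      with_local_seed(derive_seed(rep_seed, 77L), sample(labels))
    } else {
      labels
    }
    split <- stratified_split(expression, labels_r, train_frac,
                              seed = rep_seed)
    ranked <- tryCatch(
      fit_and_rank(expression[, split$train, drop = FALSE],
                   labels_r[split$train], learner, top_k = top_k,
                   seed = rep_seed),
      error = function(e) {
        stop("learner ", learner$name, " failed at repetition ", r, ": ",
             conditionMessage(e), call. = FALSE)
      })
    votes[ranked$gene_id] <- votes[ranked$gene_id] + 1L
    imp_sum[ranked$gene_id] <- imp_sum[ranked$gene_id] + ranked$importance
    accuracy[r] <- .heldout_accuracy(attr(ranked, "model"), learner,
                                     attr(ranked, "classes"),
                                     expression[, split$test, drop = FALSE],
                                     labels_r[split$test])
  }
  mean_imp <- ifelse(votes > 0, imp_sum / pmax(votes, 1L), 0)
  out <- data.frame(gene_id = gene_id, learner = learner$name,
                    vote_count = unname(votes),
                    mean_importance = unname(mean_imp),
                    selected = unname(votes) >= min_votes,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vote_count, out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "accuracy") <- accuracy
  attr(out, "n_reps") <- n_reps
  attr(out, "min_votes") <- min_votes
  out
}

.heldout_accuracy <- function(model, learner, classes, expression_test,
                              labels_test) {
  y <- as.character(labels_test)
  if (learner$name == "rf") {
    pred <- as.character(predict(model, t(expression_test)))
  } else {
    prob <- predict(model, xgboost::xgb.DMatrix(t(expression_test)))
    if (!is.matrix(prob)) {
      prob <- matrix(prob, ncol = length(classes), byrow = TRUE)
    }
    # probability columns follow the 0-based class coding used at fit time
    pred <- classes[max.col(prob, ties.method = "first")]
  }
  mean(pred == y)
}

#' Combine per-learner consensus tables into a final gene set + weights
#'
#' The final consensus set contains the genes selected by every learner
#' (`mode = "intersection"`, the default) or by any learner
#' (`"union"`). Because the learners' importance values live on
#' different scales, each learner's `mean_importance` column is min-max
#' rescaled to \[0, 1\] across its genes before combining; a consensus
#' gene's combined importance is the mean of its rescaled importances
#' over the learners. With `importance_from` set to a learner name, that
#' learner's rescaled importance is used alone instead of the mean.
#'
#' @param tables list of [run_consensus()] tables (one per learner).
#' @param mode `"intersection"` (default) or `"union"`.
#' @param importance_from `"mean"` (default) or one of `"rf"`, `"gb"`,
#'   `"xgb"`.
#' @return list with `genes` (character, sorted) and `importance` (named
#'   numeric: combined weight per consensus gene). Empty consensus
#'   raises a warning, not an error.
#' @export
combine_models <- function(tables, mode = c("intersection", "union"),
                           importance_from = "mean") {
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 1L)
  if (inherits(tables, "data.frame")) tables <- list(tables)
  sel_sets <- lapply(tables, function(t) t$gene_id[t$selected])
  genes <- if (mode == "intersection") {
    Reduce(intersect, sel_sets)
  } else {
    Reduce(union, sel_sets)
  }
  genes <- sort(genes)
  if (length(genes) == 0L) {
    warning("empty consensus gene set (no gene passed every learner)",
            call. = FALSE)
    return(list(genes = character(0), importance = setNames(numeric(0),
                                                            character(0))))
  }
  rescaled <- lapply(tables, function(t) {
    v <- t$mean_importance
    rng <- range(v)
    r <- if (rng[1] == rng[2]) rep(1, length(v)) else (v - rng[1]) / diff(rng)
    setNames(r, t$gene_id)
  })
  names(rescaled) <- vapply(tables, function(t) t$learner[1], character(1))
  mat <- vapply(rescaled, function(r) {
    out <- r[genes]
    out[is.na(out)] <- 0
    out
  }, numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(rescaled)))
  importance <- if (identical(importance_from, "mean")) {
    rowMeans(mat)
  } else {
    if (!importance_from %in% colnames(mat)) {
      stop("importance_from = ", sQuote(importance_from),
           " is not among the supplied learners (",
           paste(colnames(mat), collapse = ", "), ")", call. = FALSE)
    }
    setNames(mat[, importance_from], rownames(mat))
  }
  list(genes = genes, importance = importance)
}
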