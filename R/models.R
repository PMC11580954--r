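## models: the two random-forest scorers.
##
## The path-level "general" model filters unreliable candidates using the
## 30 general features; the pair-level "specific" model then estimates,
## for each surviving (candidate, cell) pair, the probability that the
## candidate is both correctly assembled and expressed in that cell,
## using all 51 features. Training labels come from exact intron-chain
## matches against ground truth, with a train/test split by chromosome.

#' Model configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth (default 12).
#' @param general_threshold Candidates with a general score below this are
#'   dropped before pair scoring (default 0.2).
#' @param seed RNG seed for forest construction (default 42).
#' @param train_chroms Chromosomes used for training; everything else is
#'   held out. Default: 1..9 with and without the "chr" prefix.
#' @param class_weights Optional named vector c("0" = , "1" = ) passed to
#'   the forests; \code{NULL} (default) trains unweighted.
#' @return List of class \code{model_config}.
#' @export
model_config <- function(n_trees = 100L, max_depth = 12L,
                         general_threshold = 0.2, seed = 42L,
                         train_chroms = c(paste0("chr", 1:9), as.character(1:9)),
                         class_weights = NULL) {
  stopifnot(general_threshold >= 0, general_threshold <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 general_threshold = general_threshold,
                 seed = as.integer(seed),
                 train_chroms = train_chroms,
                 class_weights = class_weights),
            class = "model_config")
}

#' Label candidate paths against unified ground truth
#'
#' A path is labeled 1 iff its (chrom, strand, intron chain) exactly
#' matches a multi-exon transcript in the unified truth set, 0 otherwise.
#'
#' @param paths Candidate table (needs chrom, strand, chain).
#' @param truth Table of ground-truth transcripts (chrom, strand, chain),
#'   typically the union over all cells restricted to the training
#'   chromosomes.
#' @return Integer vector of 0/1 labels, one per path row.
#' @export
label_general <- function(paths, truth) {
  paths <- as.data.table(paths); truth <- as.data.table(truth)
  if (nrow(truth) == 0L) {
    stop("empty ground truth: choose a different chromosome split")
  }
  tk <- unique(full_chain_key(truth$chrom, truth$strand, truth$chain))
  as.integer(full_chain_key(paths$chrom, paths$strand, paths$chain) %chin% tk)
}

#' Label (candidate, cell) pairs against per-cell ground truth
#'
#' A pair is labeled 1 only if the path's intron chain matches a
#' transcript expressed in that specific cell's ground truth.
#'
#' @param pairs Pair table (needs cell, chrom, strand, chain).
#' @param truth_cells Per-cell truth table (cell, chrom, strand, chain).
#' @return Integer vector of 0/1 labels, one per pair row.
#' @export
label_specific <- function(pairs, truth_cells) {
  pairs <- as.data.table(pairs); truth_cells <- as.data.table(truth_cells)
  if (nrow(truth_cells) == 0L) {
    stop("empty ground truth: choose a different chromosome split")
  }
  tk <- unique(paste(truth_cells$cell,
                     full_chain_key(truth_cells$chrom, truth_cells$strand,
                                    truth_cells$chain), sep = "@"))
  as.integer(paste(pairs$cell,
                   full_chain_key(pairs$chrom, pairs$strand, pairs$chain),
                   sep = "@") %chin% tk)
}

fit_forest <- function(kind, features, labels, cfg) {
  features <- as.data.frame(features)
  expected <- if (kind == "general") feature_names_general()
              else c(feature_names_general(), feature_names_cell())
  miss <- setdiff(expected, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  features <- features[, expected, drop = FALSE]
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class; cannot fit the ", kind, " model")
  }
  dat <- cbind(label = factor(labels, levels = c("0", "1")), features)
  fit <- ranger::ranger(
    dependent.variable.name = "label", data = dat,
    num.trees = cfg$n_trees, max.depth = cfg$max_depth,
    probability = TRUE, seed = cfg$seed, num.threads = 1L,
    importance = "impurity", class.weights = cfg$class_weights,
    verbose = FALSE)
  structure(list(kind = kind, fit = fit,
                 schema = FEATURE_SCHEMA_VERSION,
                 feature_names = expected,
                 meta = list(n = nrow(features),
                             n_positive = sum(labels == 1L),
                             n_negative = sum(labels == 0L),
                             seed = cfg$seed,
                             oob_error = fit$prediction.error)),
            class = "txmend_model")
}

#' Train the path-level (general) random forest
#'
#' @param features Table with the 30 general feature columns.
#' @param labels 0/1 labels from \code{\link{label_general}}.
#' @param cfg \code{\link{model_config}}.
#' @return A \code{txmend_model}.
#' @export
train_general <- function(features, labels, cfg = model_config()) {
  fit_forest("general", features, labels, cfg)
}

#' Train the pair-level (cell-specific) random forest on all 51 features
#'
#' @param features Table with the 30 general + 21 cell-specific columns.
#' @param labels 0/1 labels from \code{\link{label_specific}}.
#' @param cfg \code{\link{model_config}}.
#' @return A \code{txmend_model}.
#' @export
train_specific <- function(features, labels, cfg = model_config()) {
  fit_forest("specific", features, labels, cfg)
}

#' @export
print.txmend_model <- function(x, ...) {
  cat(sprintf("<txmend_model:%s> %d trees, %d samples (%d pos / %d neg), OOB error %.4f\n",
              x$kind, x$fit$num.trees, x$meta$n, x$meta$n_positive,
              x$meta$n_negative, x$meta$oob_error))
  invisible(x)
}

#' Predict class-1 probabilities from a trained model
#'
#' @param object A \code{txmend_model}.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0,1\].
#' @export
predict.txmend_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    stop("feature schema mismatch; missing columns: ", paste(miss, collapse = ", "))
  }
  pr <- predict(object$fit, data = newdata[, object$feature_names, drop = FALSE],
                num.threads = 1L, verbose = FALSE)$predictions
  unname(pr[, "1"])
}

#' Serialize / reload a trained model
#'
#' Models round-trip with bit-identical predictions; the embedded feature
#' schema version is checked on load.
#'
#' @param model A \code{txmend_model}.
#' @param path File path (.rds).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "txmend_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "txmend_model")) stop("not a txmend model file: ", path)
  if (!identical(m$schema, FEATURE_SCHEMA_VERSION)) {
    stop(sprintf("model schema '%s' does not match package schema '%s'",
                 m$schema, FEATURE_SCHEMA_VERSION))
  }
  m
}

#' Train both models with the chromosome split
#'
#' Restricts candidates and pairs to the configured training chromosomes,
#' labels them against ground truth, fits the general model, applies its
#' threshold to define the filtered candidate set, and fits the specific
#' model on the surviving pairs (this mirrors how the filter balances the
#' pair-level training sample).
#'
#' @param candidates \code{\link{assemble_candidates}} output.
#' @param pairs \code{\link{build_pair_table}} output.
#' @param truth_cells Per-cell truth (cell, chrom, strand, chain).
#' @param cfg \code{\link{model_config}}.
#' @return List with \code{general}, \code{specific} (both
#'   \code{txmend_model}) and a \code{report} data.table of feature
#'   importances.
#' @export
train_models <- function(candidates, pairs, truth_cells, cfg = model_config()) {
  candidates <- as.data.table(candidates)
  pairs <- as.data.table(pairs)
  truth_cells <- as.data.table(truth_cells)

  truth_train <- truth_cells[chrom %chin% cfg$train_chroms]
  if (nrow(truth_train) == 0L) {
    stop("no ground-truth transcripts on the training chromosomes; choose a different split")
  }
  cand_train <- candidates[chrom %chin% cfg$train_chroms]
  if (nrow(cand_train) == 0L) stop("no candidates on the training chromosomes")
  glabels <- label_general(cand_train,
                           unique(truth_train[, .(chrom, strand, chain)]))
  gfeat <- build_general_table(cand_train, pairs)
  general <- train_general(gfeat, glabels, cfg)

  gprob <- predict(general, gfeat)
  kept_ids <- cand_train$candidate_id[gprob >= cfg$general_threshold]
  pair_train <- pairs[chrom %chin% cfg$train_chroms & candidate_id %in% kept_ids]
  if (nrow(pair_train) == 0L) {
    stop("no training pairs survive the general filter; lower general_threshold")
  }
  slabels <- label_specific(pair_train, truth_train)
  specific <- train_specific(pair_train, slabels, cfg)

  report <- rbindlist(list(
    data.table(model = "general",
               feature = names(general$fit$variable.importance),
               importance = as.numeric(general$fit$variable.importance)),
    data.table(model = "specific",
               feature = names(specific$fit$variable.importance),
               importance = as.numeric(specific$fit$variable.importance))))
  list(general = general, specific = specific, report = report)
}

## One row of general features per candidate, pulled out of the pair table
## (the general block repeats across a candidate's cells).
build_general_table <- function(candidates, pairs) {
  pairs <- as.data.table(pairs)
  g <- unique(pairs[, c("candidate_id", feature_names_general()), with = FALSE],
              by = "candidate_id")
  out <- merge(as.data.table(candidates)[, .(candidate_id)], g,
               by = "candidate_id", all.x = TRUE, sort = FALSE)
  if (anyNA(out)) stop("candidates missing from the pair table; rebuild pairs")
  out[, candidate_id := NULL]
  out[]
}

#' Score candidates per cell: filter then assign probabilities
#'
#' Applies the general model to every candidate, drops those scoring
#' below \code{cfg$general_threshold}, scores each surviving
#' (candidate, cell) pair with the specific model, and emits per-cell
#' transcripts carrying the pair probability as their score (deduplicated
#' per cell by intron chain, keeping the maximum).
#'
#' @param candidates \code{\link{assemble_candidates}} output.
#' @param pairs \code{\link{build_pair_table}} output.
#' @param general_model,specific_model Trained \code{txmend_model}s.
#' @param cfg \code{\link{model_config}}.
#' @param min_score Optional final cutoff on the pair probability
#'   (default 0: emit everything that was scored).
#' @return data.table of scored transcripts: cell, chrom, strand,
#'   tx_start, tx_end, chain, score, prob_general, candidate_id.
#' @export
apply_pipeline <- function(candidates, pairs, general_model, specific_model,
                           cfg = model_config(), min_score = 0) {
  candidates <- as.data.table(candidates)
  pairs <- as.data.table(pairs)
  empty <- data.table(cell = character(0), chrom = character(0),
                      strand = character(0), tx_start = integer(0),
                      tx_end = integer(0), chain = character(0),
                      score = numeric(0), prob_general = numeric(0),
                      candidate_id = integer(0))
  if (nrow(candidates) == 0L || nrow(pairs) == 0L) return(empty[])
  gfeat <- build_general_table(candidates, pairs)
  gprob <- predict(general_model, gfeat)
  keep <- candidates$candidate_id[gprob >= cfg$general_threshold]
  gmap <- data.table(candidate_id = candidates$candidate_id,
                     prob_general = gprob)
  sp <- pairs[candidate_id %in% keep]
  if (nrow(sp) == 0L) return(empty[])
  sp[, score := predict(specific_model, .SD), .SDcols = specific_model$feature_names]
  out <- merge(sp[, .(candidate_id, cell, chrom, strand, chain, score)],
               candidates[, .(candidate_id, tx_start, tx_end)],
               by = "candidate_id")
  out <- merge(out, gmap, by = "candidate_id")
  out <- out[score >= min_score]
  setorder(out, cell, chrom, chain, -score)
  out <- out[!duplicated(paste(cell, full_chain_key(chrom, strand, chain)))]
  setorder(out, cell, chrom, tx_start, chain)
  setcolorder(out, c("cell", "chrom", "strand", "tx_start", "tx_end",
                     "chain", "score", "prob_general", "candidate_id"))
  out[]
}
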