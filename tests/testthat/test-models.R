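library(data.table)

## small separable feature tables for direct model tests
separable_features <- function(n, kind = "general", seed = 1) {
  set.seed(seed)
  nms <- if (kind == "general") feature_names_general()
         else c(feature_names_general(), feature_names_cell())
  X <- as.data.table(matrix(runif(n * length(nms)), nrow = n,
                            dimnames = list(NULL, nms)))
  y <- rep(0:1, length.out = n)
  X[, bottleneck := y + runif(n, 0, 0.2)]  # signal column
  list(X = X, y = y)
}

test_that("path labels are exact intron-chain membership", {
  paths <- data.table(chrom = c("chr1", "chr1", "chr2"), strand = "+",
                      chain = c("101-199,301-399", "101-199", "101-199,301-399"))
  truth <- data.table(chrom = "chr1", strand = "+", chain = "101-199,301-399")
  expect_identical(label_general(paths, truth), c(1L, 0L, 0L))
  ## a path missing one junction of its best match is negative
  paths2 <- data.table(chrom = "chr1", strand = "+", chain = "301-399")
  expect_identical(label_general(paths2, truth), 0L)
  ## oracle recount via set membership on random chains
  set.seed(3)
  rs <- random_scored_set(30)
  labs <- label_general(rs$X, rs$truth)
  expect_identical(sum(labs), nrow(unique(rs$truth)))
  expect_error(label_general(paths, truth[0]), "split")
})

test_that("pair labels are cell-specific", {
  pairs <- data.table(cell = c("A", "B"), chrom = "chr1", strand = "+",
                      chain = "101-199,301-399")
  truth <- data.table(cell = "A", chrom = "chr1", strand = "+",
                      chain = "101-199,301-399")
  expect_identical(label_specific(pairs, truth), c(1L, 0L))
  ## a path absent from every cell's truth labels all pairs 0
  pairs2 <- copy(pairs)[, chain := "501-599,701-799"]
  expect_identical(label_specific(pairs2, truth), c(0L, 0L))
})

test_that("forests separate a signal column perfectly and round-trip", {
  d <- separable_features(200)
  m <- train_general(d$X, d$y, model_config())
  pr <- predict(m, d$X)
  expect_identical(as.integer(pr > 0.5), d$y)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, d$X), pr)
})

test_that("degenerate training sets are rejected", {
  d <- separable_features(50)
  expect_error(train_general(d$X, rep(1L, 50), model_config()), "single class")
  expect_error(train_specific(d$X, d$y, model_config()), "lacks columns")
  m <- train_general(d$X, d$y, model_config())
  expect_error(predict(m, d$X[, 1:5]), "schema mismatch")
})

test_that("label permutation collapses held-out AUROC to chance", {
  d <- separable_features(400, seed = 8)
  set.seed(42)
  y_perm <- sample(d$y)
  tr <- seq_len(300); te <- 301:400
  m <- train_general(d$X[tr], y_perm[tr], model_config())
  auc <- as.numeric(pROC::auc(pROC::roc(y_perm[te], predict(m, d$X[te]),
                                        quiet = TRUE, direction = "<")))
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("training is deterministic under a fixed seed", {
  d <- separable_features(150, seed = 5)
  m1 <- train_general(d$X, d$y, model_config(seed = 42))
  m2 <- train_general(d$X, d$y, model_config(seed = 42))
  expect_identical(predict(m1, d$X), predict(m2, d$X))
})

test_that("the general threshold filters candidates before pair scoring", {
  as <- toy_assemblies()
  cand <- assemble_candidates(as)
  pairs <- build_pair_table(cand, as)
  ## train tiny forests on synthetic separable data with matching schemas
  dg <- separable_features(120, "general", seed = 2)
  ds <- separable_features(120, "specific", seed = 2)
  mg <- train_general(dg$X, dg$y, model_config())
  ms <- train_specific(ds$X, ds$y, model_config())
  ## threshold 0: every paired candidate is scored
  out0 <- apply_pipeline(cand, pairs, mg, ms, model_config(general_threshold = 0))
  expect_identical(nrow(out0), nrow(pairs))
  ## raising the threshold never increases output size, per cell
  sizes <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(th) {
    nrow(apply_pipeline(cand, pairs, mg, ms,
                        model_config(general_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  ## a candidate scoring below threshold vanishes from every cell
  gprob <- predict(mg, txmend:::build_general_table(cand, pairs))
  th <- max(gprob) + 1e-6
  outh <- apply_pipeline(cand, pairs, mg, ms,
                         model_config(general_threshold = min(th, 1)))
  if (th <= 1) expect_identical(nrow(outh), 0L)
})

test_that("train_models splits by chromosome and balances the specific set", {
  fx <- acceptance_fixture()
  cfg <- fx$cfg
  expect_true(all(fx$models$general$meta$n <= nrow(fx$candidates)))
  ## training rows all lie on train chromosomes
  expect_identical(fx$models$general$meta$n,
                   nrow(fx$candidates[chrom %chin% cfg$train_chroms]))
  ## the pair-level training set is larger than the path-level one
  expect_gt(fx$models$specific$meta$n, fx$models$general$meta$n)
  ## report covers both models with 30 and 51 features
  expect_identical(nrow(fx$models$report[model == "general"]), 30L)
  expect_identical(nrow(fx$models$report[model == "specific"]), 51L)
})
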