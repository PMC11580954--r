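## Shared fixtures, all built in code.

## junction shorthand used throughout: j1 = 201-299, j2 = 401-499,
## j3 = 601-699 on chr1:+
J1 <- "201-299"; J2 <- "401-499"; J3 <- "601-699"

frag_row <- function(id, chain, score, tx_start, tx_end,
                     chrom = "chr1", strand = "+") {
  data.table::data.table(id = id, chrom = chrom, strand = strand,
                         tx_start = as.integer(tx_start),
                         tx_end = as.integer(tx_end),
                         chain = chain, score = score)
}

## the worked three-fragment pool: t1=[j1,j2] 0.8, t2=[j2,j3] 0.6,
## t3=[j1,j2,j3] 0.4, one fragment per cell
toy_assemblies <- function() {
  list(
    make_cell_assembly(frag_row("t1", paste(J1, J2, sep = ","), 0.8, 100, 550), "A"),
    make_cell_assembly(frag_row("t2", paste(J2, J3, sep = ","), 0.6, 350, 800), "B"),
    make_cell_assembly(frag_row("t3", paste(J1, J2, J3, sep = ","), 0.4, 120, 790), "C"))
}

## random single-gene fragment sets producing small, often branched
## components: one junction backbone, sometimes an alternative-boundary
## sibling, fragments are contiguous subchains spread over up to 3 cells
random_component_assemblies <- function() {
  J <- sample(3:7, 1)
  js <- sort(sample(seq(1000L, 99000L, by = 100L), 2L * J))
  chain <- cbind(start = js[seq(1L, 2L * J, 2L)], end = js[seq(2L, 2L * J, 2L)])
  chains <- list(chain)
  if (runif(1) < 0.5) {
    alt <- chain; r <- sample(1:J, 1); alt[r, 2L] <- alt[r, 2L] + 30L
    chains[[2L]] <- alt
  }
  frs <- lapply(seq_len(sample(3:7, 1)), function(i) {
    cm <- chains[[sample(length(chains), 1)]]
    a <- sample(1:J, 1); b <- sample(a:J, 1)
    sub <- cm[a:b, , drop = FALSE]
    cbind(frag_row(paste0("f", i), format_chain(sub), round(runif(1, 0.1, 1), 3),
                   sub[1L, 1L] - 50L, sub[nrow(sub), 2L] + 50L),
          cell = paste0("c", sample(1:3, 1)))
  })
  fr <- data.table::rbindlist(frs)
  lapply(split(fr, fr$cell), function(x)
    make_cell_assembly(x[, setdiff(names(x), "cell"), with = FALSE], x$cell[1]))
}

## random scored prediction sets plus a truth subset, for metric tests
random_scored_set <- function(n = 12, distinct_scores = TRUE) {
  chains <- vapply(seq_len(n), function(i) {
    s <- sort(sample(seq(1000L, 90000L, by = 10L), 4L))
    format_chain(cbind(s[c(1, 3)], s[c(2, 4)]))
  }, character(1))
  scores <- if (distinct_scores) sample(seq(0.01, 0.99, length.out = n))
            else round(runif(n), 1)
  X <- data.table::data.table(chrom = "chr1", strand = "+", chain = chains,
                              score = scores)
  truth <- X[sample(n, max(1L, n %/% 2L)), .(chrom, strand, chain)]
  list(X = X, truth = truth)
}

## the heavy end-to-end scenario is computed once and shared across test
## files through an environment cache
.fixture_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  bundle <- scenario_recoverable(1)
  candidates <- assemble_candidates(bundle$assemblies)
  pairs <- build_pair_table(candidates, bundle$assemblies)
  cfg <- model_config()
  models <- train_models(candidates, pairs,
                         bundle$truth[, .(cell, chrom, strand, chain)], cfg)
  scored <- apply_pipeline(candidates, pairs, models$general, models$specific, cfg)
  .fixture_cache$fx <- list(bundle = bundle, candidates = candidates,
                            pairs = pairs, cfg = cfg, models = models,
                            scored = scored)
  .fixture_cache$fx
}
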