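library(data.table)

full_chain <- paste(J1, J2, J3, sep = ",")

test_that("compatibility requires a shared junction and no conflicts in span", {
  expect_true(is_compatible(paste(J1, J2, sep = ","), full_chain))
  ## junction overlapping j2's interval but not equal to it conflicts
  expect_false(is_compatible(paste(J1, "411-489", sep = ","), full_chain))
  ## disjoint fragment shares nothing
  expect_false(is_compatible("801-899", full_chain))
  ## junction outside the span is neutral
  expect_true(is_compatible(paste(J2, J3, "801-899", sep = ","), full_chain))
})

test_that("the worked three-fragment pool gives J=(1.2,1.8,1.0), BJ=1, F=3", {
  pool <- fragment_pool(toy_assemblies())
  expect_equal(junction_score(J1, full_chain, pool), 1.2)
  expect_equal(junction_score(J2, full_chain, pool), 1.8)
  expect_equal(junction_score(J3, full_chain, pool), 1.0)
  ms <- merging_score(full_chain, pool)
  expect_equal(ms$bj, 1.0)
  expect_identical(ms$nj, 3L)
  expect_equal(ms$f, 3.0)
})

test_that("a lone fragment supports its own junction", {
  pool <- data.table(chain = "101-199", score = 0.5)
  expect_equal(junction_score("101-199", "101-199", pool), 0.5)
  expect_equal(merging_score("101-199", pool)$f, 0.5)
})

test_that("merging score is linear in fragment scores", {
  pool <- fragment_pool(toy_assemblies())
  ms1 <- merging_score(full_chain, pool)
  pool2 <- copy(pool)[, score := score * 2]
  ms2 <- merging_score(full_chain, pool2)
  expect_equal(ms2$bj, 2 * ms1$bj)
  expect_equal(ms2$f, 2 * ms1$f)
  expect_identical(ms2$nj, ms1$nj)
})

test_that("the dynamic program recovers the full-length toy path", {
  g <- build_graph(toy_assemblies())
  comp <- graph_components(g)[[1]]
  top <- dp_top_paths(comp, search_params(), g$pool)
  expect_identical(top$chain[1], full_chain)
  expect_equal(top$f[1], 3.0)
  expect_equal(top$bj[1], 1.0)
  expect_identical(top$nj[1], 3L)
})

test_that("a singleton component yields exactly its singleton path", {
  a <- make_cell_assembly(frag_row("x", "101-199,301-399", 0.7, 50, 500), "A")
  g <- build_graph(list(a))
  comp <- graph_components(g)[[1]]
  top <- dp_top_paths(comp, search_params(), g$pool)
  expect_identical(nrow(top), 1L)
  expect_identical(top$chain, "101-199,301-399")
  expect_equal(top$f, 1.4)
  expect_identical(top$n_vertices, 1L)
})

test_that("brute force enumerates all directed paths and validates itself", {
  g <- build_graph(toy_assemblies())
  comp <- graph_components(g)[[1]]
  bf <- brute_force_paths(comp, g$pool)
  ## toy DAG: 3 singletons + edges (v12->v23), (v12->vall) = 5 paths
  expect_identical(nrow(bf), 5L)
  pool <- g$pool
  for (i in seq_len(nrow(bf))) {
    ms <- merging_score(bf$chain[i], pool)
    expect_equal(bf$f[i], ms$f)
    expect_equal(bf$bj[i], ms$bj)
  }
})

test_that("a linear chain-of-3 DAG has six paths", {
  ## overlap-by-one chains give a -> b -> c with no transitive edge
  rows <- rbind(frag_row("a", "101-199,301-399", 0.5, 50, 500),
                frag_row("b", "301-399,501-599", 0.5, 250, 700),
                frag_row("c", "501-599,701-799", 0.5, 450, 900))
  g <- build_graph(list(make_cell_assembly(rows, "A")))
  comp <- graph_components(g)[[1]]
  expect_identical(nrow(g$edges), 2L)
  expect_identical(nrow(brute_force_paths(comp, g$pool)), 6L)
})

test_that("brute force refuses oversized components", {
  set.seed(5)
  rows <- lapply(1:16, function(i) {
    s <- c(100L + i * 10L, 5000L)
    frag_row(paste0("f", i), format_chain(cbind(s, s + 200L)), 0.5, 50, 9000)
  })
  g <- build_graph(list(make_cell_assembly(rbindlist(rows), "A")))
  fake <- structure(list(component_id = 1L, chrom = "chr1", strand = "+",
                         vertices = g$vertices, edges = g$edges,
                         chains = g$chains, members = g$members),
                    class = "fragment_component")
  expect_error(brute_force_paths(fake, g$pool), "too large")
})

test_that("heuristic equals the oracle on random small components", {
  set.seed(23)
  tested <- 0L
  while (tested < 60L) {
    as <- random_component_assemblies()
    g <- build_graph(as)
    for (comp in graph_components(g)) {
      if (nrow(comp$vertices) > 8L) next
      tested <- tested + 1L
      dp <- dp_top_paths(comp, search_params(), g$pool)
      bf <- brute_force_paths(comp, g$pool)
      expect_equal(dp$f[1], bf$f[1])
      expect_identical(dp$chain[1], bf$chain[1])
    }
  }
})

test_that("raising a compatible fragment's score never lowers BJ or F", {
  set.seed(31)
  for (rep in 1:10) {
    as <- random_component_assemblies()
    g <- build_graph(as)
    cand <- assemble_candidates(g)
    if (nrow(cand) == 0L) next
    p <- cand$chain[1]
    pool <- g$pool
    ms0 <- merging_score(p, pool)
    compat <- which(vapply(pool$chain, is_compatible, logical(1), p = p))
    if (!length(compat)) next
    pool2 <- copy(pool)
    i <- compat[sample.int(length(compat), 1L)]
    pool2$score[i] <- min(1, pool2$score[i] + 0.3)
    ms1 <- merging_score(p, pool2)
    expect_gte(ms1$bj, ms0$bj)
    expect_gte(ms1$f, ms0$f)
  }
})

test_that("every emitted candidate satisfies F = BJ x NJ with positive BJ", {
  set.seed(37)
  for (rep in 1:8) {
    cand <- assemble_candidates(random_component_assemblies())
    expect_equal(cand$f, cand$bj * cand$nj)
    expect_true(all(cand$bj > 0))
  }
})

test_that("candidate assembly is deterministic and chain-deduplicated", {
  set.seed(41)
  as <- random_component_assemblies()
  c1 <- assemble_candidates(as)
  c2 <- assemble_candidates(as)
  expect_identical(c1$chain, c2$chain)
  expect_identical(c1$f, c2$f)
  expect_false(any(duplicated(paste(c1$chrom, c1$strand, c1$chain))))
})
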