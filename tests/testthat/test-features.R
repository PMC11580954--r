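library(data.table)

full_chain <- paste(J1, J2, J3, sep = ",")

toy_candidate <- function() {
  cand <- assemble_candidates(toy_assemblies())
  cand[chain == full_chain]
}

test_that("feature schemas have exactly 30 and 21 stable names", {
  expect_length(feature_names_general(), 30L)
  expect_length(feature_names_cell(), 21L)
  expect_false(anyDuplicated(c(feature_names_general(), feature_names_cell())) > 0)
  gf <- general_features(toy_candidate(), toy_assemblies())
  expect_identical(names(gf), feature_names_general())
  cf <- cell_features(toy_candidate(), "A", toy_assemblies())
  expect_identical(names(cf), feature_names_cell())
  expect_true(all(is.finite(gf)) && all(is.finite(cf)))
})

test_that("general features of the toy path match hand computation", {
  gf <- general_features(toy_candidate(), toy_assemblies())
  expect_equal(unname(gf["jscore_min"]), 1.0)
  expect_equal(unname(gf["jscore_max"]), 1.8)
  expect_equal(unname(gf["jscore_mean"]), 4 / 3)
  expect_equal(unname(gf["n_junctions"]), 3)
  expect_equal(unname(gf["bottleneck"]), 1.0)
  expect_equal(unname(gf["merging_score"]), 3.0)
  ## three supporting cells, one (C) covering all junctions
  expect_equal(unname(gf["n_support_cells"]), 3)
  expect_equal(unname(gf["frac_cells_full"]), 1 / 3)
  expect_equal(unname(gf["member_score_max"]), 0.8)
  ## min <= median <= max ordering on every stat block
  expect_lte(gf["jscore_min"], gf["jscore_median"])
  expect_lte(gf["jscore_median"], gf["jscore_max"])
})

test_that("a single-vertex single-member path flags chain integrity", {
  a <- make_cell_assembly(frag_row("x", "101-199", 0.7, 50, 400), "A")
  cand <- assemble_candidates(list(a))
  gf <- general_features(cand[1], list(a))
  expect_equal(unname(gf["single_fragment"]), 1)
  expect_equal(unname(gf["n_path_vertices"]), 1)
  ## one junction -> zero spread
  expect_equal(unname(gf["jscore_sd"]), 0)
})

test_that("cell features match hand computation for a partial supporter", {
  ## cell A holds t1=[j1,j2] s=0.8 against p=[j1,j2,j3]
  cf <- cell_features(toy_candidate(), "A", toy_assemblies())
  expect_equal(unname(cf["c_n_junc_supported"]), 2)
  expect_equal(unname(cf["c_frac_junc_supported"]), 2 / 3)
  ## unsupported j3 zeroes the cell-restricted bottleneck
  expect_equal(unname(cf["c_bottleneck"]), 0)
  expect_equal(unname(cf["c_total_cov"]), 0.8)
  expect_equal(unname(cf["c_longest_run"]), 2)
  ## A has the highest coverage of the three supporting cells
  expect_equal(unname(cf["c_cov_rank"]), 1)
})

test_that("a cell holding the path's full fragment supports every junction", {
  cf <- cell_features(toy_candidate(), "C", toy_assemblies())
  expect_equal(unname(cf["c_frac_junc_supported"]), 1)
  expect_equal(unname(cf["c_longest_run"]), 3)
  expect_equal(unname(cf["c_has_member"]), 1)
})

test_that("a sole supporting cell has rank 1 and coverage ratio 1", {
  a <- make_cell_assembly(frag_row("x", "101-199,301-399", 0.6, 50, 500), "A")
  cand <- assemble_candidates(list(a))
  cf <- cell_features(cand[1], "A", list(a))
  expect_equal(unname(cf["c_cov_rank"]), 1)
  expect_equal(unname(cf["c_cov_ratio"]), 1)
})

test_that("pairing requires an expressed junction", {
  a <- make_cell_assembly(frag_row("x", "101-199,301-399", 0.6, 50, 500), "A")
  b <- make_cell_assembly(frag_row("y", "901-999", 0.6, 850, 1200), "B")
  cand <- assemble_candidates(list(a, b))
  p <- cand[chain == "101-199,301-399"]
  expect_error(cell_features(p, "B", list(a, b)), "pairing rule")
})

test_that("cell-restricted junction scores never exceed pooled scores", {
  set.seed(17)
  for (rep in 1:6) {
    as <- random_component_assemblies()
    cand <- assemble_candidates(as)
    if (nrow(cand) == 0L) next
    pool <- fragment_pool(as)
    p <- cand[1]
    gf <- general_features(p, as)
    for (cc in unique(pool$cell)) {
      cf <- tryCatch(cell_features(p, cc, as), error = function(e) NULL)
      if (is.null(cf)) next
      expect_lte(cf["c_jscore_max"], gf["jscore_max"] + 1e-12)
      expect_lte(cf["c_bottleneck"], gf["bottleneck"] + 1e-12)
    }
  }
})

test_that("a one-cell pool makes cell coverage stats equal the pooled stats", {
  rows <- rbind(frag_row("a", paste(J1, J2, sep = ","), 0.5, 100, 550),
                frag_row("b", paste(J2, J3, sep = ","), 0.3, 350, 800),
                frag_row("c", full_chain, 0.2, 120, 790))
  a <- make_cell_assembly(rows, "only")
  cand <- assemble_candidates(list(a))
  p <- cand[chain == full_chain]
  gf <- general_features(p, list(a))
  cf <- cell_features(p, "only", list(a))
  for (s in c("min", "median", "mean", "max", "sd")) {
    expect_equal(unname(cf[paste0("c_jscore_", s)]),
                 unname(gf[paste0("jscore_", s)]))
  }
})

test_that("the pair table pairs exactly the cells expressing a junction", {
  as <- toy_assemblies()
  cand <- assemble_candidates(as)
  pairs <- build_pair_table(cand, as)
  ## oracle: brute-force double loop over (path, cell)
  pool <- fragment_pool(as)
  expected <- 0L
  for (i in seq_len(nrow(cand))) {
    pj <- strsplit(cand$chain[i], ",", fixed = TRUE)[[1]]
    for (cc in unique(pool$cell)) {
      cells_j <- unlist(strsplit(pool[cell == cc, chain], ",", fixed = TRUE))
      if (any(pj %in% cells_j)) expected <- expected + 1L
    }
  }
  expect_identical(nrow(pairs), expected)
  ## all three cells share junctions with both toy candidates
  expect_identical(nrow(pairs), 2L * 3L)
  ## deterministic order and full schema
  expect_identical(pairs, pairs[order(candidate_id, cell)])
  expect_true(all(c(feature_names_general(), feature_names_cell()) %in% names(pairs)))
})

test_that("cells sharing no junction with a path are never paired", {
  a <- make_cell_assembly(frag_row("x", "101-199,301-399", 0.6, 50, 500), "A")
  b <- make_cell_assembly(frag_row("y", "901-999,1101-1199", 0.6, 850, 1400), "B")
  cand <- assemble_candidates(list(a, b))
  pairs <- build_pair_table(cand, list(a, b))
  expect_identical(nrow(pairs), 2L)  # each candidate pairs only its own cell
  expect_identical(pairs[chain == "101-199,301-399", cell], "A")
})
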