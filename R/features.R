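## features: engineered predictors for candidate paths.
##
## Two fixed schemas: 30 "general" features describing a candidate path
## against the pooled fragments of all cells, and 21 "cell-specific"
## features describing the support a single cell lends to that path. All
## five-number summaries are (min, median, mean, max, sd) with the
## population standard deviation (divide by n).

FEATURE_SCHEMA_VERSION <- "txmend-features-v1"

#' Feature schema names
#'
#' @return Character vector of stable feature names (30 general, 21
#'   cell-specific).
#' @export
feature_names_general <- function() {
  c(paste0("jscore_", c("min", "median", "mean", "max", "sd")),
    paste0("jfrags_", c("min", "median", "mean", "max", "sd")),
    "n_junctions", "bottleneck", "merging_score",
    "n_support_cells",
    paste0("cellcov_", c("min", "median", "mean", "max", "sd")),
    paste0("celljn_", c("min", "median", "mean", "max", "sd")),
    "frac_cells_full",
    "n_path_vertices", "single_fragment", "n_vertex_cells",
    "member_score_max", "member_score_mean")
}

#' @rdname feature_names_general
#' @export
feature_names_cell <- function() {
  c(paste0("c_jscore_", c("min", "median", "mean", "max", "sd")),
    paste0("c_jfrags_", c("min", "median", "mean", "max", "sd")),
    "c_n_junc_supported", "c_frac_junc_supported", "c_bottleneck",
    "c_total_cov", "c_n_frags", "c_max_frag_score",
    "c_has_member", "c_n_members", "c_longest_run",
    "c_cov_rank", "c_cov_ratio")
}

## population-sd five-number summary
stats5 <- function(x) {
  if (!length(x)) return(c(0, 0, 0, 0, 0))
  mu <- mean(x)
  c(min(x), stats::median(x), mu, max(x), sqrt(mean((x - mu)^2)))
}

## longest run of TRUE values
longest_run <- function(b) {
  if (!length(b) || !any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

## Everything feature construction needs about one candidate against one
## (chrom, strand) bucket of the pool.
candidate_support <- function(chain_mat, bucket_frags, bucket_introns) {
  ck <- paste0(chain_mat[, 1L], "-", chain_mat[, 2L])
  ctx <- make_score_ctx(ck, bucket_frags, bucket_introns)
  sel <- sort(unname(ctx$jid_of[ck]))
  sc <- score_sel(ctx, sel)
  idx <- which(sc$compat)
  cells <- ctx$cells[idx]
  scores <- ctx$scores[idx]
  Mc <- ctx$M[idx, sel, drop = FALSE]
  share_cells <- if (length(ctx$cells)) unique(ctx$cells[sc$shares]) else character(0)
  if (length(idx)) {
    cov_by_cell <- rowsum(scores, cells)
    Jc <- rowsum(Mc * scores, cells)           # supporting cells x NJ
    Cc <- rowsum(Mc, cells)                    # compatible fragment counts
    supp_cells <- rownames(cov_by_cell)
  } else {
    cov_by_cell <- Jc <- Cc <- NULL
    supp_cells <- character(0)
  }
  list(J = sc$J, counts = sc$counts, bj = sc$bj, nj = sc$nj, f = sc$f,
       compat_cells = cells, compat_scores = scores,
       share_cells = sort(share_cells), supp_cells = supp_cells,
       cov_by_cell = cov_by_cell, Jc = Jc, Cc = Cc)
}

general_from_support <- function(sup, n_vertices, member_cells, member_scores) {
  njn <- if (!is.null(sup$Cc)) rowSums(sup$Cc > 0) else numeric(0)
  covs <- if (!is.null(sup$cov_by_cell)) sup$cov_by_cell[, 1L] else numeric(0)
  v <- c(stats5(sup$J), stats5(sup$counts),
         sup$nj, sup$bj, sup$f,
         length(sup$supp_cells),
         stats5(covs), stats5(njn),
         if (length(njn)) mean(njn == sup$nj) else 0,
         n_vertices, as.numeric(n_vertices == 1L),
         length(unique(member_cells)),
         if (length(member_scores)) max(member_scores) else 0,
         if (length(member_scores)) mean(member_scores) else 0)
  setNames(v, feature_names_general())
}

cell_from_support <- function(sup, cell, member_cells) {
  nj <- sup$nj
  is_supp <- cell %in% sup$supp_cells
  if (is_supp) {
    i <- match(cell, rownames(sup$cov_by_cell))
    Jc <- sup$Jc[i, ]
    Cc <- sup$Cc[i, ]
    cov <- sup$cov_by_cell[i, 1L]
    covs <- sup$cov_by_cell[, 1L]
    n <- length(covs)
    r <- rank(-covs, ties.method = "min")[i]
    rank_norm <- (n - r + 1) / n
    ratio <- cov / mean(covs)
    fscores <- sup$compat_scores[sup$compat_cells == cell]
  } else {
    Jc <- numeric(nj); Cc <- numeric(nj); cov <- 0
    rank_norm <- 0; ratio <- 0; fscores <- numeric(0)
  }
  supported <- Cc > 0
  v <- c(stats5(Jc), stats5(Cc),
         sum(supported), mean(supported), min(Jc),
         cov, length(fscores),
         if (length(fscores)) max(fscores) else 0,
         as.numeric(cell %in% member_cells),
         sum(member_cells == cell),
         longest_run(supported),
         rank_norm, ratio)
  setNames(v, feature_names_cell())
}

## normalise a path argument to a list with the fields features need
as_candidate <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    p <- as.list(p)
    for (col in c("vids", "member_cells", "member_scores")) {
      if (col %in% names(p) && is.list(p[[col]])) p[[col]] <- p[[col]][[1L]]
    }
  }
  if (is.null(p$member_cells)) p$member_cells <- character(0)
  if (is.null(p$member_scores)) p$member_scores <- numeric(0)
  if (is.null(p$n_vertices)) p$n_vertices <- max(1L, length(p$vids))
  p
}

bucket_of <- function(pool, chrom_, strand_) {
  fr <- pool[chrom == chrom_ & strand == strand_]
  ji <- explode_introns(fr)
  ji[, jkey := paste0(start, "-", end)]
  list(frags = fr, introns = ji)
}

#' General (path-level) features of a candidate
#'
#' @param p One candidate: a single row of
#'   \code{\link{assemble_candidates}} output, or a list with at least
#'   \code{chrom}, \code{strand}, \code{chain} (and optionally
#'   \code{n_vertices}, \code{member_cells}, \code{member_scores}).
#' @param pool Fragments of all cells: list of \code{cell_assembly} or a
#'   fragment table.
#' @return Named numeric vector of length 30.
#' @export
general_features <- function(p, pool) {
  p <- as_candidate(p)
  pool <- as_pool(pool)
  b <- bucket_of(pool, p$chrom, p$strand)
  sup <- candidate_support(as_chain_matrix(p$chain), b$frags, b$introns)
  general_from_support(sup, p$n_vertices, p$member_cells, p$member_scores)
}

#' Cell-specific features of a (candidate, cell) pair
#'
#' The pair must satisfy the pairing rule: at least one junction of the
#' path occurs in some fragment of the cell (compatibility is not
#' required for pairing, only for scoring).
#'
#' @inheritParams general_features
#' @param cell Cell identifier.
#' @return Named numeric vector of length 21.
#' @export
cell_features <- function(p, cell, pool) {
  p <- as_candidate(p)
  pool <- as_pool(pool)
  b <- bucket_of(pool, p$chrom, p$strand)
  sup <- candidate_support(as_chain_matrix(p$chain), b$frags, b$introns)
  if (!cell %in% sup$share_cells) {
    stop(sprintf("cell '%s' expresses no junction of the path: pair violates the pairing rule", cell))
  }
  cell_from_support(sup, cell, p$member_cells)
}

#' Build the (candidate, cell) pair feature table
#'
#' One record per pair (p, c) such that at least one junction of p occurs
#' in a fragment of cell c. Each record carries the 30 general features of
#' p (identical across its cells) and the 21 cell-specific features of
#' (p, c), in deterministic (candidate_id, cell) order.
#'
#' @param paths Candidate table from \code{\link{assemble_candidates}}.
#' @param assemblies List of \code{cell_assembly} objects or a fragment
#'   table.
#' @return data.table with columns candidate_id, cell, chrom, strand,
#'   chain, then the 30 + 21 feature columns.
#' @export
build_pair_table <- function(paths, assemblies) {
  paths <- as.data.table(paths)
  pool <- as_pool(assemblies)
  empty <- data.table(candidate_id = integer(0), cell = character(0),
                      chrom = character(0), strand = character(0),
                      chain = character(0))
  for (nm in c(feature_names_general(), feature_names_cell())) {
    empty[, (nm) := numeric(0)]
  }
  if (nrow(paths) == 0L) return(empty[])
  out <- vector("list", nrow(paths))
  buckets <- unique(paths[, .(chrom, strand)])
  for (bi in seq_len(nrow(buckets))) {
    b <- bucket_of(pool, buckets$chrom[bi], buckets$strand[bi])
    rows <- which(paths$chrom == buckets$chrom[bi] &
                  paths$strand == buckets$strand[bi])
    for (i in rows) {
      pc <- as_candidate(paths[i])
      sup <- candidate_support(as_chain_matrix(pc$chain), b$frags, b$introns)
      if (!length(sup$share_cells)) next
      gf <- general_from_support(sup, pc$n_vertices, pc$member_cells,
                                 pc$member_scores)
      recs <- lapply(sup$share_cells, function(cc) {
        cf <- cell_from_support(sup, cc, pc$member_cells)
        c(list(candidate_id = pc$candidate_id, cell = cc, chrom = pc$chrom,
               strand = pc$strand, chain = pc$chain),
          as.list(gf), as.list(cf))
      })
      out[[i]] <- rbindlist(recs)
    }
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0L) return(empty[])
  setorder(res, candidate_id, cell)
  res[]
}

#' Export a feature table as TSV
#'
#' @param pairs Output of \code{\link{build_pair_table}}.
#' @param path Output file.
#' @export
pairs_tsv <- function(pairs, path) {
  fwrite(as.data.table(pairs), path, sep = "\t")
  invisible(path)
}
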