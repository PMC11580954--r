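## synthetic: self-contained simulator of fragmented per-cell assemblies.
##
## Emulates the dropout regime the assembler targets: a reference of
## multi-isoform genes, per-cell Bernoulli isoform expression, and
## per-cell fragmentation of expressed transcripts at exon boundaries so
## that the full-length chain often survives only as overlapping pieces
## spread across cells. Intact transcripts receive high reliability
## scores (Beta(5,2)), fragments low ones (Beta(2,5)); a small noise rate
## emits spurious chains with one perturbed junction to exercise the
## conflict rules.

#' Simulation configuration
#'
#' @param chroms Chromosome names (default chr1..chr12).
#' @param genes_per_chrom Genes per chromosome.
#' @param isoforms_per_gene Integer range c(lo, hi).
#' @param exons_per_gene Integer range c(lo, hi) of exons per gene.
#' @param n_cells Number of cells.
#' @param expr_prob Per-cell Bernoulli expression probability per isoform.
#' @param d_full Probability an expressed transcript survives intact in a
#'   cell; otherwise it is split at junction boundaries into fragments of
#'   at least 2 exons each.
#' @param noise_prob Probability, per emitted fragment, of additionally
#'   emitting a spurious copy with one junction perturbed by 10-50 bp.
#' @param score_full,score_partial Beta shape pairs for intact / partial
#'   fragment scores.
#' @param score_range Clamping range for scores.
#' @param fragment_only_frac Fraction of (>= 6 exon) isoforms forced to
#'   never appear intact in any cell; their full-length chains can then
#'   only be recovered by merging fragments across cells.
#' @param exon_len,intron_len,gene_gap Length ranges (bp) for gene
#'   construction.
#' @param seed RNG seed.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(chroms = paste0("chr", 1:12), genes_per_chrom = 6L,
                       isoforms_per_gene = c(1L, 5L),
                       exons_per_gene = c(4L, 10L), n_cells = 10L,
                       expr_prob = 0.4, d_full = 0.3, noise_prob = 0.02,
                       score_full = c(5, 2), score_partial = c(2, 5),
                       score_range = c(0.05, 1), fragment_only_frac = 0,
                       exon_len = c(100L, 300L), intron_len = c(200L, 2000L),
                       gene_gap = 10000L, seed = 1L) {
  probs <- c(expr_prob, d_full, noise_prob, fragment_only_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (exons_per_gene[1L] < 2L) stop("genes need at least 2 exons (multi-exon isoforms only)")
  structure(as.list(environment()), class = "sim_config")
}

## sample() treats a length-1 numeric vector as 1:n; always index instead
safe_sample <- function(v, k = 1L, replace = FALSE) {
  v[sample.int(length(v), k, replace = replace)]
}

sample_range <- function(r) safe_sample(seq.int(r[1L], r[2L]))

## split m exons into >=2-exon pieces at K junction boundaries; returns
## list of c(a, b) exon index ranges, or NULL meaning "emit intact"
sample_split <- function(m) {
  kmax <- m %/% 2L - 1L
  if (kmax < 1L) return(NULL)
  K <- sample.int(kmax, 1L)
  pos <- NULL
  lo <- 2L; hi <- m - 2L
  for (try in 1:100) {
    cand <- sort(safe_sample(seq.int(lo, hi), K))
    if (K == 1L || all(diff(cand) >= 2L)) { pos <- cand; break }
  }
  if (is.null(pos)) pos <- safe_sample(seq.int(lo, hi))
  bounds <- c(0L, pos, m)
  lapply(seq_len(length(bounds) - 1L),
         function(i) c(bounds[i] + 1L, bounds[i + 1L]))
}

## exact reachability check: can fragments (junction-index intervals)
## chain left-to-right through suffix/prefix overlaps to cover 1..J?
chain_coverable <- function(ints, J) {
  if (!nrow(ints)) return(FALSE)
  if (any(ints[, 1L] == 1L & ints[, 2L] == J)) return(TRUE)
  o <- order(ints[, 2L], ints[, 1L])
  a <- ints[o, 1L]; b <- ints[o, 2L]
  n <- length(a)
  reach <- a == 1L
  for (i in seq_len(n)) {
    if (reach[i]) next
    for (j in seq_len(n)) {
      if (reach[j] && a[j] <= a[i] && a[i] <= b[j] && b[i] > b[j]) {
        reach[i] <- TRUE; break
      }
    }
  }
  any(reach & b == J)
}

perturb_chain <- function(chain_mat, tx_start, tx_end) {
  r <- sample.int(nrow(chain_mat), 1L)
  side <- sample(1:2, 1L)
  delta <- sample(10:50, 1L) * sample(c(-1L, 1L), 1L)
  m <- chain_mat
  m[r, side] <- m[r, side] + delta
  ## validity: introns ordered/disjoint, >= 20 bp, exons >= 10 bp
  if (m[r, 1L] >= m[r, 2L] - 18L) return(NULL)
  ex <- tryCatch(exons_from_chain(m, tx_start, tx_end), error = function(e) NULL)
  if (is.null(ex)) return(NULL)
  if (any(ex[, 2L] - ex[, 1L] + 1L < 10L)) return(NULL)
  if (is.unsorted(as.vector(t(m)), strictly = TRUE)) return(NULL)
  m
}

#' Generate a synthetic study: reference, per-cell truth, scored inputs
#'
#' Genes are placed without overlap; isoforms of a gene share a junction
#' backbone with skipped-exon and alternative-boundary variants. Each cell
#' expresses each isoform independently; expressed transcripts are
#' emitted intact with probability \code{d_full}, otherwise split at
#' junction boundaries into multi-exon fragments. For every isoform
#' expressed in at least \code{ceiling(1/d_full)} cells (2 for forced
#' fragment-only isoforms) the generator verifies that the union of its
#' fragments across cells can be chained back to full length through
#' suffix/prefix overlaps, resampling the fragmentation otherwise.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return Object of class \code{sim_bundle}: list with \code{reference}
#'   (transcript table), \code{truth} (per-cell expressed transcripts),
#'   \code{assemblies} (list of \code{cell_assembly}),
#'   \code{fragment_only_ids}, \code{emission_log} (cell, transcript_id,
#'   intact, n_fragments) and \code{config}.
#' @export
generate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## ---- reference construction
  ref_rows <- list()
  iso_exons <- list()
  for (ch in cfg$chroms) {
    cursor <- 10000L
    for (g in seq_len(cfg$genes_per_chrom)) {
      n_e <- sample_range(cfg$exons_per_gene)
      ex_w <- safe_sample(seq.int(cfg$exon_len[1L], cfg$exon_len[2L]), n_e, replace = TRUE)
      in_w <- safe_sample(seq.int(cfg$intron_len[1L], cfg$intron_len[2L]),
                     max(n_e - 1L, 0L), replace = TRUE)
      starts <- integer(n_e); ends <- integer(n_e)
      pos <- cursor
      for (i in seq_len(n_e)) {
        starts[i] <- pos; ends[i] <- pos + ex_w[i] - 1L
        pos <- ends[i] + (if (i < n_e) in_w[i] else 0L) + 1L
      }
      gene_ex <- cbind(start = starts, end = ends)
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("%s.g%02d", ch, g)
      n_iso <- sample_range(cfg$isoforms_per_gene)
      ## isoform variants share the junction backbone: skipped internal
      ## exons and alternative donor/acceptor boundaries (no truncations,
      ## so no isoform chain is a subchain of a sibling's)
      iso_list <- list(gene_ex)
      iso_keys <- format_chain(introns_from_exons(gene_ex))
      tries <- 0L
      while (length(iso_list) < n_iso && tries < 60L) {
        tries <- tries + 1L
        type <- sample(c("skip", "alt"), 1L)
        exm <- NULL
        if (type == "skip" && n_e >= 3L) {
          exm <- gene_ex[-safe_sample(seq.int(2L, n_e - 1L)), , drop = FALSE]
        } else if (type == "alt") {
          i <- safe_sample(seq_len(n_e - 1L))
          delta <- safe_sample(c(-1L, 1L)) * safe_sample(20:80)
          exm <- gene_ex
          if (sample(1:2, 1L) == 1L) exm[i, 2L] <- exm[i, 2L] + delta
          else exm[i + 1L, 1L] <- exm[i + 1L, 1L] + delta
          widths <- exm[, 2L] - exm[, 1L] + 1L
          gaps <- exm[-1L, 1L] - exm[-nrow(exm), 2L] - 1L
          if (any(widths < 20L) || any(gaps < 20L)) exm <- NULL
        }
        if (is.null(exm)) next
        key <- format_chain(introns_from_exons(exm))
        if (key %in% iso_keys) next
        iso_list[[length(iso_list) + 1L]] <- exm
        iso_keys <- c(iso_keys, key)
      }
      for (k in seq_along(iso_list)) {
        exm <- iso_list[[k]]
        tid <- sprintf("%s.i%d", gene_id, k)
        iso_exons[[tid]] <- exm
        ref_rows[[length(ref_rows) + 1L]] <- data.table(
          transcript_id = tid, gene_id = gene_id, chrom = ch, strand = strand,
          tx_start = exm[1L, 1L], tx_end = exm[nrow(exm), 2L],
          chain = format_chain(introns_from_exons(exm)),
          n_exons = nrow(exm))
      }
      cursor <- pos + cfg$gene_gap
    }
  }
  reference <- rbindlist(ref_rows)

  clamp_score <- function(x) pmin(pmax(x, cfg$score_range[1L]), cfg$score_range[2L])
  draw_full <- function(n) clamp_score(rbeta(n, cfg$score_full[1L], cfg$score_full[2L]))
  draw_part <- function(n) clamp_score(rbeta(n, cfg$score_partial[1L], cfg$score_partial[2L]))

  ## forced fragment-only isoforms (recoverable only by cross-cell merging);
  ## eligibility needs >= 6 exons: a split discards its boundary junction,
  ## so full-length recovery requires two cells whose split positions
  ## differ by >= 2, which is impossible below 6 exons
  eligible <- reference[n_exons >= 6L, transcript_id]
  n_forced <- round(cfg$fragment_only_frac * nrow(reference))
  fragment_only_ids <- if (n_forced > 0L && length(eligible)) {
    sort(safe_sample(eligible, min(n_forced, length(eligible))))
  } else character(0)

  cells <- if (cfg$n_cells > 0L) sprintf("c%03d", seq_len(cfg$n_cells)) else character(0)
  n_iso <- nrow(reference)
  expressed <- matrix(runif(n_iso * cfg$n_cells) < cfg$expr_prob,
                      nrow = n_iso, ncol = cfg$n_cells)

  ## emit fragments for one isoform in one cell
  emit_one <- function(tid, forced) {
    m <- nrow(iso_exons[[tid]])
    intact <- !forced && (runif(1) < cfg$d_full || m < 4L)
    if (!intact && m < 4L) intact <- TRUE   # unsplittable, forced or not
    if (intact) {
      list(list(a = 1L, b = m, score = draw_full(1L), intact = TRUE))
    } else {
      pieces <- sample_split(m)
      lapply(pieces, function(pb)
        list(a = pb[1L], b = pb[2L], score = draw_part(1L), intact = FALSE))
    }
  }

  ## emissions[[tid]][[cell]] = list of fragment records
  emissions <- list()
  for (t_i in seq_len(n_iso)) {
    tid <- reference$transcript_id[t_i]
    forced <- tid %in% fragment_only_ids
    percell <- list()
    for (c_i in which(expressed[t_i, ])) {
      percell[[cells[c_i]]] <- emit_one(tid, forced)
    }
    emissions[[tid]] <- percell
  }

  ## recoverability: resample fragmentation where the cross-cell union of
  ## fragments cannot be chained back to the full-length chain
  min_cells_default <- if (cfg$d_full > 0) ceiling(1 / cfg$d_full) else Inf
  for (tid in names(emissions)) {
    percell <- emissions[[tid]]
    if (!length(percell)) next
    m <- nrow(iso_exons[[tid]])
    J <- m - 1L
    if (J < 1L) next
    forced <- tid %in% fragment_only_ids
    need <- if (forced) 2L else min_cells_default
    if (length(percell) < need) next
    for (try in 1:30) {
      ints <- do.call(rbind, lapply(unlist(percell, recursive = FALSE),
                                    function(fr) c(fr$a, fr$b - 1L)))
      ints <- ints[ints[, 2L] >= ints[, 1L], , drop = FALSE]
      if (chain_coverable(ints, J)) break
      percell <- lapply(percell, function(old) emit_one(tid, forced))
      names(percell) <- names(emissions[[tid]])
    }
    emissions[[tid]] <- percell
  }

  ## ---- assemble outputs
  truth_rows <- list(); frag_rows <- list(); log_rows <- list()
  for (c_i in seq_along(cells)) {
    cc <- cells[c_i]
    for (t_i in which(expressed[, c_i])) {
      tid <- reference$transcript_id[t_i]
      ref <- reference[t_i]
      truth_rows[[length(truth_rows) + 1L]] <-
        data.table(cell = cc, transcript_id = tid, gene_id = ref$gene_id,
                   chrom = ref$chrom, strand = ref$strand,
                   tx_start = ref$tx_start, tx_end = ref$tx_end,
                   chain = ref$chain)
      frs <- emissions[[tid]][[cc]]
      if (is.null(frs)) next
      exm <- iso_exons[[tid]]
      log_rows[[length(log_rows) + 1L]] <-
        data.table(cell = cc, transcript_id = tid,
                   intact = frs[[1L]]$intact, n_fragments = length(frs),
                   n_exons = nrow(exm))
      for (fr in frs) {
        sub <- exm[fr$a:fr$b, , drop = FALSE]
        ch_mat <- introns_from_exons(sub)
        rec <- data.table(cell = cc, origin = tid, chrom = ref$chrom,
                          strand = ref$strand, tx_start = sub[1L, 1L],
                          tx_end = sub[nrow(sub), 2L],
                          chain = format_chain(ch_mat), score = fr$score)
        frag_rows[[length(frag_rows) + 1L]] <- rec
        if (cfg$noise_prob > 0 && runif(1) < cfg$noise_prob) {
          pm <- perturb_chain(ch_mat, sub[1L, 1L], sub[nrow(sub), 2L])
          if (!is.null(pm)) {
            frag_rows[[length(frag_rows) + 1L]] <-
              data.table(cell = cc, origin = paste0(tid, ".noise"),
                         chrom = ref$chrom, strand = ref$strand,
                         tx_start = sub[1L, 1L], tx_end = sub[nrow(sub), 2L],
                         chain = format_chain(pm), score = draw_part(1L))
          }
        }
      }
    }
  }
  truth <- if (length(truth_rows)) rbindlist(truth_rows) else
    data.table(cell = character(0), transcript_id = character(0),
               gene_id = character(0), chrom = character(0),
               strand = character(0), tx_start = integer(0),
               tx_end = integer(0), chain = character(0))
  frags <- if (length(frag_rows)) rbindlist(frag_rows) else
    data.table(cell = character(0), origin = character(0),
               chrom = character(0), strand = character(0),
               tx_start = integer(0), tx_end = integer(0),
               chain = character(0), score = numeric(0))
  assemblies <- lapply(cells, function(cc) {
    fr <- frags[cell == cc]
    fr[, id := sprintf("%s.f%04d", cc, seq_len(.N))]
    make_cell_assembly(fr[, .(id, chrom, strand, tx_start, tx_end, chain, score)], cc)
  })
  names(assemblies) <- cells
  structure(list(reference = reference, truth = truth,
                 assemblies = assemblies,
                 fragment_only_ids = fragment_only_ids,
                 emission_log = if (length(log_rows)) rbindlist(log_rows) else
                   data.table(cell = character(0), transcript_id = character(0),
                              intact = logical(0), n_fragments = integer(0),
                              n_exons = integer(0)),
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d isoforms on %d chroms, %d cells, %d truth records, %d fragment-only isoforms\n",
              nrow(x$reference), length(unique(x$reference$chrom)),
              length(x$assemblies), nrow(x$truth),
              length(x$fragment_only_ids)))
  invisible(x)
}

#' Preset end-to-end recovery scenario
#'
#' 30 cells over six chromosomes (chr7-chr9 fall in the default training
#' set, chr10-chr12 are held out), roughly 200 isoforms with 4-10 exons,
#' d_full = 0.25, and 30\% of isoforms forced to appear only as fragments
#' in every cell — recovering those full-length is attributable solely to
#' the cross-cell fragment graph and path search.
#'
#' @param seed RNG seed.
#' @return A \code{sim_bundle}; \code{$fragment_only_ids} lists the
#'   forced fragment-only isoforms, \code{$train_chroms} /
#'   \code{$test_chroms} the split.
#' @export
scenario_recoverable <- function(seed = 1L) {
  cfg <- sim_config(chroms = paste0("chr", 7:12), genes_per_chrom = 12L,
                    isoforms_per_gene = c(2L, 4L), exons_per_gene = c(4L, 10L),
                    n_cells = 30L, expr_prob = 0.4, d_full = 0.25,
                    noise_prob = 0.02, fragment_only_frac = 0.30, seed = seed)
  bundle <- generate_cells(cfg)
  bundle$train_chroms <- paste0("chr", 7:9)
  bundle$test_chroms <- paste0("chr", 10:12)
  bundle
}

#' Write a simulation bundle to GTF files plus a manifest
#'
#' @param bundle A \code{sim_bundle}.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest TSV (columns cell, input, truth),
#'   invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "input"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  ref <- copy(bundle$reference)[, score := 1]
  write_cell_gtf(file.path(dir, "reference.gtf"), ref)
  rows <- lapply(names(bundle$assemblies), function(cc) {
    fin <- file.path(dir, "input", paste0(cc, ".gtf"))
    ftr <- file.path(dir, "truth", paste0(cc, ".gtf"))
    fr <- copy(bundle$assemblies[[cc]]$fragments)
    fr[, transcript_id := id]
    write_cell_gtf(fin, fr)
    tr <- copy(bundle$truth[cell == cc])[, score := 1]
    write_cell_gtf(ftr, tr)
    data.table(cell = cc, input = fin, truth = ftr)
  })
  manifest <- file.path(dir, "manifest.tsv")
  fwrite(rbindlist(rows), manifest, sep = "\t")
  invisible(manifest)
}
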