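## gtf_io: read/write scored GTF transcript models and derive intron chains.

#' Construct a cell assembly from a fragment table
#'
#' Low-level constructor used by the simulator and by tests; applies the
#' same invariants as \code{\link{read_cell_gtf}}: multi-exon only, scores
#' clamped to \[0,1\], duplicate intron chains within the cell resolved by
#' keeping the highest score.
#'
#' @param fragments data.table/data.frame with columns \code{id},
#'   \code{chrom}, \code{strand}, \code{tx_start}, \code{tx_end},
#'   \code{chain} (intron chain string, non-empty), \code{score}.
#' @param cell Cell identifier.
#' @return Object of class \code{cell_assembly}: a list with \code{cell},
#'   \code{fragments} (data.table) and \code{n_single_exon}.
#' @export
make_cell_assembly <- function(fragments, cell) {
  fr <- as.data.table(fragments)
  needed <- c("id", "chrom", "strand", "tx_start", "tx_end", "chain", "score")
  miss <- setdiff(needed, names(fr))
  if (length(miss)) stop("fragment table lacks columns: ", paste(miss, collapse = ", "))
  fr <- fr[, needed, with = FALSE]
  single <- !nzchar(fr$chain)
  n_single <- sum(single)
  fr <- fr[!single]
  fr[, score := pmin(pmax(score, 0), 1)]
  fr[, nj := vapply(chain, function(ch) nrow(parse_chain(ch)), integer(1))]
  ## duplicate chains within a cell: keep highest score
  setorder(fr, chrom, strand, chain, -score, id)
  fr <- fr[!duplicated(full_chain_key(chrom, strand, chain))]
  setorder(fr, chrom, tx_start, chain, id)
  structure(list(cell = as.character(cell), fragments = fr[],
                 n_single_exon = n_single),
            class = "cell_assembly")
}

#' @export
print.cell_assembly <- function(x, ...) {
  cat(sprintf("<cell_assembly> cell=%s  %d multi-exon fragments (%d single-exon dropped)\n",
              x$cell, nrow(x$fragments), x$n_single_exon))
  invisible(x)
}

#' Read one cell's scored transcript fragments from a GTF file
#'
#' Parses a GTF (Ensembl dialect) of assembled transcripts, derives each
#' transcript's intron chain from its exon features, and attaches a
#' reliability score in \[0,1\] taken from a configurable attribute.
#' Single-exon transcripts are counted and dropped: the method operates on
#' intron chains and can only extend transcripts with at least one
#' junction.
#'
#' If the score attribute contains values above 1 (raw coverage from an
#' upstream assembler), scores are first normalized to \[0,1\]:
#' \code{"squash"} applies x/(x+1), \code{"minmax"} rescales per cell by
#' the observed range, \code{"none"} only clamps.
#'
#' @param path GTF file path.
#' @param cell_id Cell identifier attached to every fragment.
#' @param score_attribute Name of the GTF attribute carrying the score
#'   (default \code{"cov"}); looked up on transcript lines first, then on
#'   exon lines.
#' @param fallback_score Constant used when the attribute is absent;
#'   if \code{NULL} (default) a missing attribute is an error.
#' @param normalize One of \code{"squash"}, \code{"minmax"}, \code{"none"};
#'   applied only when raw values exceed 1.
#' @return A \code{cell_assembly}.
#' @export
read_cell_gtf <- function(path, cell_id, score_attribute = "cov",
                          fallback_score = NULL,
                          normalize = c("squash", "minmax", "none")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  is_exon <- as.character(mc$type) == "exon"
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  if (length(ex) == 0L) {
    return(make_cell_assembly(
      data.table(id = character(0), chrom = character(0), strand = character(0),
                 tx_start = integer(0), tx_end = integer(0),
                 chain = character(0), score = numeric(0)),
      cell_id))
  }
  tid <- as.character(exm$transcript_id)
  if (anyNA(tid) || any(!nzchar(tid))) {
    bad <- which(is.na(tid) | !nzchar(tid))[1L]
    stop(sprintf("exon feature #%d in %s lacks a transcript_id attribute", bad, path))
  }

  ## per-transcript score: transcript feature first, else exon features.
  ## When the attribute is named "score", rtracklayer exposes it as
  ## "score.1" (plain "score" is GFF column 6); prefer the attribute and
  ## fall back to the column.
  get_attr <- function(meta) {
    for (nm in c(paste0(score_attribute, ".1"), score_attribute)) {
      if (nm %in% names(meta)) {
        v <- suppressWarnings(as.numeric(as.character(meta[[nm]])))
        if (any(!is.na(v))) return(v)
      }
    }
    rep(NA_real_, nrow(meta))
  }
  tx_rows <- as.character(mc$type) == "transcript"
  score_map <- new.env(parent = emptyenv())
  if (any(tx_rows)) {
    tmeta <- S4Vectors::mcols(gr[tx_rows])
    tsc <- get_attr(tmeta)
    tids <- as.character(tmeta$transcript_id)
    for (i in seq_along(tids)) {
      if (!is.na(tsc[i])) assign(tids[i], tsc[i], envir = score_map)
    }
  }
  esc <- get_attr(exm)

  exdt <- data.table(
    id = tid,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(ex))),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    escore = esc
  )
  setorder(exdt, id, start, end)

  one_tx <- function(sd, tid1) {
    ## merge overlapping/adjacent exon records
    s <- sd$start; e <- sd$end
    keep_s <- s[1L]; keep_e <- e[1L]
    if (length(s) > 1L) {
      ms <- integer(0); me <- integer(0)
      for (i in 2L:length(s)) {
        if (s[i] <= keep_e + 1L) keep_e <- max(keep_e, e[i]) else {
          ms <- c(ms, keep_s); me <- c(me, keep_e)
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
      s <- c(ms, keep_s); e <- c(me, keep_e)
    } else { s <- keep_s; e <- keep_e }
    sc <- if (!is.null(get0(tid1, envir = score_map))) get0(tid1, envir = score_map)
          else if (any(!is.na(sd$escore))) max(sd$escore, na.rm = TRUE)
          else NA_real_
    list(chrom = sd$chrom[1L], strand = sd$strand[1L],
         tx_start = s[1L], tx_end = e[length(e)],
         chain = format_chain(introns_from_exons(cbind(s, e))),
         score = sc)
  }
  frags <- exdt[, one_tx(.SD, .BY[[1L]]), by = id]

  if (anyNA(frags$score)) {
    if (is.null(fallback_score)) {
      stop(sprintf("attribute '%s' missing for transcript(s) %s in %s and no fallback_score configured",
                   score_attribute,
                   paste(head(frags$id[is.na(frags$score)], 3L), collapse = ", "), path))
    }
    frags[is.na(score), score := fallback_score]
  }
  if (any(frags$score > 1)) {
    frags[, score := switch(normalize,
      squash = score / (score + 1),
      minmax = if (diff(range(score)) > 0) (score - min(score)) / diff(range(score)) else rep(1, .N),
      none = score)]
  }
  make_cell_assembly(frags, cell_id)
}

#' Write scored transcripts to a GTF file
#'
#' Emits one \code{transcript} line plus \code{exon} lines per record, with
#' the model probability in attribute \code{score} at 4 decimal places.
#' Records are written in deterministic order (chrom, transcript start,
#' intron chain, id) so identical inputs yield byte-identical files.
#'
#' @param path Output file path.
#' @param transcripts data.table/data.frame with columns \code{chrom},
#'   \code{strand}, \code{tx_start}, \code{tx_end}, \code{chain},
#'   \code{score}; optional \code{transcript_id}, \code{gene_id},
#'   \code{cell}.
#' @return Invisibly, the path.
#' @export
write_cell_gtf <- function(path, transcripts) {
  tx <- as.data.table(transcripts)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("## txmend scored transcript models", con)
  if (nrow(tx) == 0L) return(invisible(path))
  if (!"transcript_id" %in% names(tx)) tx[, transcript_id := sprintf("tx.%06d", .I)]
  if (!"gene_id" %in% names(tx)) tx[, gene_id := transcript_id]
  tx[, key_ := padded_chain_key(chain)]
  setorder(tx, chrom, tx_start, key_, transcript_id)
  cell_attr <- if ("cell" %in% names(tx)) sprintf(" cell \"%s\";", tx$cell) else ""
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    at <- sprintf("gene_id \"%s\"; transcript_id \"%s\"; score \"%.4f\";%s",
                  tx$gene_id[i], tx$transcript_id[i], tx$score[i],
                  if (length(cell_attr) > 1L) cell_attr[i] else cell_attr)
    ex <- exons_from_chain(tx$chain[i], tx$tx_start[i], tx$tx_end[i])
    lines <- c(lines,
      paste(tx$chrom[i], "txmend", "transcript", tx$tx_start[i], tx$tx_end[i],
            ".", tx$strand[i], ".", at, sep = "\t"),
      paste(tx$chrom[i], "txmend", "exon", ex[, 1L], ex[, 2L],
            ".", tx$strand[i], ".", at, sep = "\t"))
  }
  writeLines(lines, con)
  invisible(path)
}
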