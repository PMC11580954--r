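## Intron-chain primitives shared by all modules.
##
## A chain is the ordered list of introns (junctions) of a multi-exon
## transcript. Coordinates are GTF-style: 1-based, inclusive, with an
## intron spanning the first to the last intronic base. Internally a chain
## travels either as a 2-column integer matrix (start, end) or as its
## canonical string form "start-end,start-end,..." which doubles as the
## equality/hash key within a (chrom, strand) bucket.

#' Parse a chain string into an intron matrix
#'
#' @param chain Character scalar like \code{"201-299,401-499"}.
#' @return Integer matrix with columns \code{start}, \code{end}, one row per
#'   intron, in genomic order.
#' @export
#' @examples
#' parse_chain("201-299,401-499")
parse_chain <- function(chain) {
  stopifnot(is.character(chain), length(chain) == 1L)
  if (!nzchar(chain)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(chain, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  if (anyNA(m)) stop("malformed chain string: ", chain)
  m
}

#' Format an intron matrix as a chain string
#'
#' @param introns Integer matrix with columns start, end.
#' @return Canonical chain string.
#' @export
format_chain <- function(introns) {
  if (is.null(introns) || nrow(introns) == 0L) return("")
  paste(paste0(introns[, 1L], "-", introns[, 2L]), collapse = ",")
}

## Coerce either representation to a matrix.
as_chain_matrix <- function(chain) {
  if (is.character(chain)) parse_chain(chain) else {
    stopifnot(is.matrix(chain), ncol(chain) == 2L)
    storage.mode(chain) <- "integer"
    colnames(chain) <- c("start", "end")
    chain
  }
}

#' Derive the intron chain from an exon chain
#'
#' Introns are exactly the gaps between consecutive exons: for exons
#' (s1,e1),(s2,e2) the intron is (e1+1, s2-1).
#'
#' @param exons Integer matrix with columns start, end; sorted,
#'   non-overlapping, non-adjacent.
#' @return Intron matrix with \code{nrow(exons) - 1} rows.
#' @export
introns_from_exons <- function(exons) {
  exons <- as_chain_matrix(exons)
  n <- nrow(exons)
  if (n == 0L) stop("empty exon chain")
  if (is.unsorted(exons[, 1L])) stop("exons must be sorted by start")
  if (n == 1L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  s <- exons[-n, 2L] + 1L
  e <- exons[-1L, 1L] - 1L
  if (any(e < s)) stop("exons must be non-overlapping and non-adjacent (gap >= 1)")
  cbind(start = s, end = e)
}

#' Reconstruct the exon chain implied by an intron chain
#'
#' @param chain Intron chain (string or matrix).
#' @param tx_start,tx_end Transcript start/end (first exon start, last exon
#'   end).
#' @return Exon matrix with \code{n_introns + 1} rows.
#' @export
exons_from_chain <- function(chain, tx_start, tx_end) {
  m <- as_chain_matrix(chain)
  if (nrow(m) == 0L) {
    return(cbind(start = as.integer(tx_start), end = as.integer(tx_end)))
  }
  if (tx_start >= m[1L, 1L] || tx_end <= m[nrow(m), 2L]) {
    stop("transcript bounds must enclose the intron chain")
  }
  cbind(start = as.integer(c(tx_start, m[, 2L] + 1L)),
        end   = as.integer(c(m[, 1L] - 1L, tx_end)))
}

## Zero-padded chain key giving lexicographic order consistent with the
## numeric order of the junction sequence (used only for tie-breaking).
padded_chain_key <- function(chain) {
  vapply(chain, function(ch) {
    m <- parse_chain(ch)
    paste(sprintf("%012d-%012d", m[, 1L], m[, 2L]), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

## Full identity key of a transcript model across buckets.
full_chain_key <- function(chrom, strand, chain) {
  paste(chrom, strand, chain, sep = "|")
}

## Long-format intron table for a fragment data.table (columns uid, chain).
explode_introns <- function(dt, id_col = "uid") {
  if (nrow(dt) == 0L) {
    out <- data.table(uid = integer(0), idx = integer(0),
                      start = integer(0), end = integer(0))
    if (id_col != "uid") setnames(out, "uid", id_col)
    return(out)
  }
  mats <- lapply(dt[["chain"]], parse_chain)
  nper <- vapply(mats, nrow, integer(1))
  out <- data.table(
    uid   = rep(dt[[id_col]], nper),
    idx   = unlist(lapply(nper, seq_len), use.names = FALSE),
    start = unlist(lapply(mats, function(m) m[, 1L]), use.names = FALSE),
    end   = unlist(lapply(mats, function(m) m[, 2L]), use.names = FALSE)
  )
  if (id_col != "uid") setnames(out, "uid", id_col)
  out
}
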