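## fragment_graph: directed transcript fragment graph over all cells.
##
## Vertices are distinct (chrom, strand, intron chain) triples pooled
## across cells; a directed edge u -> v exists iff a non-empty suffix of
## u's junction list equals a prefix of v's junction list AND v extends
## strictly to the right of u (strict extension + identical-chain merging
## make the graph acyclic by construction).

#' Pool fragments from several cell assemblies into one table
#'
#' @param assemblies List of \code{cell_assembly} objects (or a single one).
#' @return data.table with one row per input fragment: \code{uid},
#'   \code{cell}, \code{id}, \code{chrom}, \code{strand}, \code{tx_start},
#'   \code{tx_end}, \code{nj}, \code{chain}, \code{score}.
#' @export
fragment_pool <- function(assemblies) {
  if (inherits(assemblies, "cell_assembly")) assemblies <- list(assemblies)
  tabs <- lapply(assemblies, function(a) {
    fr <- copy(a$fragments)
    if (nrow(fr)) fr[, cell := a$cell] else fr[, cell := character(0)]
    fr
  })
  pool <- rbindlist(tabs, use.names = TRUE, fill = TRUE)
  if (nrow(pool) == 0L) {
    pool <- data.table(id = character(0), chrom = character(0),
                       strand = character(0), tx_start = integer(0),
                       tx_end = integer(0), chain = character(0),
                       score = numeric(0), nj = integer(0), cell = character(0))
  }
  pool[, uid := .I]
  setcolorder(pool, c("uid", "cell", "id", "chrom", "strand",
                      "tx_start", "tx_end", "nj", "chain", "score"))
  pool[]
}

#' Test the suffix/prefix intron-chain overlap predicate
#'
#' TRUE iff there is a k >= 1 such that the last k junctions of \code{u}
#' equal the first k junctions of \code{v} and \code{v} extends strictly
#' beyond \code{u} (v's last intron end > u's last intron end). Identical
#' chains return FALSE: they are merged into one vertex upstream, and the
#' strict-extension rule is what keeps the graph acyclic.
#'
#' @param u,v Intron chains: chain strings, intron matrices, or lists with
#'   a \code{chain} element. Both are assumed to lie on the same chromosome
#'   and strand.
#' @return Logical scalar.
#' @export
#' @examples
#' suffix_prefix_overlap("100-200,300-400", "300-400,500-600") # TRUE, k = 1
#' suffix_prefix_overlap("100-200", "100-200")                 # FALSE
suffix_prefix_overlap <- function(u, v) {
  get_chain <- function(x) {
    if (is.list(x) && !is.null(x$chain)) x <- x$chain
    as_chain_matrix(x)
  }
  mu <- get_chain(u); mv <- get_chain(v)
  nu <- nrow(mu); nv <- nrow(mv)
  if (nu == 0L || nv == 0L) return(FALSE)
  if (mv[nv, 2L] <= mu[nu, 2L]) return(FALSE)  # no strict rightward extension
  for (k in seq_len(min(nu, nv))) {
    if (all(mu[(nu - k + 1L):nu, , drop = FALSE] == mv[seq_len(k), , drop = FALSE])) {
      return(TRUE)
    }
  }
  FALSE
}

#' Build the transcript fragment graph
#'
#' Collapses fragments with identical (chrom, strand, chain) across all
#' cells into single vertices (retaining every member), then adds every
#' directed edge allowed by \code{\link{suffix_prefix_overlap}}. The graph
#' is bucketed by (chrom, strand): no cross-chromosome or cross-strand
#' edges exist, and unstranded (".") fragments never connect to stranded
#' ones.
#'
#' @param assemblies List of \code{cell_assembly} objects, or a fragment
#'   pool table from \code{\link{fragment_pool}}.
#' @return Object of class \code{fragment_graph}: list with
#'   \code{vertices} (vid, chrom, strand, chain, nj, span_start, span_end,
#'   tx_start, tx_end, n_members, comp), \code{members} (vid, uid, cell,
#'   id, score), \code{edges} (from, to, k), \code{chains} (list of intron
#'   matrices indexed by vid) and \code{pool} (the fragment pool).
#' @export
build_graph <- function(assemblies) {
  pool <- if (is.data.frame(assemblies)) as.data.table(assemblies)
          else fragment_pool(assemblies)
  if (nrow(pool) == 0L) {
    g <- structure(list(
      vertices = data.table(vid = integer(0), chrom = character(0),
                            strand = character(0), chain = character(0),
                            nj = integer(0), span_start = integer(0),
                            span_end = integer(0), tx_start = integer(0),
                            tx_end = integer(0), n_members = integer(0),
                            comp = integer(0)),
      members = data.table(vid = integer(0), uid = integer(0),
                           cell = character(0), id = character(0),
                           score = numeric(0)),
      edges = data.table(from = integer(0), to = integer(0), k = integer(0)),
      chains = list(), pool = pool), class = "fragment_graph")
    return(g)
  }

  pool[, key_ := full_chain_key(chrom, strand, chain)]
  verts <- pool[, .(chrom = chrom[1L], strand = strand[1L], chain = chain[1L],
                    nj = nj[1L], tx_start = min(tx_start), tx_end = max(tx_end),
                    n_members = .N),
                by = key_]
  setorder(verts, chrom, strand, chain)
  verts[, vid := .I]
  chains <- lapply(verts$chain, parse_chain)
  verts[, span_start := vapply(chains, function(m) m[1L, 1L], integer(1))]
  verts[, span_end := vapply(chains, function(m) m[nrow(m), 2L], integer(1))]

  members <- merge(pool[, .(key_, uid, cell, id, score)],
                   verts[, .(key_, vid)], by = "key_")[, key_ := NULL][]
  setorder(members, vid, cell, id)
  pool[, key_ := NULL]
  verts[, key_ := NULL]

  ## candidate edges: v's first junction occurs somewhere in u's chain
  jlong <- verts[, {
    m <- chains[[vid]]
    .(pos = seq_len(nrow(m)), jkey = paste0(m[, 1L], "-", m[, 2L]))
  }, by = .(vid, chrom, strand)]
  firstj <- jlong[pos == 1L, .(to = vid, chrom, strand, jkey)]
  cand <- merge(jlong[, .(from = vid, chrom, strand, jkey, pos)], firstj,
                by = c("chrom", "strand", "jkey"), allow.cartesian = TRUE)
  cand <- cand[from != to]

  edges <- data.table(from = integer(0), to = integer(0), k = integer(0))
  if (nrow(cand)) {
    nu <- verts$nj[cand$from]
    nv <- verts$nj[cand$to]
    k <- nu - cand$pos + 1L
    ext <- verts$span_end[cand$to] > verts$span_end[cand$from]
    cand <- cand[k <= nv & ext]
    k <- k[k <= nv & ext]
    if (nrow(cand)) {
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        mu <- chains[[cand$from[i]]]; mv <- chains[[cand$to[i]]]
        ki <- k[i]
        all(mu[(nrow(mu) - ki + 1L):nrow(mu), , drop = FALSE] ==
            mv[seq_len(ki), , drop = FALSE])
      }, logical(1))
      edges <- unique(data.table(from = cand$from[ok], to = cand$to[ok],
                                 k = k[ok]))
      setorder(edges, from, to)
    }
  }

  ig <- igraph::graph_from_data_frame(
    edges[, .(from = as.character(from), to = as.character(to))],
    directed = TRUE, vertices = data.frame(name = as.character(verts$vid)))
  if (!igraph::is_dag(ig)) stop("internal error: fragment graph contains a cycle")
  comp <- igraph::components(ig, mode = "weak")$membership
  verts[, comp := as.integer(comp[as.character(vid)])]

  structure(list(vertices = verts[], members = members, edges = edges,
                 chains = chains, pool = pool),
            class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("<fragment_graph> %d vertices, %d edges, %d components, %d member fragments\n",
              nrow(x$vertices), nrow(x$edges),
              if (nrow(x$vertices)) length(unique(x$vertices$comp)) else 0L,
              nrow(x$members)))
  invisible(x)
}

#' Split a fragment graph into weakly connected components
#'
#' Isolated vertices form singleton components; they still yield candidate
#' paths downstream.
#'
#' @param graph A \code{fragment_graph}.
#' @return List of \code{fragment_component} objects, each with
#'   \code{component_id}, \code{chrom}, \code{strand}, \code{vertices},
#'   \code{edges}, \code{chains} (indexed by vid) and \code{members}.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "fragment_graph"))
  if (nrow(graph$vertices) == 0L) return(list())
  comps <- sort(unique(graph$vertices$comp))
  lapply(comps, function(cid) {
    vs <- graph$vertices[comp == cid]
    es <- graph$edges[from %in% vs$vid & to %in% vs$vid]
    structure(list(component_id = cid, chrom = vs$chrom[1L],
                   strand = vs$strand[1L], vertices = vs, edges = es,
                   chains = graph$chains[vs$vid],
                   members = graph$members[vid %in% vs$vid]),
              class = "fragment_component")
  })
}

#' Dump a fragment graph as a TSV edge list or DOT text
#'
#' @param graph A \code{fragment_graph}.
#' @param path Output file; for \code{graph_edges_tsv}, \code{NULL} returns
#'   the table instead of writing.
#' @return The edge table (TSV) or DOT string, invisibly when written.
#' @export
graph_edges_tsv <- function(graph, path = NULL) {
  v <- graph$vertices
  e <- merge(merge(graph$edges, v[, .(from = vid, from_chain = chain)], by = "from"),
             v[, .(to = vid, to_chain = chain, chrom, strand)], by = "to")
  setcolorder(e, c("chrom", "strand", "from", "to", "k", "from_chain", "to_chain"))
  setorder(e, chrom, strand, from, to)
  if (is.null(path)) return(e[])
  fwrite(e, path, sep = "\t")
  invisible(e[])
}

#' @rdname graph_edges_tsv
#' @export
graph_as_dot <- function(graph, path = NULL) {
  v <- graph$vertices
  lines <- c("digraph fragment_graph {",
             sprintf("  v%d [label=\"%s:%s %s\"];", v$vid, v$chrom, v$strand, v$chain),
             sprintf("  v%d -> v%d;", graph$edges$from, graph$edges$to),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
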