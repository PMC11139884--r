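#' Build a word-adjacency speech graph
#'
#' Represents a narrative as a directed multigraph over word types: one node
#' per distinct unit (lemma by default), one directed edge per pair of
#' consecutive word tokens (punctuation, ellipses and word fragments
#' excluded).  Multi-edges are preserved — repeated transitions are the
#' repetition signal the loop/parallel-edge features quantify.  With
#' `scope = "sentence"` adjacency does not cross sentence boundaries, so the
#' edge count is (number of units) minus (number of non-empty segments).
#'
#' @param doc `lf_doc` from [tokenize()].
#' @param unit Node identity: `"lemma"` (default) or `"surface"`
#'   (lower-cased).
#' @param scope `"document"` (default) or `"sentence"`.
#' @return Object of class `lf_speech_graph`: list with `nodes` (character),
#'   `edges` (integer matrix, columns from/to), `n_nodes`, `n_edges`.
#' @export
build_speech_graph <- function(doc, unit = c("lemma", "surface"),
                               scope = c("document", "sentence")) {
  unit <- match.arg(unit); scope <- match.arg(scope)
  tok <- doc$tokens
  keep <- tok$is_word
  units <- if (unit == "lemma") tolower(tok$lemma[keep]) else tolower(tok$surface[keep])
  seg <- if (scope == "sentence") tok$sentence[keep] else rep(1L, sum(keep))
  nodes <- unique(units)
  id <- match(units, nodes)
  if (length(id) >= 2L) {
    same <- seg[-1L] == seg[-length(seg)]
    edges <- cbind(from = id[-length(id)][same], to = id[-1L][same])
  } else {
    edges <- cbind(from = integer(), to = integer())
  }
  g <- list(nodes = nodes, edges = edges,
            n_nodes = length(nodes), n_edges = nrow(edges))
  class(g) <- "lf_speech_graph"
  g
}

#' Speech-graph structural features
#'
#' Computes the twelve graph features: loop counts `L1` (self-edges), `L2`
#' (directed 2-cycle instances: every pairing of an edge u->v with an edge
#' v->u, u != v), `L3` (directed 3-cycles through distinct nodes, each cycle
#' counted once), the parallel-edge count `PE` (unordered pairs of edges
#' sharing both endpoints and direction), average and standard deviation of
#' the total (in+out, multi-edge) node degree, and average local clustering,
#' average shortest path and global transitivity computed on the undirected
#' simple-graph projection of the largest weakly connected component.
#' Single-node or empty graphs return 0 for path/clustering measures.
#'
#' @param g `lf_speech_graph` from [build_speech_graph()].
#' @return Named numeric vector of the 12 features (names carry the
#'   `graph_` prefix used in the feature registry).
#' @export
graph_features <- function(g) {
  out <- c(graph_l1 = 0, graph_l2 = 0, graph_l3 = 0, graph_pe = 0,
           graph_degree_average = 0, graph_degree_std = 0,
           graph_average_clustering = 0, graph_average_shortest_path = 0,
           graph_transitivity = 0, graph_n_nodes = g$n_nodes,
           graph_n_edges = g$n_edges, graph_lcc_size = 0)
  n <- g$n_nodes
  if (n == 0L) return(out)
  out["graph_lcc_size"] <- 1
  e <- g$edges
  if (nrow(e) == 0L) return(out)

  out["graph_l1"] <- sum(e[, "from"] == e[, "to"])

  # multiplicity per ordered pair
  key <- paste(e[, "from"], e[, "to"])
  mult <- table(key)
  pairs <- do.call(rbind, strsplit(names(mult), " ", fixed = TRUE))
  u <- as.integer(pairs[, 1]); v <- as.integer(pairs[, 2])
  m <- as.integer(mult)

  out["graph_pe"] <- sum(choose(m, 2))

  rev_m <- m[match(paste(v, u), names(mult))]
  rev_m[is.na(rev_m)] <- 0L
  sel <- u < v
  out["graph_l2"] <- sum(m[sel] * rev_m[sel])

  # L3 via trace(B^3)/3 on the off-diagonal count matrix
  off <- u != v
  if (any(off)) {
    B <- Matrix::sparseMatrix(i = u[off], j = v[off], x = m[off],
                              dims = c(n, n))
    out["graph_l3"] <- sum(Matrix::diag(B %*% B %*% B)) / 3
  }

  deg <- tabulate(e[, "from"], n) + tabulate(e[, "to"], n)
  out["graph_degree_average"] <- 2 * nrow(e) / n
  out["graph_degree_std"] <- if (n > 1L) stats::sd(deg) else 0

  ig <- igraph::graph_from_edgelist(e, directed = TRUE)
  comp <- igraph::components(ig, mode = "weak")
  out["graph_lcc_size"] <- max(comp$csize)
  lcc <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(ig, lcc)
  und <- igraph::simplify(igraph::as_undirected(sub, mode = "collapse"))
  if (igraph::vcount(und) > 1L) {
    cl <- igraph::transitivity(und, type = "localaverage", isolates = "zero")
    out["graph_average_clustering"] <- if (is.finite(cl)) cl else 0
    gt <- igraph::transitivity(und, type = "global")
    out["graph_transitivity"] <- if (is.finite(gt)) gt else 0
    sp <- igraph::mean_distance(und, directed = FALSE)
    out["graph_average_shortest_path"] <- if (is.finite(sp)) sp else 0
  }
  out
}

#' @export
print.lf_speech_graph <- function(x, ...) {
  cat("<lf_speech_graph> N =", x$n_nodes, "nodes, E =", x$n_edges, "edges\n")
  invisible(x)
}
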