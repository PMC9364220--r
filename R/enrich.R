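# Class / pathway over-representation of selected annotated lipids, with
# step-down Holm correction and an optional topology-based pathway impact.

#' Upper-tail hypergeometric over-representation test
#'
#' Probability of drawing at least \code{k} members of a size-\code{K} set
#' when sampling \code{n} items without replacement from a universe of
#' \code{N}; equals the one-tailed Fisher exact p for the corresponding 2x2
#' table. The universe is the set of detected lipids with annotations, not
#' all detected peaks.
#'
#' @param k hits in the selection.
#' @param K set size in the universe.
#' @param n selection size.
#' @param N universe size.
#' @return upper-tail probability P(X >= k).
#' @examples
#' overrep_test(3, 3, 3, 6)  # = 1 / choose(6, 3) = 0.05
#' @export
overrep_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > K || k > n || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Step-down multiple-testing adjustment
#'
#' Holm's step-down familywise-error correction by default (sort ascending,
#' multiply the i-th smallest p by m - i + 1, enforce monotonicity, cap at
#' 1); the Benjamini--Hochberg FDR adjustment is available via
#' \code{method = "BH"}.
#'
#' @param p vector of p-values in [0, 1].
#' @param method "holm" (default) or "BH".
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Pathway impact from topology
#'
#' The impact of a hit set on a pathway graph is the summed relative
#' betweenness centrality of the hit nodes: node betweenness divided by the
#' total betweenness over the pathway. When the graph carries no betweenness
#' at all (e.g. a single edge), the fraction of nodes hit is used so that an
#' all-hit pathway still scores 1.
#'
#' @param edges data frame of edges (\code{from}, \code{to}) or an
#'   \code{igraph} graph.
#' @param hits character vector of hit node names.
#' @return impact in [0, 1].
#' @export
topology_impact <- function(edges, hits) {
  g <- if (inherits(edges, "igraph")) edges
       else igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(g)$name
  if (!all(hits %in% nodes))
    stop("hit node(s) not in the pathway graph: ",
         paste(setdiff(hits, nodes), collapse = ", "))
  if (!length(hits)) return(0)
  bt <- igraph::betweenness(g, directed = FALSE)
  tot <- sum(bt)
  if (tot <= 0) return(length(unique(hits)) / length(nodes))
  unname(sum(bt[unique(hits)]) / tot)
}

#' Class / pathway over-representation table
#'
#' For each set (lipid class or pathway), counts the hits among the selected
#' annotations against the annotated-detected universe, computes the
#' upper-tail hypergeometric p, applies the step-down adjustment across all
#' sets, and (when a pathway graph is supplied) the topology impact.
#'
#' @param selected character vector of selected item identifiers.
#' @param universe character vector of all detected, annotated items.
#' @param sets named list of character vectors (set -> member items).
#' @param graphs optional named list of edge data frames per set for the
#'   impact column.
#' @param method adjustment method passed to \code{\link{holm_adjust}}.
#' @return data frame of class \code{enrichment_table}, sorted by raw p:
#'   \code{set}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p_raw},
#'   \code{p_adjusted}, \code{impact}.
#' @export
enrich_sets <- function(selected, universe, sets, graphs = NULL,
                        method = "holm") {
  if (!all(selected %in% universe))
    stop("selected items must be a subset of the universe")
  N <- length(unique(universe))
  n <- length(unique(selected))
  rows <- lapply(names(sets), function(sn) {
    members <- intersect(sets[[sn]], universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (K == 0) 1 else overrep_test(k, K, n, N)
    imp <- if (!is.null(graphs) && sn %in% names(graphs)) {
      g <- graphs[[sn]]
      nodes <- unique(c(g$from, g$to))
      topology_impact(g, intersect(intersect(members, selected), nodes))
    } else NA_real_
    data.frame(set = sn, k = k, K = K, n = n, N = N, p_raw = p,
               impact = imp, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- holm_adjust(tab$p_raw, method = method)
  tab <- tab[order(tab$p_raw, tab$set), ]
  rownames(tab) <- NULL
  tab <- tab[, c("set", "k", "K", "n", "N", "p_raw", "p_adjusted",
                 "impact")]
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Over-representation:", nrow(x), "sets;",
      sum(x$p_adjusted < 0.05), "significant at adjusted p < 0.05\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' The bundled class-to-pathway map and pathway graphs
#'
#' A miniature KEGG-style mapping of lipid classes to metabolic pathways
#' (glycerophospholipid, ether lipid, sphingolipid metabolism, ...) bundled
#' for deterministic, offline enrichment, plus small pathway graphs
#' (edge lists over class nodes) for the topology impact.
#'
#' @return \code{pathway_map}: data frame (\code{pathway}, \code{class});
#'   \code{pathway_graphs}: named list of edge data frames.
#' @export
pathway_map <- function() {
  path <- system.file("extdata", "class_pathways.tsv", package = "lipidmsi")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pathway_map
#' @export
pathway_graphs <- function() {
  path <- system.file("extdata", "pathway_edges.tsv", package = "lipidmsi")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab[, c("from", "to")], tab$pathway)
}
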