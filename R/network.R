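#' Load a protein-interaction edge list
#'
#' Reads a STRING protein-links-style TSV (columns `protein1`, `protein2`,
#' `combined_score` with scores 0-1000), drops self-loops, merges
#' duplicate and reciprocal-duplicate edges keeping the maximum score, and
#' applies the score cutoff. The default cutoff 400 is the STRING
#' "medium confidence" convention.
#'
#' @param path TSV file (any whitespace/tab separated; header required).
#' @param min_score minimum combined score to retain an edge (0-1000).
#' @return an `igraph` undirected graph with edge attribute
#'   `combined_score`; attribute `n_self_loops_dropped` records cleanup.
#' @export
load_interaction_edges <- function(path, min_score = 400) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  interaction_network(tab, min_score = min_score)
}

#' Build an interaction network from an edge data frame
#'
#' @param edges data frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param min_score minimum combined score (0-1000).
#' @return an `igraph` graph; see [load_interaction_edges()].
#' @export
interaction_network <- function(edges, min_score = 400) {
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  sc <- edges$combined_score
  if (any(!is.finite(sc)) || any(sc < 0 | sc > 1000))
    stop("combined scores must lie in [0, 1000]")
  self <- edges$protein1 == edges$protein2
  edges <- edges[!self, , drop = FALSE]
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  best <- tapply(edges$combined_score, key, max)
  uk <- names(best)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  dedup <- data.frame(protein1 = parts[, 1L], protein2 = parts[, 2L],
                      combined_score = as.numeric(best))
  dedup <- dedup[dedup$combined_score >= min_score, , drop = FALSE]
  g <- igraph::graph_from_data_frame(dedup, directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_self_loops_dropped", sum(self))
  g
}

#' Connectivity summary of a focal protein set
#'
#' Induced subgraph statistics for the proteins of interest (e.g. the
#' positively selected set): how many have at least one interaction among
#' themselves, the degree-ranked hub list (ties broken lexicographically),
#' and the connected components.
#'
#' @param net an `igraph` network.
#' @param focal_nodes protein identifiers; nodes absent from the network
#'   count as degree 0.
#' @return list: `n_connected`, `hubs` (data frame protein, degree),
#'   `components` (list of protein-id vectors, decreasing size).
#' @export
connectivity_summary <- function(net, focal_nodes) {
  present <- intersect(focal_nodes, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, present)
  deg <- stats::setNames(rep(0L, length(focal_nodes)), focal_nodes)
  if (length(present)) deg[present] <- igraph::degree(sub)[present]
  ord <- order(-deg, names(deg))
  hubs <- data.frame(protein = names(deg)[ord],
                     degree = as.integer(deg[ord]), row.names = NULL)
  comp <- igraph::components(sub)
  comps <- split(names(comp$membership), comp$membership)
  comps <- comps[order(-lengths(comps))]
  list(n_connected = sum(deg >= 1L), hubs = hubs,
       components = unname(comps))
}

#' Map grouped GO categories onto network nodes
#'
#' Labels every node with the set of functional category groups reachable
#' through its GO terms; nodes may carry several labels (e.g. both
#' "muscle" and "nervous system") or none.
#'
#' @param net an `igraph` network.
#' @param annotation data frame with columns `gene`, `term`.
#' @param groups named list: category name -> GO term ids.
#' @return named list: node -> character vector of category labels.
#' @export
map_categories <- function(net, annotation, groups) {
  all_terms <- unique(annotation$term)
  unknown <- setdiff(unique(unlist(groups)), all_terms)
  # unknown terms in groups are allowed to be absent from this annotation
  # subset only if the caller says so; default is strict
  if (length(unknown))
    stop("category groups reference GO term(s) absent from the annotation: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  nodes <- igraph::V(net)$name
  ann <- split(annotation$term, annotation$gene)
  lab <- lapply(nodes, function(v) {
    terms <- ann[[v]]
    if (is.null(terms)) return(character(0))
    names(groups)[vapply(groups, function(g) any(terms %in% g), logical(1))]
  })
  stats::setNames(lab, nodes)
}

#' Permutation test of category clustering on a network
#'
#' Observed fraction of edges whose two endpoints both carry the category,
#' against the null distribution obtained by permuting the node-label
#' assignment; p = (1 + #\{null >= observed\}) / (n_permutations + 1).
#'
#' @param net an `igraph` network.
#' @param labeling named list from [map_categories()].
#' @param category category name to test.
#' @param n_permutations at least 100 (default 999).
#' @param seed integer seed.
#' @return list: `observed` (same-category edge fraction), `p_value`,
#'   `n_carriers`.
#' @export
category_clustering <- function(net, labeling, category,
                                n_permutations = 999L, seed = 1L) {
  stopifnot(n_permutations >= 100L)
  nodes <- igraph::V(net)$name
  has <- vapply(labeling[nodes], function(l) category %in% l, logical(1))
  if (!any(has)) stop("category '", category, "' is absent from the labeling")
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) stop("network has no edges")
  obs <- mean(has[el[, 1L]] & has[el[, 2L]])
  null <- .with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    ph <- stats::setNames(sample(has), nodes)
    mean(ph[el[, 1L]] & ph[el[, 2L]])
  }, numeric(1)))
  list(observed = obs,
       p_value = (1 + sum(null >= obs)) / (n_permutations + 1),
       n_carriers = sum(has))
}

#' Classic Fisher GO enrichment
#'
#' One-sided Fisher exact test (hypergeometric upper tail) for
#' over-representation of each GO term among the selected genes, with BH
#' q-values across tested terms. The universe should be the genes actually
#' tested for selection, not the whole genome. Unannotated universe genes
#' are dropped (count reported via attribute `n_unannotated`). Terms with
#' no selected member are reported with p = 1.
#'
#' @param selected gene set of interest (must be contained in `universe`).
#' @param universe background gene set.
#' @param annotation data frame with columns `gene`, `term`.
#' @return data frame, one row per term: `term`, `n_selected_term`,
#'   `n_selected`, `n_term`, `n_universe`, `p`, `q`; sorted by p.
#' @export
fisher_enrichment <- function(selected, universe, annotation) {
  if (!length(selected)) stop("empty selected set")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  annotated <- intersect(universe, unique(annotation$gene))
  n_unann <- length(universe) - length(annotated)
  universe <- annotated
  selected <- intersect(selected, universe)
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  N <- length(universe); n <- length(selected)
  res <- do.call(rbind, lapply(terms, function(tm) {
    members <- unique(ann$gene[ann$term == tm])
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_selected_term = k, n_selected = n,
               n_term = K, n_universe = N, p = p)
  }))
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  attr(res, "n_unannotated") <- n_unann
  res
}
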