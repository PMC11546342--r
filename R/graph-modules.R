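#' Average local clustering coefficient
#'
#' Mean over all nodes of `C_v = 2 T_v / (deg_v (deg_v - 1))`, where
#' `T_v` counts triangles through `v`; nodes of degree < 2 contribute 0.
#' A complete graph scores exactly 1.
#'
#' @param graph an undirected [igraph::graph].
#' @return A single number in `[0, 1]`.
#' @export
average_clustering <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) stop("empty graph")
  local <- igraph::transitivity(graph, type = "local", isolates = "zero")
  mean(local)
}

#' Rank hub genes by degree or maximal clique centrality
#'
#' Degree ranking scores each node by its number of neighbors. MCC
#' (maximal clique centrality) scores a node by the sum of
#' `(|C| - 1)!` over all maximal cliques `C` containing it; a node whose
#' every edge is itself a maximal clique (no triangles through it)
#' thereby scores its degree. Ties break lexicographically by gene id.
#'
#' @param graph an undirected [igraph::graph] with named vertices.
#' @param method `"degree"` or `"mcc"`.
#' @param top_k how many hubs to return (default 10); if larger than the
#'   node count, all nodes are returned with a warning.
#' @return A `data.frame` with columns `gene`, `score`, ordered by
#'   decreasing score.
#' @export
rank_hubs <- function(graph, method = c("degree", "mcc"), top_k = 10L) {
  method <- match.arg(method)
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) stop("empty graph")
  names <- igraph::V(graph)$name
  if (is.null(names)) names <- as.character(seq_len(igraph::vcount(graph)))
  score <- if (method == "degree") {
    as.numeric(igraph::degree(graph))
  } else {
    mcc_scores(graph)
  }
  ord <- order(-score, names)
  if (top_k > length(ord)) {
    warning("top_k exceeds node count; returning all ", length(ord), " nodes")
    top_k <- length(ord)
  }
  sel <- ord[seq_len(top_k)]
  data.frame(gene = names[sel], score = score[sel],
             stringsAsFactors = FALSE, row.names = NULL)
}

mcc_scores <- function(graph) {
  score <- numeric(igraph::vcount(graph))
  if (igraph::ecount(graph) > 0) {
    cliques <- igraph::max_cliques(graph, min = 2)
    for (cl in cliques) {
      idx <- as.integer(cl)
      score[idx] <- score[idx] + factorial(length(idx) - 1)
    }
  }
  score
}

#' MCODE-style clustering parameters
#'
#' The defaults mirror the usual settings of the density-based molecular
#' complex detection procedure: degree cutoff 2, node score cutoff 0.2,
#' k-core 2, maximum depth 100; reported clusters need a score
#' (density x size) of at least 2.8 and at least 3 nodes.
#'
#' @param degree_cutoff minimum intra-cluster degree kept by the haircut.
#' @param node_score_cutoff admissible fractional drop from the seed
#'   weight during expansion, in (0, 1).
#' @param k_core cluster must survive this k-core.
#' @param max_depth breadth-first expansion depth limit.
#' @param min_cluster_score minimum density x size to report.
#' @param min_cluster_nodes minimum cluster size to report.
#' @return An `MCODEParams` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         min_cluster_score = 2.8, min_cluster_nodes = 3L) {
  stopifnot(degree_cutoff > 0, node_score_cutoff > 0, node_score_cutoff < 1,
            k_core > 0, max_depth > 0, min_cluster_score > 0,
            min_cluster_nodes > 0)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 min_cluster_score = min_cluster_score,
                 min_cluster_nodes = as.integer(min_cluster_nodes)),
            class = "MCODEParams")
}

graph_density <- function(n, e) if (n >= 2) 2 * e / (n * (n - 1)) else 0

#' Density-based graph clustering (MCODE-style)
#'
#' (1) Each node is weighted by the density of the highest k-core of its
#' closed neighborhood times that core's k. (2) Clusters are seeded from
#' the highest-weight unassigned node and grown breadth-first, admitting
#' unassigned neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight, up to `max_depth`.
#' (3) A haircut iteratively removes nodes whose intra-cluster degree is
#' below `degree_cutoff` (equivalently, the cluster is reduced to its
#' `degree_cutoff`-core). (4) Clusters below the score or size floor are
#' discarded. Clusters are disjoint and reported in decreasing score.
#'
#' @param graph an undirected simple [igraph::graph].
#' @param params an [mcode_params()] object.
#' @return A list of clusters, each a list with `nodes` (ids), `score`
#'   (density x size), `density`, `n_nodes`, `n_edges`.
#' @export
mcode_cluster <- function(graph, params = mcode_params()) {
  stopifnot(igraph::is_igraph(graph), inherits(params, "MCODEParams"))
  n <- igraph::vcount(graph)
  if (n == 0) return(list())
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) {
    vnames <- as.character(seq_len(n))
    graph <- igraph::set_vertex_attr(graph, "name", value = vnames)
  }

  # vertex weighting: core-clustering coefficient x core number
  weight <- numeric(n)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (v in seq_len(n)) {
    nb <- c(v, as.integer(adj[[v]]))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_g <- igraph::induced_subgraph(sub, which(core == kmax))
    weight[v] <- kmax * graph_density(igraph::vcount(core_g),
                                      igraph::ecount(core_g))
  }

  assigned <- rep(FALSE, n)
  clusters <- list()
  for (seed in order(-weight, vnames)) {
    if (assigned[seed] || weight[seed] <= 0) next
    thresh <- (1 - params$node_score_cutoff) * weight[seed]
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in as.integer(adj[[v]])) {
          if (!assigned[w] && weight[w] >= thresh) {
            assigned[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(graph, members)
    # haircut: keep the degree_cutoff-core (and enforce the k_core floor)
    core <- igraph::coreness(sub)
    keep_names <- igraph::V(sub)$name[core >= max(params$degree_cutoff,
                                                  params$k_core)]
    release <- setdiff(vnames[members], keep_names)
    assigned[match(release, vnames)] <- FALSE  # may join later seeds
    if (!length(keep_names)) next
    sub <- igraph::induced_subgraph(sub, keep_names)
    nn <- igraph::vcount(sub)
    dens <- graph_density(nn, igraph::ecount(sub))
    score <- dens * nn
    if (nn >= params$min_cluster_nodes && score >= params$min_cluster_score) {
      clusters[[length(clusters) + 1]] <-
        list(nodes = sort(keep_names), score = score,
             density = dens, n_nodes = nn, n_edges = igraph::ecount(sub))
    } else {
      assigned[match(keep_names, vnames)] <- FALSE
    }
  }
  clusters[order(-vapply(clusters, `[[`, numeric(1), "score"))]
}

#' Induced subnetwork around hub genes
#'
#' Returns the induced graph on the hubs plus, per hub, its top
#' `max_neighbors` neighbors by edge confidence (ties broken by node
#' name). With no `confidence` edge attribute all edges count as 1.
#'
#' @param graph an undirected [igraph::graph] with named vertices.
#' @param hubs character vector of hub gene ids; must all be nodes.
#' @param max_neighbors neighbors added per hub (default 5).
#' @return An [igraph::graph], the induced subgraph on hubs and selected
#'   neighbors.
#' @export
hub_subnetwork <- function(graph, hubs, max_neighbors = 5L) {
  stopifnot(igraph::is_igraph(graph))
  vnames <- igraph::V(graph)$name
  unknown <- setdiff(hubs, vnames)
  if (length(unknown)) {
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  }
  if (!length(hubs)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  conf <- igraph::E(graph)$confidence
  if (is.null(conf)) conf <- rep(1, igraph::ecount(graph))
  keep <- hubs
  for (h in hubs) {
    eids <- igraph::incident(graph, h)
    if (!length(eids)) next
    ends <- igraph::ends(graph, eids)
    nb <- ifelse(ends[, 1] == h, ends[, 2], ends[, 1])
    ord <- order(-conf[as.integer(eids)], nb)
    keep <- c(keep, nb[ord][seq_len(min(max_neighbors, length(nb)))])
  }
  igraph::induced_subgraph(graph, unique(keep))
}
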