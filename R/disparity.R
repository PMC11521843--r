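# Differential amino-acid space: Hamming distances, nearest neighbours,
# cross-reactive classification and per-group disparity graphs.
#
# Residue sets are encoded as 20-bit integer masks (one bit per letter of
# AA_ALPHABET, 0 = position not covered), so disjointness tests vectorise.

#' Default coordinate namespaces
#'
#' Loci whose mature-protein position numbering is comparable share a
#' coordinate namespace, within which distances are defined: the class I
#' heavy chains A, B and C form one space (B-C inter-locus similarities are
#' real and reportable), the DRB chains DRB1/3/4/5 another, and each of
#' DQA1, DQB1, DPA1, DPB1 stands alone. The partition is configurable: any
#' data.frame with columns `namespace` and `locus` covering the loci of
#' interest can be passed wherever a namespace table is accepted.
#'
#' @return data.frame with columns `namespace`, `locus`.
#' @export
default_namespaces <- function() {
  data.frame(
    namespace = c("classI", "classI", "classI",
                  "DRB", "DRB", "DRB", "DRB",
                  "DQA1", "DQB1", "DPA1", "DPB1"),
    locus = c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
              "DQA1", "DQB1", "DPA1", "DPB1"),
    stringsAsFactors = FALSE)
}

namespace_of_locus <- function(locus, namespaces = default_namespaces()) {
  ns <- namespaces$namespace[match(locus, namespaces$locus)]
  if (anyNA(ns)) {
    stop(sprintf("locus without namespace: %s",
                 paste(unique(locus[is.na(ns)]), collapse = ", ")))
  }
  ns
}

residue_bits <- function(set) {
  sum(bitwShiftL(1L, match(set, AA_ALPHABET) - 1L))
}

# positions x alleles integer matrix of residue-set bitmasks (0 = uncovered)
profile_bit_matrix <- function(profiles, positions) {
  B <- matrix(0L, nrow = length(positions), ncol = length(profiles),
              dimnames = list(as.character(positions),
                              vapply(profiles, function(p) p$allele, "",
                                     USE.NAMES = FALSE)))
  for (j in seq_along(profiles)) {
    res <- profiles[[j]]$residues
    for (pos in names(res)) {
      B[pos, j] <- residue_bits(res[[pos]])
    }
  }
  B
}

#' Hamming distance between two allele profiles
#'
#' The number of positions at which the two polymorphic amino-acid profiles
#' disagree. Residue sets with alternatives count as agreeing whenever they
#' overlap. Two policies handle positions covered by only one profile:
#' `"difference"` (default) counts one-sided coverage as a difference -
#' absence of an eplet from a repertoire is itself a mismatch signal -
#' while `"shared_only"` restricts the count to positions covered by both
#' profiles.
#'
#' @param p1,p2 `allele_profile` objects. Their loci must share a
#'   coordinate namespace.
#' @param policy `"difference"` or `"shared_only"`.
#' @param namespaces namespace table, see [default_namespaces()].
#' @return a non-negative integer.
#' @examples
#' reg <- example_registry()
#' hamming_distance(build_profile(reg, "A*01:01"), build_profile(reg, "A*01:02"))
#' @export
hamming_distance <- function(p1, p2, policy = c("difference", "shared_only"),
                             namespaces = default_namespaces()) {
  policy <- match.arg(policy)
  stopifnot(inherits(p1, "allele_profile"), inherits(p2, "allele_profile"))
  ns <- namespace_of_locus(c(p1$locus, p2$locus), namespaces)
  if (ns[1] != ns[2]) {
    stop(sprintf("profiles live in different coordinate namespaces (%s vs %s)",
                 ns[1], ns[2]))
  }
  pos <- sort(unique(as.integer(c(names(p1$residues), names(p2$residues)))))
  B <- profile_bit_matrix(list(p1, p2), pos)
  pair_distance(B[, 1], B[, 2], policy)
}

pair_distance <- function(b1, b2, policy) {
  c1 <- b1 > 0L
  c2 <- b2 > 0L
  disjoint <- c1 & c2 & bitwAnd(b1, b2) == 0L
  if (policy == "difference") {
    sum(disjoint | xor(c1, c2))
  } else {
    sum(disjoint)
  }
}

#' Pairwise distance matrix over an atlas
#'
#' Computes all pairwise Hamming distances between the atlas profiles that
#' belong to one coordinate namespace. Symmetric with zero diagonal by
#' construction.
#'
#' @param atlas an `eplet_atlas`.
#' @param namespace name of the coordinate namespace to use. May be omitted
#'   when all atlas loci fall into a single namespace.
#' @inheritParams hamming_distance
#' @return an object of class `eplet_distmat`: an integer matrix with
#'   allele dimnames and attributes `policy`, `namespace` and `groups` (a
#'   named character vector allele -> group label).
#' @export
distance_matrix <- function(atlas, namespace = NULL,
                            policy = c("difference", "shared_only"),
                            namespaces = default_namespaces()) {
  policy <- match.arg(policy)
  stopifnot(inherits(atlas, "eplet_atlas"))
  info <- atlas$info
  info$namespace <- namespace_of_locus(info$locus, namespaces)
  if (is.null(namespace)) {
    namespace <- unique(info$namespace)
    if (length(namespace) > 1) {
      stop(sprintf("atlas spans several namespaces (%s); pass `namespace`",
                   paste(namespace, collapse = ", ")))
    }
  }
  info <- info[info$namespace == namespace, , drop = FALSE]
  if (nrow(info) == 0) stop(sprintf("no atlas alleles in namespace '%s'", namespace))
  profiles <- atlas$profiles[info$allele]

  all_pos <- sort(unique(unlist(lapply(profiles,
                                       function(p) as.integer(names(p$residues))))))
  B <- profile_bit_matrix(profiles, all_pos)
  cov <- B > 0L
  n <- ncol(B)
  D <- matrix(0L, n, n, dimnames = list(colnames(B), colnames(B)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      jj <- (i + 1):n
      sub <- B[, jj, drop = FALSE]
      csub <- cov[, jj, drop = FALSE]
      ands <- matrix(bitwAnd(B[, i], as.vector(sub)), nrow = nrow(B))
      disjoint <- csub & cov[, i] & ands == 0L
      d <- if (policy == "difference") {
        colSums(disjoint | xor(csub, cov[, i]))
      } else {
        colSums(disjoint)
      }
      D[i, jj] <- as.integer(d)
      D[jj, i] <- as.integer(d)
    }
  }
  structure(D, policy = policy, namespace = namespace,
            groups = stats::setNames(info$group_label, info$allele),
            class = c("eplet_distmat", "matrix", "array"))
}

#' @export
print.eplet_distmat <- function(x, ...) {
  cat(sprintf("distance matrix: %d allele(s), namespace '%s', policy '%s'\n",
              ncol(x), attr(x, "namespace"), attr(x, "policy")))
  invisible(x)
}

distmat_groups <- function(dm) attr(dm, "groups")

check_allele_in_matrix <- function(dm, allele) {
  a <- parse_allele_name(allele)$allele
  if (!(a %in% colnames(dm))) {
    stop(sprintf("allele %s is not in the distance matrix", a))
  }
  a
}

#' Nearest neighbours of an allele
#'
#' All alleles attaining the minimal distance to the query within the
#' requested scope - ties are kept, never broken arbitrarily. The query
#' itself is always excluded.
#'
#' @param dm an `eplet_distmat`.
#' @param allele query allele.
#' @param scope `"all"` (whole namespace), `"own_group"` or
#'   `"other_groups"`.
#' @return data.frame with columns `allele`, `distance` (zero rows when the
#'   scope is empty, e.g. `own_group` for a singleton group).
#' @export
nearest_neighbours <- function(dm, allele, scope = c("all", "own_group", "other_groups")) {
  scope <- match.arg(scope)
  a <- check_allele_in_matrix(dm, allele)
  groups <- distmat_groups(dm)
  others <- setdiff(colnames(dm), a)
  others <- switch(scope,
    all = others,
    own_group = others[groups[others] == groups[[a]]],
    other_groups = others[groups[others] != groups[[a]]])
  if (length(others) == 0) {
    return(data.frame(allele = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- stats::setNames(as.integer(dm[a, others]), others)
  hit <- others[d == min(d)]
  data.frame(allele = hit, distance = unname(d[hit]), stringsAsFactors = FALSE)
}

#' Classify an allele as cross-reactive
#'
#' An allele is cross-reactive (in the computational sense) when it is
#' strictly more similar to some allele of another group than to any allele
#' of its own group: `d_other < d_own`. Ties resolve to the own group, so a
#' tie never inflates cross-reactivity counts. For a singleton group there
#' is no own-group distance and the allele is trivially cross-reactive
#' whenever any other-group allele exists in the namespace (the degenerate
#' one-allele-per-group pattern of DPB1).
#'
#' @inheritParams nearest_neighbours
#' @return list with `is_cr` (logical), `d_own` and `d_other` (integer or
#'   `NA` when the respective scope is empty).
#' @export
classify_cross_reactive <- function(dm, allele) {
  a <- check_allele_in_matrix(dm, allele)
  own <- nearest_neighbours(dm, a, "own_group")
  oth <- nearest_neighbours(dm, a, "other_groups")
  d_own <- if (nrow(own) == 0) NA_integer_ else own$distance[1]
  d_other <- if (nrow(oth) == 0) NA_integer_ else oth$distance[1]
  is_cr <- if (is.na(d_own)) !is.na(d_other) else (!is.na(d_other) && d_other < d_own)
  list(is_cr = is_cr, d_own = d_own, d_other = d_other)
}

#' Cross-reactivity classification of every allele in a matrix
#'
#' @inheritParams nearest_neighbours
#' @return data.frame with columns `allele`, `group`, `d_own`, `d_other`,
#'   `is_cr`.
#' @export
cross_reactive_table <- function(dm) {
  groups <- distmat_groups(dm)
  rows <- lapply(colnames(dm), function(a) {
    cls <- classify_cross_reactive(dm, a)
    data.frame(allele = a, group = groups[[a]], d_own = cls$d_own,
               d_other = cls$d_other, is_cr = cls$is_cr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the disparity graph of one allele group
#'
#' A 1-nearest-neighbour graph over the alleles of a group in differential
#' amino-acid space. Every in-group allele is connected to *all* of its
#' minimal-distance neighbours (no arbitrary tie-break): to its own-group
#' nearest neighbours when it is not cross-reactive, or to its other-group
#' nearest neighbours when it is - those foreign alleles are added to the
#' graph as external nodes. Edges carry the Hamming distance; distance-0
#' edges link monomorphic alleles and are flagged so renderers can suppress
#' their labels. In-group nodes carry the id of their monomorphic cluster
#' (connected component of the distance-0 relation), `NA` for singletons
#' and external nodes.
#'
#' @inheritParams nearest_neighbours
#' @param group group label, e.g. `"A*01"`.
#' @return an igraph object with vertex attributes `group`, `is_external`,
#'   `cluster`, edge attributes `distance`, `monomorphic`, and graph
#'   attributes `focus_group`, `namespace`, `policy`.
#' @export
disparity_graph <- function(dm, group) {
  groups <- distmat_groups(dm)
  ingroup <- names(groups)[groups == group]
  if (length(ingroup) == 0) {
    stop(sprintf("unknown group '%s' in namespace '%s'", group, attr(dm, "namespace")))
  }
  edges <- list()
  externals <- character()
  for (a in ingroup) {
    cls <- classify_cross_reactive(dm, a)
    nn <- if (cls$is_cr) {
      nearest_neighbours(dm, a, "other_groups")
    } else {
      nearest_neighbours(dm, a, "own_group")
    }
    if (nrow(nn) == 0) next
    if (cls$is_cr) externals <- union(externals, nn$allele)
    edges[[length(edges) + 1L]] <- data.frame(
      from = a, to = nn$allele, distance = nn$distance, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), distance = integer(),
               stringsAsFactors = FALSE)
  # de-duplicate undirected edges
  if (nrow(edges) > 0) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  edges$monomorphic <- edges$distance == 0L

  clusters <- monomorphic_clusters(dm, group)
  cluster_id <- rep(NA_character_, length(ingroup))
  names(cluster_id) <- ingroup
  for (i in seq_along(clusters)) cluster_id[clusters[[i]]] <- sprintf("M%d", i)

  vertices <- rbind(
    data.frame(name = sort(ingroup), group = group, is_external = FALSE,
               stringsAsFactors = FALSE),
    if (length(externals) > 0) {
      data.frame(name = sort(externals), group = unname(groups[sort(externals)]),
                 is_external = TRUE, stringsAsFactors = FALSE)
    })
  vertices$cluster <- cluster_id[vertices$name]

  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "focus_group", group)
  g <- igraph::set_graph_attr(g, "namespace", attr(dm, "namespace"))
  g <- igraph::set_graph_attr(g, "policy", attr(dm, "policy"))
  g
}

#' Monomorphic clusters of a group
#'
#' Connected components of the distance-0 relation among the group's
#' alleles - sets of alleles with identical residue content at every
#' confirmed-eplet position. Singletons are excluded from the report.
#' Equality of residue maps is transitive, so the components are genuine
#' equivalence classes.
#'
#' @inheritParams disparity_graph
#' @return list of character vectors (each sorted), ordered by decreasing
#'   size then first allele.
#' @export
monomorphic_clusters <- function(dm, group) {
  groups <- distmat_groups(dm)
  ingroup <- names(groups)[groups == group]
  if (length(ingroup) == 0) {
    stop(sprintf("unknown group '%s' in namespace '%s'", group, attr(dm, "namespace")))
  }
  if (length(ingroup) < 2) return(list())
  sub <- unclass(dm)[ingroup, ingroup, drop = FALSE]
  adj <- (sub == 0L) * 1L
  diag(adj) <- 0L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  out <- split(ingroup, comp$membership)
  out <- lapply(out, sort)
  out <- out[vapply(out, length, 1L) >= 2L]
  names(out) <- NULL
  out[order(-vapply(out, length, 1L), vapply(out, `[[`, "", 1L))]
}

#' Export a disparity graph
#'
#' `write_graphml()` and `write_dot()` serialize the graph with all node
#' and edge attributes via igraph; `graph_to_json()` returns (and
#' `write_graph_json()` writes) a plain nodes/edges adjacency structure for
#' programmatic use. All outputs are deterministic functions of the graph.
#'
#' @param graph an igraph object from [disparity_graph()].
#' @param path output file.
#' @return invisibly, the path (`graph_to_json()`: a list).
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(graph, path) {
  igraph::write_graph(graph, path, format = "dot")
  invisible(path)
}

#' @rdname write_graphml
#' @export
graph_to_json <- function(graph) {
  nodes <- data.frame(
    allele = igraph::V(graph)$name,
    group = igraph::V(graph)$group,
    is_external = igraph::V(graph)$is_external,
    cluster = igraph::V(graph)$cluster,
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      distance = igraph::E(graph)$distance,
                      monomorphic = igraph::E(graph)$monomorphic,
                      stringsAsFactors = FALSE)
  list(focus_group = igraph::graph_attr(graph, "focus_group"),
       namespace = igraph::graph_attr(graph, "namespace"),
       policy = igraph::graph_attr(graph, "policy"),
       nodes = nodes, edges = edges)
}

#' @rdname write_graphml
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(graph_to_json(graph), path, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export a distance matrix as TSV
#'
#' @param dm an `eplet_distmat`.
#' @param path output file.
#' @export
write_distmat_tsv <- function(dm, path) {
  out <- data.frame(allele = rownames(dm), unclass(dm), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a disparity graph
#'
#' Base-graphics rendering: in-group nodes in one colour, external
#' (cross-reactive target) nodes in another; edge labels show the Hamming
#' distance except on distance-0 edges, which connect monomorphic alleles.
#' Layout is a rendering concern only (seeded Fruchterman-Reingold); the
#' graph data structure itself is deterministic.
#'
#' @param graph an igraph object from [disparity_graph()].
#' @param layout_seed seed for the layout.
#' @param ... further arguments to [igraph::plot.igraph()].
#' @export
plot_disparity_graph <- function(graph, layout_seed = 1L, ...) {
  set.seed(layout_seed)
  lay <- igraph::layout_with_fr(graph)
  cols <- ifelse(igraph::V(graph)$is_external, "#E69F00", "#56B4E9")
  labs <- ifelse(igraph::E(graph)$monomorphic, "", igraph::E(graph)$distance)
  igraph::plot.igraph(graph, layout = lay, vertex.color = cols,
                      vertex.label.cex = 0.7, edge.label = labs,
                      edge.label.cex = 0.8, ...)
  invisible(graph)
}
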