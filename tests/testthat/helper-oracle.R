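# Independent brute-force reference implementations. They re-derive allele
# profiles and distances from the raw registry tables with a naive
# string/set code path, deliberately separate from the package's bitmask
# machinery, so agreement between the two is a real cross-check.

oracle_expand_eplet <- function(name) {
  m <- regmatches(name, regexec("^([0-9]+)([A-Z]+)(/([A-Z]))?$", name))[[1]]
  start <- as.integer(m[2])
  letters <- strsplit(m[3], "", fixed = TRUE)[[1]]
  sets <- as.list(letters)
  if (nzchar(m[5])) sets[[length(sets)]] <- c(sets[[length(sets)]], m[5])
  names(sets) <- seq(start, start + length(letters) - 1L)
  sets
}

oracle_profile <- function(registry, allele) {
  eplets <- registry$assignments$eplet[registry$assignments$allele == allele]
  long <- list()
  for (ep in eplets) {
    sets <- oracle_expand_eplet(ep)
    for (pos in names(sets)) long[[pos]] <- c(long[[pos]], list(sets[[pos]]))
  }
  lapply(long, function(sets) Reduce(intersect, sets))
}

oracle_distance_profiles <- function(pa, pb, policy = "difference") {
  pos <- if (policy == "difference") union(names(pa), names(pb)) else
    intersect(names(pa), names(pb))
  d <- 0L
  for (p in pos) {
    sa <- pa[[p]]
    sb <- pb[[p]]
    if (is.null(sa) || is.null(sb)) {
      if (policy == "difference") d <- d + 1L
    } else if (length(intersect(sa, sb)) == 0) {
      d <- d + 1L
    }
  }
  d
}

# full pairwise scan over a registry's alleles
oracle_distances <- function(registry, policy = "difference") {
  alleles <- sort(unique(registry$assignments$allele))
  profs <- lapply(alleles, oracle_profile, registry = registry)
  names(profs) <- alleles
  D <- matrix(0L, length(alleles), length(alleles),
              dimnames = list(alleles, alleles))
  for (i in seq_along(alleles)) {
    for (j in seq_along(alleles)) {
      if (j > i) {
        d <- oracle_distance_profiles(profs[[i]], profs[[j]], policy)
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  D
}

# argmin scan over an oracle distance matrix
oracle_nn <- function(D, query, candidates) {
  candidates <- setdiff(candidates, query)
  if (length(candidates) == 0) return(character())
  d <- D[query, candidates]
  sort(candidates[d == min(d)])
}

# expected disparity-graph edge set by full scan
oracle_graph_edges <- function(D, groups, focus) {
  ingroup <- names(groups)[groups == focus]
  edges <- character()
  for (a in ingroup) {
    own <- oracle_nn(D, a, names(groups)[groups == focus])
    oth <- oracle_nn(D, a, names(groups)[groups != focus])
    d_own <- if (length(own)) D[a, own[1]] else NA_integer_
    d_oth <- if (length(oth)) D[a, oth[1]] else NA_integer_
    is_cr <- if (is.na(d_own)) !is.na(d_oth) else (!is.na(d_oth) && d_oth < d_own)
    nn <- if (is_cr) oth else own
    if (length(nn)) edges <- c(edges, paste(pmin(a, nn), pmax(a, nn)))
  }
  sort(unique(edges))
}

graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
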