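# Hamming distances, nearest neighbours, cross-reactivity and graphs.

test_that("pairwise distance counts disjoint residue positions under both policies", {
  reg <- example_registry()
  p1 <- build_profile(reg, "A*01:01")
  p2 <- build_profile(reg, "A*01:02")
  expect_equal(hamming_distance(p1, p1), 0)
  expect_equal(hamming_distance(p1, p2), 0)  # identical confirmed eplets

  r <- tiny_registry(list(`A*01:01` = "44K", `A*01:02` = "44R", `A*01:03` = "90D"))
  a <- build_atlas(r)
  expect_equal(hamming_distance(a[["A*01:01"]], a[["A*01:02"]]), 1)
  # one-sided coverage: a difference by default, ignored under shared_only
  expect_equal(hamming_distance(a[["A*01:01"]], a[["A*01:03"]]), 2)
  expect_equal(hamming_distance(a[["A*01:01"]], a[["A*01:03"]], "shared_only"), 0)

  # overlapping residue sets agree
  r2 <- tiny_registry(list(`B*44:02` = "163LS/G", `B*44:03` = "163LG"))
  a2 <- build_atlas(r2)
  expect_equal(hamming_distance(a2[["B*44:02"]], a2[["B*44:03"]]), 0)
})

test_that("profiles from different coordinate namespaces cannot be compared", {
  reg <- eplet_registry(
    data.frame(name = c("44KM", "44RM"), hla_class = c("I", "II"), confirmed = TRUE),
    data.frame(allele = c("A*01:01", "DQB1*03:01"), eplet = c("44KM", "44RM")))
  a <- build_atlas(reg)
  expect_error(hamming_distance(a[["A*01:01"]], a[["DQB1*03:01"]]), "namespaces")
  expect_error(distance_matrix(a), "spans several namespaces")
  expect_equal(dim(distance_matrix(a, namespace = "classI")), c(1, 1))
})

test_that("distance matrix is symmetric, zero-diagonal and order-invariant", {
  sim <- simulate_registry(sim_params(seed = 3))
  atlas <- build_atlas(sim$registry)
  dm <- distance_matrix(atlas)
  expect_true(all(diag(dm) == 0))
  expect_true(isSymmetric(unclass(dm)))
  # permuting the atlas leaves every pairwise value unchanged
  perm <- rev(names(atlas$profiles))
  atlas2 <- atlas
  atlas2$profiles <- atlas$profiles[perm]
  atlas2$info <- atlas$info[match(perm, atlas$info$allele), ]
  dm2 <- distance_matrix(atlas2)
  plain <- function(m) matrix(as.integer(m), nrow(m), dimnames = dimnames(m))
  expect_equal(plain(dm2)[rownames(dm), colnames(dm)], plain(dm))
})

test_that("distance matrix agrees with the brute-force oracle on random registries", {
  for (seed in 1:5) {
    sim <- simulate_registry(sim_params(
      groups_per_locus = 3, alleles_per_group = 6, n_planted_cross_reactive = 2,
      seed = seed))
    for (policy in c("difference", "shared_only")) {
      dm <- distance_matrix(build_atlas(sim$registry), policy = policy)
      D <- oracle_distances(sim$registry, policy)
      expect_equal(unclass(dm)[rownames(D), colnames(D)], D)
    }
  }
})

test_that("nearest neighbours return the full argmin set and respect scope", {
  dm <- tiny_distmat(list(
    `A*01:01` = c("10A", "20C", "30D", "40E", "50F"),
    `A*01:02` = c("10G", "20H", "30D", "40E", "50F"),   # d = 2
    `A*01:03` = c("10I", "20K", "30D", "40E", "50F"),   # d = 2
    `A*02:01` = c("10L", "20M", "30N", "40P", "50Q")))  # d = 5
  nn <- nearest_neighbours(dm, "A*01:01")
  expect_setequal(nn$allele, c("A*01:02", "A*01:03"))
  expect_true(all(nn$distance == 2))
  # singleton group: own-group scope is empty, not an error
  expect_equal(nrow(nearest_neighbours(dm, "A*02:01", "own_group")), 0)
  expect_equal(nrow(nearest_neighbours(dm, "A*02:01", "other_groups")), 3)
  expect_error(nearest_neighbours(dm, "A*99:99"), "not in the distance matrix")
})

test_that("cross-reactivity requires strictly smaller foreign distance", {
  # tie: d_own == d_other == 1 resolves to the own group
  dm <- tiny_distmat(list(
    `A*01:01` = c("10A", "20C"),
    `A*01:02` = c("10A", "20D"),
    `A*02:01` = c("10A", "20E")))
  cls <- classify_cross_reactive(dm, "A*01:01")
  expect_equal(cls$d_own, 1)
  expect_equal(cls$d_other, 1)
  expect_false(cls$is_cr)

  # strictly nearer foreign allele
  dm2 <- tiny_distmat(list(
    `A*01:01` = c("10A", "20C", "30D", "40E"),
    `A*01:02` = c("10F", "20G", "30H", "40I"),
    `A*02:01` = c("10A", "20C", "30D", "40K")))
  cls2 <- classify_cross_reactive(dm2, "A*01:01")
  expect_true(cls2$is_cr)
  expect_equal(cls2$d_own, 4)
  expect_equal(cls2$d_other, 1)

  # singleton group is trivially cross-reactive when foreigners exist
  cls3 <- classify_cross_reactive(dm, "A*02:01")
  expect_true(cls3$is_cr)
  expect_true(is.na(cls3$d_own))
})

test_that("every one-allele group in a namespace is classified cross-reactive", {
  # degenerate one-allele-per-group nomenclature (the DPB1 pattern)
  dm <- tiny_distmat(list(
    `DPB1*01:01` = "10A", `DPB1*02:01` = "10C", `DPB1*03:01` = "10D"),
    hla_class = "II")
  crt <- cross_reactive_table(dm)
  expect_true(all(crt$is_cr))
})

test_that("disparity graphs connect monomorphic clusters and label distances", {
  dm <- tiny_distmat(list(
    `A*01:01` = c("10A", "20C"), `A*01:02` = c("10A", "20C"),
    `A*01:03` = c("10A", "20C"), `A*01:04` = c("10D", "20E")))
  g <- disparity_graph(dm, "A*01")
  ed <- igraph::as_data_frame(g, "edges")
  expect_equal(sum(ed$distance == 0), 3)  # triangle of monomorphic edges
  expect_true(all(ed$monomorphic[ed$distance == 0]))
  expect_equal(sort(unique(ed$distance)), c(0, 2))
  expect_false(any(igraph::V(g)$is_external))
  cl <- igraph::V(g)$cluster
  names(cl) <- igraph::V(g)$name
  expect_equal(unname(cl[c("A*01:01", "A*01:02", "A*01:03")]), rep("M1", 3))
  expect_true(is.na(cl[["A*01:04"]]))
})

test_that("cross-reactive alleles pull their foreign neighbours in as external nodes", {
  reg <- tiny_registry(list(
    `A*01:01` = c("10A", "20C", "30D", "40E"),
    `A*01:02` = c("10F", "20G", "30H", "40I"),  # d=4 to own group, d=1 to A*02
    `A*02:01` = c("10F", "20G", "30H", "40K"),
    `A*02:02` = c("10F", "20G", "30H", "40K")))
  dm <- distance_matrix(build_atlas(reg))
  g <- disparity_graph(dm, "A*01")
  v <- igraph::as_data_frame(g, "vertices")
  expect_setequal(v$name[v$is_external], c("A*02:01", "A*02:02"))
  ed <- igraph::as_data_frame(g, "edges")
  ext <- ed[ed$from == "A*01:02" | ed$to == "A*01:02", ]
  expect_true(all(ext$distance %in% c(1, 4)))
  expect_true(any(ext$distance == 1))
  expect_error(disparity_graph(dm, "A*99"), "unknown group")
})

test_that("monomorphic clusters are the components of the zero-distance relation", {
  dm <- tiny_distmat(list(
    `A*01:01` = c("10A", "20C"), `A*01:02` = c("10A", "20C"),
    `A*01:03` = c("10A", "20C"), `A*01:04` = c("10D", "20E")))
  cl <- monomorphic_clusters(dm, "A*01")
  expect_equal(cl, list(c("A*01:01", "A*01:02", "A*01:03")))
  # all-distinct group reports nothing
  dm2 <- tiny_distmat(list(`A*01:01` = "10A", `A*01:02` = "10C"))
  expect_equal(monomorphic_clusters(dm2, "A*01"), list())
  # transitivity: d(a,b)=0 and d(b,c)=0 puts a and c together
  expect_true(all(c("A*01:01", "A*01:03") %in% cl[[1]]))
})

test_that("triangle inequality holds for singleton-residue profiles", {
  for (seed in 1:3) {
    sim <- simulate_registry(sim_params(
      groups_per_locus = 3, alleles_per_group = 5, n_planted_cross_reactive = 1,
      seed = seed))
    dm <- unclass(distance_matrix(build_atlas(sim$registry)))
    n <- nrow(dm)
    trios <- t(combn(n, 3))
    ok <- apply(trios, 1, function(t) {
      d <- c(dm[t[1], t[2]], dm[t[1], t[3]], dm[t[2], t[3]])
      all(c(d[1] <= d[2] + d[3], d[2] <= d[1] + d[3], d[3] <= d[1] + d[2]))
    })
    expect_true(all(ok))
  }
})

test_that("graph construction is deterministic and serializes reproducibly", {
  sim <- simulate_registry(sim_params(seed = 9))
  dm <- distance_matrix(build_atlas(sim$registry))
  g1 <- disparity_graph(dm, "A*01")
  g2 <- disparity_graph(dm, "A*01")
  expect_true(igraph::identical_graphs(g1, g2))
  f1 <- file.path(tempdir(), "g1.graphml")
  f2 <- file.path(tempdir(), "g2.graphml")
  write_graphml(g1, f1)
  write_graphml(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # JSON adjacency carries the node/edge attributes
  j <- graph_to_json(g1)
  expect_named(j, c("focus_group", "namespace", "policy", "nodes", "edges"))
  expect_equal(j$focus_group, "A*01")
})
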