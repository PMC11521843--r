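# Synthetic registries with planted structure: monomorphic cores, halo
# alleles at a fixed distance, and cross-reactive alleles built strictly
# nearer to a foreign group's signature. The planted structure is created by
# eplet sharing, never by editing distances, so every emitted registry is
# internally consistent and the analysis pipeline can be checked against the
# construction ground truth.

# Loci used by the simulator, chosen so that each occupies its own default
# coordinate namespace (A has no B/C companion here, DRB1 no DRB3/4/5), which
# keeps the per-locus constructions independent.
SIM_LOCI <- c("A", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

#' Parameters for a simulated registry
#'
#' Validates a parameter set for [simulate_registry()]. Every group receives
#' a core eplet signature: `n_eplets_per_group` eplets tiling
#' `n_positions` consecutive positions, all built from one group-specific
#' residue letter. Alleles are then:
#' \describe{
#'   \item{core}{`monomorphic_core_size` alleles carrying the signature
#'     verbatim (pairwise distance 0).}
#'   \item{halo}{alleles whose first signature eplet is replaced by a
#'     variant differing at exactly `halo_mutation_distance` positions, each
#'     halo with its own variant letter (distance to the core is exactly the
#'     mutation distance).}
#'   \item{planted cross-reactive}{alleles assigned to one group but
#'     carrying a foreign group's signature mutated at a single position, so
#'     their nearest neighbour is the foreign core at distance 1 while every
#'     own-group allele is `n_positions` away.}
#' }
#' Constraints that the construction needs are checked here and violation
#' raises an error before anything is emitted: positions must tile evenly
#' into eplets, the mutation distance must fit inside one eplet and satisfy
#' `2*halo_mutation_distance + 2 <= n_positions` (so halos stay closer to
#' their own core than to anything foreign), at most one cross-reactive
#' allele is planted per group, cores must have at least 2 members whenever
#' cross-reactive alleles are planted (a singleton core targeted at
#' distance 1 would itself turn cross-reactive), and the 20-letter alphabet
#' must be large enough for the group and variant letters.
#'
#' @param n_loci number of loci (at most `length(SIM_LOCI)`; each locus
#'   occupies its own coordinate namespace).
#' @param groups_per_locus allele groups per locus.
#' @param alleles_per_group alleles per group (core + halo + planted).
#' @param monomorphic_core_size size of the monomorphic core cluster.
#' @param n_positions polymorphic positions per locus.
#' @param n_eplets_per_group eplets forming a group signature.
#' @param halo_mutation_distance exact Hamming distance of each halo allele
#'   to its group core.
#' @param n_planted_cross_reactive total planted cross-reactive alleles.
#' @param seed integer seed; the whole construction is deterministic given
#'   the seed.
#' @param loci optional explicit locus names (overrides `n_loci`).
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_loci = 1L, groups_per_locus = 4L, alleles_per_group = 8L,
                       monomorphic_core_size = 3L, n_positions = 12L,
                       n_eplets_per_group = 4L, halo_mutation_distance = 2L,
                       n_planted_cross_reactive = 2L, seed = 1L, loci = NULL) {
  p <- list(n_loci = as.integer(n_loci),
            groups_per_locus = as.integer(groups_per_locus),
            alleles_per_group = as.integer(alleles_per_group),
            monomorphic_core_size = as.integer(monomorphic_core_size),
            n_positions = as.integer(n_positions),
            n_eplets_per_group = as.integer(n_eplets_per_group),
            halo_mutation_distance = as.integer(halo_mutation_distance),
            n_planted_cross_reactive = as.integer(n_planted_cross_reactive),
            seed = as.integer(seed),
            loci = loci)
  if (is.null(p$loci)) {
    if (p$n_loci < 1L || p$n_loci > length(SIM_LOCI)) {
      stop(sprintf("n_loci must be between 1 and %d", length(SIM_LOCI)))
    }
    p$loci <- SIM_LOCI[seq_len(p$n_loci)]
  } else {
    stopifnot(all(p$loci %in% HLA_LOCI))
    p$n_loci <- length(p$loci)
  }
  with(p, {
    if (groups_per_locus < 1L || alleles_per_group < 1L) {
      stop("groups_per_locus and alleles_per_group must be positive")
    }
    if (monomorphic_core_size < 1L || monomorphic_core_size > alleles_per_group) {
      stop("monomorphic_core_size must be in 1..alleles_per_group")
    }
    if (n_positions %% n_eplets_per_group != 0L) {
      stop("n_positions must be a multiple of n_eplets_per_group")
    }
    run_len <- n_positions %/% n_eplets_per_group
    if (halo_mutation_distance < 1L || halo_mutation_distance > run_len) {
      stop("halo_mutation_distance must be in 1..(n_positions / n_eplets_per_group)")
    }
    if (2L * halo_mutation_distance + 2L > n_positions) {
      stop("need 2*halo_mutation_distance + 2 <= n_positions for the planted distances to hold")
    }
    if (n_planted_cross_reactive > 0L) {
      if (groups_per_locus < 2L) {
        stop("planted cross-reactive alleles need at least 2 groups per locus")
      }
      if (monomorphic_core_size < 2L) {
        stop("planted cross-reactive alleles need monomorphic_core_size >= 2")
      }
      if (n_planted_cross_reactive > n_loci * groups_per_locus) {
        stop("at most one planted cross-reactive allele per group is supported")
      }
    }
    NULL
  })
  # halos use the first variant letters, planted cross-reactive alleles share
  # one reserved letter at the end of the variant alphabet
  n_halo_max <- p$alleles_per_group - p$monomorphic_core_size
  n_variant <- length(AA_ALPHABET) - p$groups_per_locus
  n_reserved <- as.integer(p$n_planted_cross_reactive > 0L)
  if (n_halo_max + n_reserved > n_variant) {
    stop(sprintf(
      "not enough amino-acid letters: %d halo + %d reserved letters needed, %d available",
      n_halo_max, n_reserved, n_variant))
  }
  structure(p, class = "sim_params")
}

#' Simulate an eplet registry with known ground truth
#'
#' Builds the registry described by [sim_params()] and returns it together
#' with the construction truth, so the full pipeline (atlas, distance
#' matrix, disparity graphs, summaries) can be validated by exact recovery.
#' Deterministic given `params$seed`: the same parameters always emit an
#' identical registry.
#'
#' @param params a [sim_params()] object.
#' @return list with elements
#'   \describe{
#'     \item{registry}{an [eplet_registry()].}
#'     \item{truth}{list with `planted_cross_reactive` (data.frame
#'       allele/target_group), `planted_clusters` (list of core allele
#'       sets of size >= 2), and `planted_distances` (data.frame a/b/d of
#'       constructed halo-core and cross-reactive-target distances).}
#'   }
#' @examples
#' sim <- simulate_registry(sim_params(seed = 42))
#' sim$truth$planted_cross_reactive
#' @export
simulate_registry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)

  run_len <- p$n_positions %/% p$n_eplets_per_group
  eplets <- list()   # name -> hla_class
  assignments <- list()
  cr_truth <- list()
  clusters <- list()
  planted_d <- list()

  # planted cross-reactive allele counts per (locus, group): round-robin
  cr_slots <- data.frame(locus_i = integer(), group_i = integer())
  if (p$n_planted_cross_reactive > 0) {
    k <- seq_len(p$n_planted_cross_reactive) - 1L
    cr_slots <- data.frame(locus_i = (k %% p$n_loci) + 1L,
                           group_i = ((k %/% p$n_loci) %% p$groups_per_locus) + 1L)
  }

  add_eplet <- function(start, residues, cls) {
    name <- paste0(start, paste(residues, collapse = ""))
    eplets[[name]] <<- cls
    name
  }

  for (li in seq_len(p$n_loci)) {
    locus <- p$loci[li]
    cls <- locus_class(locus)
    offset <- (li - 1L) * p$n_positions
    run_starts <- offset + (seq_len(p$n_eplets_per_group) - 1L) * run_len + 1L

    group_letters <- sample(AA_ALPHABET, p$groups_per_locus)
    variant_letters <- sample(setdiff(AA_ALPHABET, group_letters))
    locus_cr <- cr_slots[cr_slots$locus_i == li, , drop = FALSE]

    signature <- list()  # group index -> eplet names
    for (gi in seq_len(p$groups_per_locus)) {
      signature[[gi]] <- vapply(run_starts, function(s) {
        add_eplet(s, rep(group_letters[gi], run_len), cls)
      }, "")
    }

    for (gi in seq_len(p$groups_per_locus)) {
      group <- sprintf("%02d", gi)
      n_cr <- sum(locus_cr$group_i == gi)
      n_halo <- p$alleles_per_group - p$monomorphic_core_size - n_cr
      if (n_halo < 0) stop("alleles_per_group too small for core + planted alleles")
      protein <- 0L
      next_name <- function() {
        protein <<- protein + 1L
        paste0(locus, "*", group, ":", sprintf("%02d", protein))
      }

      core_names <- vapply(seq_len(p$monomorphic_core_size), function(i) next_name(), "")
      for (al in core_names) {
        assignments[[length(assignments) + 1L]] <-
          data.frame(allele = al, eplet = signature[[gi]], stringsAsFactors = FALSE)
      }
      if (length(core_names) >= 2) clusters[[length(clusters) + 1L]] <- core_names

      for (hi in seq_len(n_halo)) {
        al <- next_name()
        v <- variant_letters[hi]
        variant <- add_eplet(run_starts[1],
                             c(rep(v, p$halo_mutation_distance),
                               rep(group_letters[gi], run_len - p$halo_mutation_distance)),
                             cls)
        assignments[[length(assignments) + 1L]] <-
          data.frame(allele = al, eplet = c(variant, signature[[gi]][-1]),
                     stringsAsFactors = FALSE)
        planted_d[[length(planted_d) + 1L]] <-
          data.frame(a = al, b = core_names[1], d = p$halo_mutation_distance,
                     stringsAsFactors = FALSE)
      }

      if (n_cr > 0) {
        target <- (gi %% p$groups_per_locus) + 1L
        al <- next_name()
        w <- variant_letters[length(variant_letters)]  # reserved: never a halo letter
        variant <- add_eplet(run_starts[1],
                             c(w, rep(group_letters[target], run_len - 1L)),
                             cls)
        assignments[[length(assignments) + 1L]] <-
          data.frame(allele = al, eplet = c(variant, signature[[target]][-1]),
                     stringsAsFactors = FALSE)
        target_core <- paste0(locus, "*", sprintf("%02d", target), ":01")
        cr_truth[[length(cr_truth) + 1L]] <-
          data.frame(allele = al,
                     target_group = paste0(locus, "*", sprintf("%02d", target)),
                     stringsAsFactors = FALSE)
        planted_d[[length(planted_d) + 1L]] <-
          data.frame(a = al, b = target_core, d = 1L, stringsAsFactors = FALSE)
      }
    }
  }

  eplet_df <- data.frame(name = names(eplets),
                         hla_class = unlist(eplets, use.names = FALSE),
                         confirmed = TRUE, stringsAsFactors = FALSE)
  assignment_df <- do.call(rbind, assignments)
  registry <- eplet_registry(eplet_df, assignment_df)

  truth <- list(
    planted_cross_reactive = if (length(cr_truth) > 0) do.call(rbind, cr_truth) else
      data.frame(allele = character(), target_group = character(), stringsAsFactors = FALSE),
    planted_clusters = clusters,
    planted_distances = if (length(planted_d) > 0) do.call(rbind, planted_d) else
      data.frame(a = character(), b = character(), d = integer(), stringsAsFactors = FALSE)
  )
  list(registry = registry, truth = truth)
}

#' Write simulation truth as JSON
#'
#' @param truth the `truth` element of [simulate_registry()]'s result.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}
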