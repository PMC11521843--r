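# Group- and locus-level cross-reactivity and frequent-eplet summaries.

#' Eplets confirmed for more than a threshold fraction of a group
#'
#' Returns the eplets assigned to strictly more than `threshold` of the
#' group's alleles (default 0.8, i.e. the ">80% of the alleles" rule: an
#' eplet carried by exactly 4 of 5 alleles is excluded). Ordered by first
#' position, then name.
#'
#' @param registry an [eplet_registry()].
#' @param group group label, e.g. `"A*01"`.
#' @param threshold strict lower bound on the carried fraction.
#' @return character vector of eplet names.
#' @export
frequent_eplets <- function(registry, group, threshold = 0.8) {
  stopifnot(inherits(registry, "eplet_registry"))
  alleles <- group_alleles(registry, group)
  if (length(alleles) == 0) stop(sprintf("no alleles in group '%s'", group))
  asn <- registry$assignments[registry$assignments$allele %in% alleles, , drop = FALSE]
  counts <- table(asn$eplet)
  hits <- names(counts)[counts > threshold * length(alleles)]
  starts <- registry$eplets$start[match(hits, registry$eplets$name)]
  hits[order(starts, hits)]
}

#' Summary of one allele group
#'
#' Counts the group's cross-reactive alleles (strict nearest-neighbour
#' rule, see [classify_cross_reactive()]) and tallies, per foreign group,
#' the distinct foreign alleles that appear as nearest neighbours of the
#' group's cross-reactive members - distinct alleles, not edges. When a
#' registry is supplied, the group's frequent eplets are included.
#'
#' @param dm an `eplet_distmat` whose namespace contains the group.
#' @param group group label.
#' @param registry optional [eplet_registry()] for the frequent-eplet
#'   column.
#' @param threshold frequent-eplet threshold, see [frequent_eplets()].
#' @return an object of class `group_summary`: list with `group`,
#'   `n_alleles`, `n_cross_reactive`, `pct_cross_reactive` (fraction in
#'   [0,1]), `external_allele_counts` (named integer vector, foreign group
#'   -> distinct allele count; empty when there is no cross-reactivity) and
#'   `frequent_eplets` (character, or `NULL` without a registry).
#' @export
group_summary <- function(dm, group, registry = NULL, threshold = 0.8) {
  groups <- distmat_groups(dm)
  ingroup <- names(groups)[groups == group]
  if (length(ingroup) == 0) {
    stop(sprintf("unknown group '%s' in namespace '%s'", group, attr(dm, "namespace")))
  }
  cr <- character()
  ext <- character()
  for (a in ingroup) {
    cls <- classify_cross_reactive(dm, a)
    if (cls$is_cr) {
      cr <- c(cr, a)
      ext <- union(ext, nearest_neighbours(dm, a, "other_groups")$allele)
    }
  }
  ext_counts <- if (length(ext) > 0) {
    tab <- table(unname(groups[ext]))
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    cnt[order(-cnt, names(cnt))]
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(
    group = group,
    n_alleles = length(ingroup),
    n_cross_reactive = length(cr),
    pct_cross_reactive = length(cr) / length(ingroup),
    cross_reactive_alleles = sort(cr),
    external_allele_counts = ext_counts,
    frequent_eplets = if (!is.null(registry)) frequent_eplets(registry, group, threshold)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group %s: %d allele(s), %d cross-reactive (%.0f%%)\n",
              x$group, x$n_alleles, x$n_cross_reactive, 100 * x$pct_cross_reactive))
  if (length(x$external_allele_counts) > 0) {
    cat("  other-group alleles:", format_external_counts(x$external_allele_counts), "\n")
  }
  if (!is.null(x$frequent_eplets)) {
    cat("  frequent eplets:", paste(x$frequent_eplets, collapse = ", "), "\n")
  }
  invisible(x)
}

format_external_counts <- function(counts) {
  if (length(counts) == 0) return("-")
  paste(sprintf("%s (%d)", names(counts), counts), collapse = "; ")
}

#' Tabulate group summaries
#'
#' One row per group of the distance matrix (or per requested group), with
#' the columns of [group_summary()] rendered as printable strings: empty
#' cross-reactivity is shown as `"-"`.
#'
#' @inheritParams group_summary
#' @param groups group labels to include; default all groups in the matrix.
#' @return data.frame with columns `group`, `n_alleles`,
#'   `n_cross_reactive`, `pct_cross_reactive` (percent, 1 decimal),
#'   `cross_reactivity`, `other_group_alleles`, `frequent_eplets`.
#' @export
group_summary_table <- function(dm, registry = NULL, groups = NULL, threshold = 0.8) {
  if (is.null(groups)) groups <- sort(unique(unname(distmat_groups(dm))))
  rows <- lapply(groups, function(g) {
    s <- group_summary(dm, g, registry, threshold)
    data.frame(
      group = s$group,
      n_alleles = s$n_alleles,
      n_cross_reactive = s$n_cross_reactive,
      pct_cross_reactive = round(100 * s$pct_cross_reactive, 1),
      cross_reactivity = if (s$n_cross_reactive == 0) "-" else
        sprintf("%d (%.0f%%)", s$n_cross_reactive, 100 * s$pct_cross_reactive),
      other_group_alleles = format_external_counts(s$external_allele_counts),
      frequent_eplets = if (is.null(s$frequent_eplets)) NA_character_ else
        paste(s$frequent_eplets, collapse = ", "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-locus overview of cross-reactivity
#'
#' One row per locus in the atlas: number of groups, number of alleles,
#' average alleles per group (rounded to the nearest integer), and the
#' count and percentage (rounded to integer) of cross-reactive alleles.
#' Distances are computed within each locus's coordinate namespace, so for
#' example B alleles may find their nearest neighbour among C alleles.
#'
#' @param atlas an `eplet_atlas`.
#' @inheritParams distance_matrix
#' @return data.frame with columns `locus`, `n_groups`, `n_alleles`,
#'   `avg_alleles_per_group`, `n_cross_reactive`, `pct_cross_reactive`.
#' @export
locus_overview <- function(atlas, policy = c("difference", "shared_only"),
                           namespaces = default_namespaces()) {
  policy <- match.arg(policy)
  stopifnot(inherits(atlas, "eplet_atlas"))
  info <- atlas$info
  info$namespace <- namespace_of_locus(info$locus, namespaces)
  rows <- list()
  for (ns in unique(info$namespace)) {
    dm <- distance_matrix(atlas, namespace = ns, policy = policy,
                          namespaces = namespaces)
    crt <- cross_reactive_table(dm)
    crt$locus <- info$locus[match(crt$allele, info$allele)]
    for (loc in sort(unique(crt$locus))) {
      sub <- crt[crt$locus == loc, , drop = FALSE]
      n_groups <- length(unique(sub$group))
      n_alleles <- nrow(sub)
      n_cr <- sum(sub$is_cr)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc,
        n_groups = n_groups,
        n_alleles = n_alleles,
        avg_alleles_per_group = as.integer(round(n_alleles / n_groups)),
        n_cross_reactive = n_cr,
        pct_cross_reactive = as.integer(round(100 * n_cr / n_alleles)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$locus, HLA_LOCI)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a data.frame as a Markdown table
#'
#' Minimal pipe-table renderer used by the summary and mismatch writers so
#' the Markdown and TSV outputs agree cell for cell.
#'
#' @param df a data.frame of atomic columns.
#' @return character vector of Markdown lines.
#' @export
markdown_table <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0) return(c(header, sep))
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(cells)] <- ""
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
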