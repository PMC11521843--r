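# Per-allele polymorphic amino-acid profiles and motif prevalence.

#' Build the polymorphic amino-acid profile of one allele
#'
#' Collects every eplet assigned to the allele, expands each name to its
#' residue map and merges the maps into a single sparse profile: position ->
#' set of allowed residues. Where two eplets cover the same position, their
#' residue sets are merged by intersection; an empty intersection means the
#' registry is internally inconsistent for this allele and raises a conflict
#' error (condition class `epletatlas_conflict`) naming the allele, the
#' position and the clashing eplets.
#'
#' @param registry an [eplet_registry()].
#' @param allele allele name (canonical or with `HLA-` prefix).
#' @return an object of class `allele_profile`: list with `allele`, `locus`,
#'   `group_label`, `residues` (named list position -> residue set, ordered
#'   by position) and `eplets` (the source eplet names).
#' @examples
#' prof <- build_profile(example_registry(), "A*01:01")
#' length(prof$residues)  # 21 covered positions
#' @export
build_profile <- function(registry, allele) {
  stopifnot(inherits(registry, "eplet_registry"))
  a <- parse_allele_name(allele)
  eplets <- registry$assignments$eplet[registry$assignments$allele == a$allele]
  if (length(eplets) == 0) {
    stop(sprintf("allele %s has no eplet assignments in the registry", a$allele))
  }
  maps <- registry_residues(registry, eplets)
  residues <- merge_residue_maps(maps, allele = a$allele)
  structure(list(allele = a$allele, locus = a$locus, group_label = a$group_label,
                 residues = residues, eplets = sort(unique(eplets))),
            class = "allele_profile")
}

# Merge named residue maps position-wise by intersection. `maps` is a named
# list (eplet name -> residues list). Conflicts raise epletatlas_conflict.
merge_residue_maps <- function(maps, allele = "<unnamed>") {
  out <- list()
  src <- list()  # position -> eplet names contributing
  for (ep in names(maps)) {
    for (pos in names(maps[[ep]])) {
      new <- maps[[ep]][[pos]]
      if (is.null(out[[pos]])) {
        out[[pos]] <- new
        src[[pos]] <- ep
      } else {
        both <- intersect(out[[pos]], new)
        src[[pos]] <- c(src[[pos]], ep)
        if (length(both) == 0) {
          stop(structure(class = c("epletatlas_conflict", "error", "condition"),
                         list(message = sprintf(
                                "conflicting residues for %s at position %s (eplets %s): {%s} vs {%s}",
                                allele, pos, paste(src[[pos]], collapse = ", "),
                                paste(out[[pos]], collapse = ","), paste(new, collapse = ",")),
                              call = NULL,
                              allele = allele, position = as.integer(pos),
                              eplets = src[[pos]])))
        }
        out[[pos]] <- both
      }
    }
  }
  out[order(as.integer(names(out)))]
}

#' @export
print.allele_profile <- function(x, ...) {
  sets <- vapply(x$residues, paste, "", collapse = "/")
  cat(sprintf("profile of %s (%d positions from %d eplets)\n",
              x$allele, length(x$residues), length(x$eplets)))
  cat(" ", paste(sprintf("%s:%s", names(sets), sets), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.allele_profile <- function(x, ...) {
  sprintf("allele_profile(%s, %d positions)", x$allele, length(x$residues))
}

#' Build an atlas of allele profiles
#'
#' One [build_profile()] per allele in the registry, optionally restricted
#' by locus, group label or explicit allele list. With `lenient = TRUE`,
#' alleles whose profile raises a residue conflict are skipped with a
#' warning instead of aborting the build.
#'
#' @inheritParams build_profile
#' @param loci,groups,alleles optional filters (character vectors of locus
#'   names, group labels like `"A*01"`, or allele names).
#' @param lenient skip conflicted alleles with a warning.
#' @return an object of class `eplet_atlas`: list with `profiles` (named
#'   list of `allele_profile`) and `info` (data.frame allele/locus/group).
#' @export
build_atlas <- function(registry, loci = NULL, groups = NULL, alleles = NULL,
                        lenient = FALSE) {
  stopifnot(inherits(registry, "eplet_registry"))
  info <- registry$alleles
  if (!is.null(loci)) info <- info[info$locus %in% loci, , drop = FALSE]
  if (!is.null(groups)) info <- info[info$group_label %in% groups, , drop = FALSE]
  if (!is.null(alleles)) info <- info[info$allele %in% canonical_alleles(alleles), , drop = FALSE]
  if (nrow(info) == 0) stop("no alleles selected for the atlas")

  profiles <- list()
  for (al in info$allele) {
    p <- tryCatch(build_profile(registry, al), epletatlas_conflict = function(e) {
      if (lenient) {
        warning(sprintf("skipping %s: %s", al, conditionMessage(e)), call. = FALSE)
        NULL
      } else {
        stop(e)
      }
    })
    if (!is.null(p)) profiles[[al]] <- p
  }
  info <- info[info$allele %in% names(profiles), , drop = FALSE]
  rownames(info) <- NULL
  structure(list(profiles = profiles, info = info), class = "eplet_atlas")
}

#' @export
print.eplet_atlas <- function(x, ...) {
  cat(sprintf("eplet atlas: %d allele profile(s) across %d locus/loci\n",
              length(x$profiles), length(unique(x$info$locus))))
  invisible(x)
}

#' @export
`[[.eplet_atlas` <- function(x, i) x$profiles[[i]]

#' @export
length.eplet_atlas <- function(x) length(x$profiles)

#' Amino-acid prevalence per position across a set of profiles
#'
#' For each covered position, the prevalence of each residue across the
#' profiles. A profile whose residue set at a position has more than one
#' member (a `/` alternative) contributes weight `1/|set|` to each member,
#' so each covered profile contributes total weight 1 and, together with the
#' gap fraction (profiles not covering the position), every position column
#' sums to exactly 1.
#'
#' @param x an `eplet_atlas` or a list of `allele_profile` objects.
#' @return an object of class `motif_table`: list with `prevalence`
#'   (data.frame position/residue/prevalence), `gap` (data.frame
#'   position/gap_fraction) and `n_alleles`.
#' @export
motif_prevalence <- function(x) {
  profiles <- if (inherits(x, "eplet_atlas")) x$profiles else x
  if (length(profiles) == 0) stop("no profiles supplied")
  n <- length(profiles)
  rows <- list()
  for (p in profiles) {
    for (pos in names(p$residues)) {
      set <- p$residues[[pos]]
      rows[[length(rows) + 1L]] <- data.frame(
        position = as.integer(pos), residue = set, w = 1 / length(set),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  prev <- stats::aggregate(w ~ position + residue, long, sum)
  prev$prevalence <- prev$w / n
  prev$w <- NULL
  prev <- prev[order(prev$position, prev$residue), , drop = FALSE]
  rownames(prev) <- NULL

  cover <- stats::aggregate(w ~ position, long, sum)  # total weight = n covered
  gap <- data.frame(position = cover$position,
                    gap_fraction = 1 - cover$w / n)
  structure(list(prevalence = prev, gap = gap, n_alleles = n), class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("motif table: %d position(s) over %d allele(s)\n",
              nrow(x$gap), x$n_alleles))
  invisible(x)
}

#' Render a profile as an aligned sequence string
#'
#' One character per position of `positions`: the residue letter where the
#' profile covers the position with a single residue, `placeholder` where it
#' is uncovered, and `X` where the residue set has more than one member (the
#' detail is returned in the `ambiguities` attribute, e.g. `164 = "S/G"`).
#'
#' @param profile an `allele_profile`.
#' @param positions integer vector of positions to render; defaults to the
#'   full covered span `min..max` of the profile.
#' @param placeholder character used at uncovered positions.
#' @return a one-character-per-position string with attribute `ambiguities`
#'   (named character vector, possibly empty).
#' @export
profile_to_sequence_string <- function(profile, positions = NULL, placeholder = ".") {
  stopifnot(inherits(profile, "allele_profile"))
  covered <- as.integer(names(profile$residues))
  if (is.null(positions)) {
    if (length(covered) == 0) return(structure("", ambiguities = character()))
    positions <- seq.int(min(covered), max(covered))
  }
  chars <- rep(placeholder, length(positions))
  amb <- character()
  for (i in seq_along(positions)) {
    set <- profile$residues[[as.character(positions[i])]]
    if (is.null(set)) next
    if (length(set) == 1L) {
      chars[i] <- set
    } else {
      chars[i] <- "X"
      amb[as.character(positions[i])] <- paste(set, collapse = "/")
    }
  }
  structure(paste(chars, collapse = ""), ambiguities = amb)
}

#' Export an atlas as a long TSV (allele, position, residues)
#'
#' @param atlas an `eplet_atlas`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_atlas_tsv <- function(atlas, path) {
  stopifnot(inherits(atlas, "eplet_atlas"))
  rows <- list()
  for (p in atlas$profiles) {
    rows[[length(rows) + 1L]] <- data.frame(
      allele = p$allele,
      position = as.integer(names(p$residues)),
      residues = vapply(p$residues, paste, "", collapse = "/"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an atlas as aligned FASTA-like text
#'
#' Each profile is rendered with [profile_to_sequence_string()] over a
#' common position range (default: the union span of all profiles) under a
#' `>allele` header line.
#'
#' @inheritParams write_atlas_tsv
#' @inheritParams profile_to_sequence_string
#' @export
write_atlas_alignment <- function(atlas, path, positions = NULL, placeholder = ".") {
  stopifnot(inherits(atlas, "eplet_atlas"))
  if (is.null(positions)) {
    all_pos <- unlist(lapply(atlas$profiles, function(p) as.integer(names(p$residues))))
    positions <- seq.int(min(all_pos), max(all_pos))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in atlas$profiles) {
    writeLines(c(paste0(">", p$allele),
                 as.character(profile_to_sequence_string(p, positions, placeholder))),
               con)
  }
  invisible(path)
}

#' Export a motif table as TSV
#'
#' Long format: position, residue, prevalence; gap fractions appear as
#' residue `"-"` rows so that each position's rows sum to 1.
#'
#' @param motif a `motif_table`.
#' @param path output file.
#' @export
write_motif_tsv <- function(motif, path) {
  stopifnot(inherits(motif, "motif_table"))
  gaps <- data.frame(position = motif$gap$position, residue = "-",
                     prevalence = motif$gap$gap_fraction, stringsAsFactors = FALSE)
  out <- rbind(motif$prevalence, gaps)
  out <- out[order(out$position, out$residue), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stacked-bar motif plot
#'
#' Prevalence of each amino acid per polymorphic position, stacked to at
#' most height 1; positions covered by no profile in the plotted range show
#' an empty bar. The full integer span between the first and last covered
#' position is shown so monomorphic/uncovered positions remain visible.
#'
#' @param motif a `motif_table`.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_motif <- function(motif, title = NULL) {
  stopifnot(inherits(motif, "motif_table"))
  span <- seq.int(min(motif$gap$position), max(motif$gap$position))
  df <- motif$prevalence
  df$position <- factor(df$position, levels = span)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = position, y = prevalence,
                                         fill = residue)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_discrete(drop = FALSE,
                              breaks = as.character(span[span %% 10 == 0])) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (mature protein)", y = "prevalence",
                  fill = "residue", title = title) +
    ggplot2::theme_minimal()
  gg
}
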