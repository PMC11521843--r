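# Registry container: validated eplet definitions + allele-eplet assignments.

#' Construct a validated eplet registry
#'
#' A registry couples a table of eplet definitions with a table of
#' allele-eplet assignments, mirroring the data model of an HLA Eplet
#' Registry export. Validation enforces referential integrity (every
#' assigned eplet is defined), uniqueness of definitions and assignment
#' rows, and HLA-class consistency (class I loci carry class I eplets only,
#' class II likewise).
#'
#' @param eplets data.frame with columns `name`, `hla_class` ("I"/"II") and
#'   `confirmed` (logical or "TRUE"/"FALSE"/"yes"/"no"/1/0).
#' @param assignments data.frame with columns `allele`, `eplet`. Extra
#'   columns are ignored.
#' @param confirmed_only drop eplets without antibody confirmation, and any
#'   assignments referring to them (default `TRUE`, following the
#'   restriction of the analysis to antibody-confirmed eplets).
#' @param include_null_alleles keep null-expression alleles (suffix `N`)?
#'   They are excluded from analysis by default.
#' @param lenient if `TRUE`, unparseable eplet names and duplicate rows are
#'   dropped with a warning instead of raising an error.
#' @return an object of class `eplet_registry`: a list with
#'   \describe{
#'     \item{eplets}{data.frame `name`, `hla_class`, `confirmed`, `start`,
#'       plus a list column `residues` (position -> residue set).}
#'     \item{assignments}{data.frame `allele`, `eplet`, `locus`,
#'       `group_label`.}
#'     \item{alleles}{data.frame of distinct alleles with parsed name
#'       fields.}
#'   }
#' @seealso [read_registry()], [write_registry()], [example_registry()]
#' @export
eplet_registry <- function(eplets, assignments, confirmed_only = TRUE,
                           include_null_alleles = FALSE, lenient = FALSE) {
  req_e <- c("name", "hla_class", "confirmed")
  req_a <- c("allele", "eplet")
  if (!all(req_e %in% names(eplets))) {
    stop(sprintf("eplet table must have columns: %s", paste(req_e, collapse = ", ")))
  }
  if (!all(req_a %in% names(assignments))) {
    stop(sprintf("assignment table must have columns: %s", paste(req_a, collapse = ", ")))
  }
  eplets <- data.frame(name = as.character(eplets$name),
                       hla_class = as.character(eplets$hla_class),
                       confirmed = parse_flag(eplets$confirmed),
                       stringsAsFactors = FALSE)
  if (anyNA(eplets$confirmed)) stop("eplet table: 'confirmed' must be TRUE/FALSE")
  if (!all(eplets$hla_class %in% c("I", "II"))) {
    stop("eplet table: 'hla_class' must be 'I' or 'II'")
  }
  if (anyDuplicated(eplets$name)) {
    dup <- unique(eplets$name[duplicated(eplets$name)])
    stop(sprintf("duplicate eplet definitions: %s", paste(dup, collapse = ", ")))
  }

  parsed <- vector("list", nrow(eplets))
  keep <- rep(TRUE, nrow(eplets))
  for (i in seq_len(nrow(eplets))) {
    res <- tryCatch(parse_eplet_name(eplets$name[i]), error = function(e) {
      if (lenient) {
        warning(sprintf("skipping unparseable eplet name '%s': %s",
                        eplets$name[i], conditionMessage(e)), call. = FALSE)
        NULL
      } else {
        stop(e)
      }
    })
    if (is.null(res)) keep[i] <- FALSE else parsed[[i]] <- res
  }
  eplets <- eplets[keep, , drop = FALSE]
  parsed <- parsed[keep]
  eplets$start <- vapply(parsed, function(p) p$start, 1L)
  eplets$residues <- I(lapply(parsed, function(p) p$residues))

  if (confirmed_only) {
    dropped <- eplets$name[!eplets$confirmed]
    eplets <- eplets[eplets$confirmed, , drop = FALSE]
    assignments <- assignments[!(assignments$eplet %in% dropped), , drop = FALSE]
  }

  assignments <- data.frame(allele = as.character(assignments$allele),
                            eplet = as.character(assignments$eplet),
                            stringsAsFactors = FALSE)
  unknown <- setdiff(assignments$eplet, eplets$name)
  if (length(unknown) > 0) {
    rows <- which(assignments$eplet %in% unknown)
    stop(sprintf("assignments reference undefined eplets (rows %s): %s",
                 paste(utils::head(rows, 10), collapse = ", "),
                 paste(unique(unknown), collapse = ", ")))
  }
  dup <- duplicated(assignments[c("allele", "eplet")])
  if (any(dup)) {
    if (lenient) {
      warning(sprintf("dropping %d duplicate assignment rows", sum(dup)), call. = FALSE)
      assignments <- assignments[!dup, , drop = FALSE]
    } else {
      stop(sprintf("duplicate assignment rows, e.g. %s / %s",
                   assignments$allele[dup][1], assignments$eplet[dup][1]))
    }
  }

  parsed_alleles <- lapply(unique(assignments$allele), parse_allele_name)
  alleles <- do.call(rbind, lapply(parsed_alleles, function(a) {
    data.frame(allele = a$allele, raw = a$raw, locus = a$locus, group = a$group,
               protein = a$protein, suffix = a$suffix, group_label = a$group_label,
               hla_class = a$hla_class, stringsAsFactors = FALSE)
  }))
  if (is.null(alleles)) {
    alleles <- data.frame(allele = character(), raw = character(), locus = character(),
                          group = character(), protein = character(), suffix = character(),
                          group_label = character(), hla_class = character(),
                          stringsAsFactors = FALSE)
  }
  # normalise assignment allele names to the canonical form
  assignments$allele <- alleles$allele[match(assignments$allele, alleles$raw)]

  if (!include_null_alleles && nrow(alleles) > 0) {
    null_alleles <- alleles$allele[alleles$suffix == "N"]
    if (length(null_alleles) > 0) {
      message(sprintf("excluding %d null (N-suffix) allele(s): %s",
                      length(null_alleles), paste(null_alleles, collapse = ", ")))
      alleles <- alleles[!(alleles$allele %in% null_alleles), , drop = FALSE]
      assignments <- assignments[!(assignments$allele %in% null_alleles), , drop = FALSE]
    }
  }

  # class consistency: an allele may only carry eplets of its own HLA class
  cls <- merge(assignments, alleles[c("allele", "hla_class")], by = "allele")
  cls$eplet_class <- eplets$hla_class[match(cls$eplet, eplets$name)]
  bad <- cls[cls$hla_class != cls$eplet_class, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop(sprintf("HLA class mismatch between allele and eplet: %s",
                 paste(sprintf("%s/%s", bad$allele, bad$eplet)[seq_len(min(5, nrow(bad)))],
                       collapse = ", ")))
  }
  assignments$locus <- alleles$locus[match(assignments$allele, alleles$allele)]
  assignments$group_label <- alleles$group_label[match(assignments$allele, alleles$allele)]

  rownames(eplets) <- NULL
  rownames(assignments) <- NULL
  rownames(alleles) <- NULL
  structure(list(eplets = eplets, assignments = assignments, alleles = alleles),
            class = "eplet_registry")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' @export
print.eplet_registry <- function(x, ...) {
  cat(sprintf("eplet registry: %d eplet(s) (%d confirmed), %d allele(s), %d assignment(s)\n",
              nrow(x$eplets), sum(x$eplets$confirmed), nrow(x$alleles), nrow(x$assignments)))
  if (nrow(x$alleles) > 0) {
    tab <- table(x$alleles$locus)
    cat("  loci:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read an eplet registry from delimited tables
#'
#' Reads the two-table registry dialect: an eplet-definition table with
#' columns `name`, `hla_class`, `confirmed` and an assignment table with
#' columns `allele`, `eplet`. Tab-separated by default; pass `delim = ","`
#' for CSV. A header row is mandatory; extra columns are ignored.
#'
#' @param eplets_path,assignments_path paths to the two tables.
#' @param delim field delimiter (default tab).
#' @inheritParams eplet_registry
#' @return an [eplet_registry()] object.
#' @export
read_registry <- function(eplets_path, assignments_path, confirmed_only = TRUE,
                          include_null_alleles = FALSE, lenient = FALSE,
                          delim = "\t") {
  for (p in c(eplets_path, assignments_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  e <- utils::read.delim(eplets_path, sep = delim, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  a <- utils::read.delim(assignments_path, sep = delim, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  eplet_registry(e, a, confirmed_only = confirmed_only,
                 include_null_alleles = include_null_alleles, lenient = lenient)
}

#' Write an eplet registry to delimited tables
#'
#' Inverse of [read_registry()]: writes the definition and assignment tables
#' so that reading them back reproduces the registry (raw eplet names,
#' including `/` alternatives, are preserved verbatim).
#'
#' @param registry an [eplet_registry()] object.
#' @inheritParams read_registry
#' @return invisibly, the two paths.
#' @export
write_registry <- function(registry, eplets_path, assignments_path, delim = "\t") {
  stopifnot(inherits(registry, "eplet_registry"))
  e <- registry$eplets[c("name", "hla_class", "confirmed")]
  a <- registry$assignments[c("allele", "eplet")]
  utils::write.table(e, eplets_path, sep = delim, quote = FALSE, row.names = FALSE)
  utils::write.table(a, assignments_path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(c(eplets_path, assignments_path))
}

#' The bundled example registry
#'
#' A small registry shipped with the package, transcribed from published
#' antibody-confirmed eplet listings for selected common HLA class I allele
#' groups: the complete 10-eplet listing for A*01:01 (with A*01:02 as its
#' monomorphic companion carrying the same confirmed eplets, plus the
#' unconfirmed 9S/17S pair), the most-frequent-eplet signatures of common
#' A, B and C allele groups assigned to one representative allele per group,
#' and a handful of per-allele additions inferred from published
#' donor-recipient mismatch listings (tagged `pair_inference` in the raw
#' TSV's `source` column). It is a fixture for documentation and tests, not
#' a registry snapshot: alleles absent from the published listings (e.g.
#' B*56:01) carry no assignments.
#'
#' A few published group signatures are internally inconsistent at
#' overlapping positions (e.g. 62GE with 62GK); profiles for those
#' representative alleles can only be built in lenient mode, which is
#' deliberate - the conflict surfaces instead of being patched.
#'
#' @param confirmed_only restrict to antibody-confirmed eplets (default).
#' @return an [eplet_registry()] object.
#' @examples
#' reg <- example_registry()
#' subset(reg$assignments, allele == "A*01:01")$eplet
#' @export
example_registry <- function(confirmed_only = TRUE) {
  read_registry(
    system.file("extdata", "example_eplets.tsv", package = "epletatlas", mustWork = TRUE),
    system.file("extdata", "example_assignments.tsv", package = "epletatlas", mustWork = TRUE),
    confirmed_only = confirmed_only
  )
}

#' Path to the bundled donor-recipient pairs table
#'
#' Nine published living-kidney-donation pairs typed at HLA-A, -B and -C,
#' in the TSV dialect accepted by [read_pairs()].
#'
#' @return a file path.
#' @export
example_pairs_path <- function() {
  system.file("extdata", "example_pairs.tsv", package = "epletatlas", mustWork = TRUE)
}

# eplet name -> residues list lookup
registry_residues <- function(registry, eplet_names) {
  idx <- match(eplet_names, registry$eplets$name)
  if (anyNA(idx)) {
    stop(sprintf("eplet(s) not in registry: %s",
                 paste(eplet_names[is.na(idx)], collapse = ", ")))
  }
  stats::setNames(registry$eplets$residues[idx], eplet_names)
}

# alleles of a group label such as "A*01"
group_alleles <- function(registry, group) {
  registry$alleles$allele[registry$alleles$group_label == group]
}
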