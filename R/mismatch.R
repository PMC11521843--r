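# Donor-recipient antigen/allele and eplet mismatch analysis.

#' Parse a genotype string
#'
#' Slash dialect: `"A*02:01/A*03:01"`. Homozygous genotypes may repeat the
#' allele (`"A*02:01/A*02:01"`) or give it once; either way the result is a
#' one-element set. All alleles must share one locus, which must equal
#' `locus` when given.
#'
#' @param x a genotype string.
#' @param locus optional expected locus.
#' @return character vector of 1 or 2 canonical allele names.
#' @export
parse_genotype <- function(x, locus = NULL) {
  if (!is.character(x) || length(x) != 1L || !nzchar(trimws(x))) {
    stop("genotype must be a single non-empty string like 'A*02:01/A*03:01'")
  }
  parts <- trimws(strsplit(x, "/", fixed = TRUE)[[1]])
  parsed <- lapply(parts, parse_allele_name)
  loci <- vapply(parsed, function(p) p$locus, "")
  if (length(unique(loci)) != 1L) {
    stop(sprintf("genotype '%s' mixes loci: %s", x, paste(unique(loci), collapse = ", ")))
  }
  if (!is.null(locus) && loci[1] != locus) {
    stop(sprintf("genotype '%s' is at locus %s, expected %s", x, loci[1], locus))
  }
  alleles <- unique(vapply(parsed, function(p) p$allele, ""))
  if (length(alleles) > 2L) {
    stop(sprintf("genotype '%s' lists more than two distinct alleles", x))
  }
  alleles
}

#' Antigen/allele mismatches at one locus
#'
#' Host-versus-graft direction: the donor alleles absent from the
#' recipient's allele set at the same locus. For graft-versus-host, swap
#' the arguments.
#'
#' @param recipient,donor character vectors of allele names at one locus
#'   (or genotype strings, which are parsed).
#' @return sorted character vector of mismatched donor alleles (0, 1 or 2).
#' @examples
#' allele_mismatches("A*02:01/A*03:01", "A*02:01/A*30:01")  # "A*30:01"
#' @export
allele_mismatches <- function(recipient, donor) {
  r <- as_allele_set(recipient)
  d <- as_allele_set(donor)
  if (parse_allele_name(r[1])$locus != parse_allele_name(d[1])$locus) {
    stop("recipient and donor genotypes are typed at different loci")
  }
  sort(setdiff(d, r))
}

as_allele_set <- function(x) {
  if (length(x) == 1L && grepl("/", x, fixed = TRUE)) {
    parse_genotype(x)
  } else {
    unique(canonical_alleles(x))
  }
}

#' Mismatched eplets of a donor-recipient pair at one locus
#'
#' The union of the eplets carried by the mismatched donor alleles, minus
#' the union of the eplets of the recipient's repertoire (set semantics:
#' an eplet shared by both mismatched donor alleles counts once). The
#' recipient repertoire is the recipient's alleles at the same locus by
#' default; pass additional alleles via `recipient_repertoire` to pool a
#' whole HLA class. Result ordered by eplet position, then name.
#'
#' @param registry an [eplet_registry()].
#' @param recipient,donor genotype strings or allele vectors at one locus.
#' @param recipient_repertoire optional character vector of further
#'   recipient alleles whose eplets also count as covered.
#' @param strict if `TRUE` (default), any involved allele absent from the
#'   registry raises an error naming it; if `FALSE`, absent alleles
#'   contribute an empty eplet set with a warning.
#' @return character vector of mismatched eplet names.
#' @export
eplet_mismatches <- function(registry, recipient, donor,
                             recipient_repertoire = NULL, strict = TRUE) {
  stopifnot(inherits(registry, "eplet_registry"))
  r <- as_allele_set(recipient)
  d <- as_allele_set(donor)
  mm <- allele_mismatches(r, d)
  if (length(mm) == 0) return(character())
  rep_alleles <- unique(c(r, if (!is.null(recipient_repertoire))
    canonical_alleles(recipient_repertoire)))
  donor_eplets <- allele_eplet_union(registry, mm, strict)
  covered <- allele_eplet_union(registry, rep_alleles, strict)
  out <- setdiff(donor_eplets, covered)
  starts <- registry$eplets$start[match(out, registry$eplets$name)]
  out[order(starts, out)]
}

allele_eplet_union <- function(registry, alleles, strict) {
  known <- unique(registry$assignments$allele)
  missing <- setdiff(alleles, known)
  if (length(missing) > 0) {
    if (strict) {
      stop(sprintf("allele(s) absent from the registry: %s",
                   paste(missing, collapse = ", ")))
    }
    warning(sprintf("allele(s) absent from the registry contribute no eplets: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  unique(registry$assignments$eplet[registry$assignments$allele %in% alleles])
}

#' Read a donor-recipient pairs table
#'
#' TSV with columns `pair_id`, `locus`, `recipient_genotype`,
#' `donor_genotype`; genotypes in the slash dialect of [parse_genotype()].
#' Each row is one pair at one locus. Malformed genotypes are reported with
#' their row number.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return data.frame with the four raw columns plus list columns
#'   `recipient_alleles`, `donor_alleles`.
#' @export
read_pairs <- function(path, delim = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  req <- c("pair_id", "locus", "recipient_genotype", "donor_genotype")
  if (!all(req %in% names(df))) {
    stop(sprintf("pairs table must have columns: %s", paste(req, collapse = ", ")))
  }
  rec <- vector("list", nrow(df))
  don <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rec[[i]] <- tryCatch(parse_genotype(df$recipient_genotype[i], df$locus[i]),
                         error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e))))
    don[[i]] <- tryCatch(parse_genotype(df$donor_genotype[i], df$locus[i]),
                         error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e))))
  }
  df$recipient_alleles <- I(rec)
  df$donor_alleles <- I(don)
  df
}

#' Mismatch report for a cohort of donor-recipient pairs
#'
#' For every row of a pairs table: the mismatched donor alleles
#' (host-versus-graft by default) and the mismatched-eplet set against the
#' recipient's repertoire. With `scope = "locus"` the repertoire is the
#' recipient's genotype at the row's locus; with `scope = "class"` it pools
#' all of the pair's recipient alleles at loci of the same HLA class across
#' the table.
#'
#' @param registry an [eplet_registry()].
#' @param pairs data.frame from [read_pairs()], or a path to one.
#' @param scope `"locus"` or `"class"`.
#' @param direction `"hvg"` (host versus graft, default) or `"gvh"`.
#' @inheritParams eplet_mismatches
#' @return data.frame with columns `pair_id`, `locus`,
#'   `n_allele_mismatches`, `mismatched_alleles`, `n_eplet_mismatches`,
#'   `mismatched_eplets` (comma-joined strings) plus list columns
#'   `allele_set`, `eplet_set`.
#' @export
mismatch_report <- function(registry, pairs, scope = c("locus", "class"),
                            direction = c("hvg", "gvh"), strict = TRUE) {
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    rec <- pairs$recipient_alleles[[i]]
    don <- pairs$donor_alleles[[i]]
    if (direction == "gvh") {
      tmp <- rec; rec <- don; don <- tmp
    }
    repertoire <- NULL
    if (scope == "class") {
      same_pair <- pairs$pair_id == pairs$pair_id[i]
      cls <- locus_class(pairs$locus[i])
      same_class <- locus_class(pairs$locus) == cls
      side <- if (direction == "gvh") pairs$donor_alleles else pairs$recipient_alleles
      repertoire <- unique(unlist(side[same_pair & same_class]))
    }
    mm <- allele_mismatches(rec, don)
    ep <- eplet_mismatches(registry, rec, don, recipient_repertoire = repertoire,
                           strict = strict)
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pairs$pair_id[i],
      locus = pairs$locus[i],
      n_allele_mismatches = length(mm),
      mismatched_alleles = paste(mm, collapse = ", "),
      n_eplet_mismatches = length(ep),
      mismatched_eplets = paste(ep, collapse = ", "),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$allele_set <- I(list(mm))
    rows[[length(rows)]]$eplet_set <- I(list(ep))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mismatch report
#'
#' TSV or Markdown rendering of the printable columns of
#' [mismatch_report()].
#'
#' @param report data.frame from [mismatch_report()].
#' @param path output file.
#' @param format `"tsv"` or `"markdown"`.
#' @export
write_mismatch_report <- function(report, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  cols <- c("pair_id", "locus", "n_allele_mismatches", "mismatched_alleles",
            "n_eplet_mismatches", "mismatched_eplets")
  df <- report[cols]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(markdown_table(df), path)
  }
  invisible(path)
}
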