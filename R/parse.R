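# Constants shared across modules.

#' The 20-letter amino-acid alphabet
#'
#' One-letter IUPAC symbols of the 20 proteinogenic amino acids, in
#' alphabetical order. Residue letters in eplet names must come from this
#' alphabet; the order fixes the bit assignment used internally to encode
#' residue sets.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CLASS_I_LOCI <- c("A", "B", "C")
CLASS_II_LOCI <- c("DRB1", "DRB3", "DRB4", "DRB5", "DQA1", "DQB1", "DPA1", "DPB1")

#' Classical HLA loci recognised by the package
#'
#' The 11 classical loci: the class I heavy chains A, B, C and the class II
#' chains DRB1, DRB3, DRB4, DRB5, DQA1, DQB1, DPA1, DPB1.
#'
#' @export
HLA_LOCI <- c(CLASS_I_LOCI, CLASS_II_LOCI)

#' @rdname HLA_LOCI
#' @param locus character vector of locus names.
#' @return `locus_class()`: "I" or "II" for each locus.
#' @export
locus_class <- function(locus) {
  bad <- setdiff(locus, HLA_LOCI)
  if (length(bad) > 0) {
    stop(sprintf("unknown HLA locus: %s", paste(unique(bad), collapse = ", ")))
  }
  ifelse(locus %in% CLASS_I_LOCI, "I", "II")
}

#' Parse an eplet name into its residue map
#'
#' Eplet names follow the registry grammar `<position><RESIDUES>[/<residue>]`:
#' an integer position in the mature protein (1-based), one or more uppercase
#' amino-acid letters placed at consecutive positions starting there, and an
#' optional `/`-separated alternative residue. The alternative is an
#' additional allowed residue at the *last* enumerated position, so
#' `"163LS/G"` reads as leucine at 163 and serine-or-glycine at 164. `"44KM"`
#' reads as lysine at 44 and methionine at 45.
#'
#' The grammar is total: every string either parses or raises an error naming
#' the offending token; there is no silent partial parse.
#'
#' @param name a single eplet name, e.g. `"44KM"`, `"90D"`, `"163LS/G"`.
#' @return an object of class `eplet_definition`: a list with elements
#'   `name` (the raw name), `start` (first position), and `residues`, a list
#'   mapping position (as character names) to a character vector of allowed
#'   residues. Only the last position may carry more than one residue.
#' @examples
#' parse_eplet_name("44KM")$residues     # 44 -> K, 45 -> M
#' parse_eplet_name("163LS/G")$residues  # 163 -> L, 164 -> S or G
#' @export
parse_eplet_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("eplet name must be a single character string")
  }
  if (!nzchar(name)) stop("eplet name is empty")
  m <- regmatches(name, regexec("^([0-9]+)([A-Z]+)(/([A-Z]))?$", name))[[1]]
  if (length(m) == 0L) {
    stop(sprintf(
      "malformed eplet name '%s': expected <position><RESIDUES>[/<residue>] with uppercase amino-acid letters",
      name))
  }
  start <- suppressWarnings(as.integer(m[2]))
  if (is.na(start) || start < 1L) {
    stop(sprintf("eplet name '%s': position '%s' is not a positive integer", name, m[2]))
  }
  letters <- strsplit(m[3], "", fixed = TRUE)[[1]]
  alt <- m[5]
  bad <- setdiff(c(letters, if (nzchar(alt)) alt), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("eplet name '%s': '%s' is not a standard amino-acid letter", name, bad[1]))
  }
  residues <- as.list(letters)
  if (nzchar(alt)) {
    k <- length(residues)
    residues[[k]] <- unique(c(residues[[k]], alt))
  }
  names(residues) <- as.character(seq.int(start, start + length(letters) - 1L))
  structure(list(name = name, start = start, residues = residues),
            class = "eplet_definition")
}

#' @export
print.eplet_definition <- function(x, ...) {
  sets <- vapply(x$residues, paste, "", collapse = "/")
  cat(sprintf("eplet %s: %s\n", x$name,
              paste(sprintf("%s:%s", names(sets), sets), collapse = " ")))
  invisible(x)
}

#' Parse an HLA allele name
#'
#' Accepts IPD-IMGT/HLA-style names with or without the `HLA-` prefix, e.g.
#' `"HLA-A*01:01"` or `"B*07:13"`. The locus must be one of the 11 classical
#' loci, the fields after `*` are colon-separated digit strings (at least
#' group and protein), and an optional trailing expression suffix
#' (N/Q/L/S/C/A) is retained.
#'
#' @param name a single allele name.
#' @return an object of class `hla_allele`: a list with `raw`, `locus`,
#'   `group` (first field), `protein` (second field), `suffix` (possibly
#'   empty), `allele` (canonical name without the `HLA-` prefix),
#'   `group_label` (e.g. `"A*01"`) and `hla_class` ("I" or "II").
#' @examples
#' parse_allele_name("HLA-A*01:01")$group_label
#' parse_allele_name("B*07:13")$protein
#' @export
parse_allele_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("allele name must be a single character string")
  }
  raw <- name
  x <- sub("^HLA-", "", trimws(name))
  if (!grepl("*", x, fixed = TRUE)) {
    stop(sprintf("allele name '%s': missing '*' locus separator", raw))
  }
  locus <- sub("\\*.*$", "", x)
  if (!(locus %in% HLA_LOCI)) {
    stop(sprintf("allele name '%s': unknown locus '%s'", raw, locus))
  }
  rest <- sub("^[^*]*\\*", "", x)
  suffix <- ""
  if (grepl("[NQLSCA]$", rest)) {
    suffix <- substr(rest, nchar(rest), nchar(rest))
    rest <- substr(rest, 1L, nchar(rest) - 1L)
  }
  fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
  if (length(fields) < 2L || !all(grepl("^[0-9]+$", fields))) {
    stop(sprintf(
      "allele name '%s': expected at least group and protein fields of digits separated by ':'",
      raw))
  }
  structure(list(
    raw = raw,
    locus = locus,
    group = fields[1],
    protein = fields[2],
    suffix = suffix,
    allele = paste0(locus, "*", paste(fields, collapse = ":"), suffix),
    group_label = paste0(locus, "*", fields[1]),
    hla_class = locus_class(locus)
  ), class = "hla_allele")
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(sprintf("HLA allele %s (locus %s, group %s, protein %s%s)\n",
              x$allele, x$locus, x$group, x$protein,
              if (nzchar(x$suffix)) paste0(", suffix ", x$suffix) else ""))
  invisible(x)
}

# Vectorised canonical form; errors on the first unparseable name.
canonical_alleles <- function(names) {
  vapply(names, function(n) parse_allele_name(n)$allele, "", USE.NAMES = FALSE)
}
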