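# In-code registry builders for tests.

# assignments: named list allele -> character vector of eplet names; every
# eplet defaults to confirmed.
tiny_registry <- function(assignments, hla_class = "I", unconfirmed = character(), ...) {
  eplets <- unique(unlist(assignments, use.names = FALSE))
  asn <- do.call(rbind, lapply(names(assignments), function(al) {
    data.frame(allele = al, eplet = assignments[[al]], stringsAsFactors = FALSE)
  }))
  eplet_registry(
    data.frame(name = eplets, hla_class = hla_class,
               confirmed = !(eplets %in% unconfirmed), stringsAsFactors = FALSE),
    asn, ...)
}

# atlas + distance matrix in one step for single-namespace registries
tiny_distmat <- function(assignments, hla_class = "I", policy = "difference", ...) {
  reg <- tiny_registry(assignments, hla_class = hla_class)
  distance_matrix(build_atlas(reg, ...), policy = policy)
}
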