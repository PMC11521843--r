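# Donor-recipient antigen/allele and eplet mismatch analysis.

test_that("allele mismatches are donor alleles absent from the recipient", {
  expect_equal(allele_mismatches("A*02:01/A*03:01", "A*02:01/A*30:01"), "A*30:01")
  expect_setequal(allele_mismatches("A*02:05/A*32:01", "A*03:01/A*24:02"),
                  c("A*03:01", "A*24:02"))
  expect_equal(allele_mismatches("A*02:01/A*03:01", "A*02:01/A*03:01"), character())
  expect_error(allele_mismatches("A*02:01/A*03:01", "B*07:02/B*08:01"),
               "different loci")
})

test_that("genotype strings parse with homozygosity as a one-element set", {
  expect_equal(parse_genotype("A*02:01/A*02:01"), "A*02:01")
  expect_equal(parse_genotype("A*02:01"), "A*02:01")
  expect_setequal(parse_genotype("A*02:01/A*03:01", locus = "A"),
                  c("A*02:01", "A*03:01"))
  expect_error(parse_genotype("A*02:01/B*07:02"), "mixes loci")
  expect_error(parse_genotype("A*02:01", locus = "B"), "expected B")
})

test_that("eplet mismatches are the uncovered eplets of mismatched donor alleles", {
  reg <- tiny_registry(list(
    `A*01:01` = c("10A", "20C", "30D"),   # mismatched donor allele
    `A*02:01` = c("20C", "30D"),          # recipient covers 20C, 30D
    `A*03:01` = "90K"))
  out <- eplet_mismatches(reg, c("A*02:01", "A*03:01"), c("A*01:01", "A*02:01"))
  expect_equal(out, "10A")

  # full coverage: an allele mismatch with zero eplet mismatches
  reg2 <- tiny_registry(list(
    `A*01:01` = c("10A", "20C"),
    `A*02:01` = c("10A", "20C", "30D")))
  expect_equal(eplet_mismatches(reg2, "A*02:01", "A*01:01"), character())

  # the uncovered remainder comes back ordered by position
  reg3 <- example_registry()
  out3 <- eplet_mismatches(reg3, "A*30:01/A*32:01", "A*01:01/A*30:01")
  expect_equal(out3, c("44KM", "76ANT", "90D", "144KR", "163RG", "166DG"))
})

test_that("zero allele mismatches imply zero eplet mismatches", {
  reg <- example_registry()
  expect_equal(eplet_mismatches(reg, "A*01:01/A*02:01", "A*01:01/A*02:01"),
               character())
})

test_that("mismatched eplets shrink monotonically as the recipient repertoire grows", {
  reg <- example_registry()
  base <- eplet_mismatches(reg, "C*07:01", "C*03:04/C*05:01")
  wider <- eplet_mismatches(reg, "C*07:01", "C*03:04/C*05:01",
                            recipient_repertoire = "C*04:01")
  expect_true(all(wider %in% base))
  expect_lt(length(wider), length(base))
})

test_that("mismatched-eplet sets ignore donor allele order and count shared eplets once", {
  reg <- example_registry()
  a <- eplet_mismatches(reg, "C*04:01/C*07:02", "C*03:04/C*05:01")
  b <- eplet_mismatches(reg, "C*04:01/C*07:02", "C*05:01/C*03:04")
  expect_identical(a, b)
  # 65QKR is carried by both donors but appears at most once
  expect_equal(anyDuplicated(a), 0)
})

test_that("alleles absent from the registry error by default and warn when not strict", {
  reg <- example_registry()
  expect_error(eplet_mismatches(reg, "B*35:01/B*56:01", "B*35:01/B*44:02"),
               "B\\*56:01")
  expect_warning(
    out <- eplet_mismatches(reg, "B*35:01/B*56:01", "B*35:01/B*44:02",
                            strict = FALSE),
    "B\\*56:01")
  expect_equal(out, c("41T", "45KE", "80TLR", "82LR", "156DA", "163LS/G"))
})

test_that("the pairs reader validates genotypes with row numbers", {
  path <- file.path(tempdir(), "pairs_bad.tsv")
  writeLines(c("pair_id\tlocus\trecipient_genotype\tdonor_genotype",
               "1\tA\tA*02:01/A*03:01\tA*02:01/A*30:01",
               "2\tA\tA*02:01/B*07:02\tA*02:01/A*30:01"), path)
  expect_error(read_pairs(path), "row 2")

  pairs <- read_pairs(example_pairs_path())
  expect_equal(nrow(pairs), 9)
  expect_equal(pairs$recipient_alleles[[1]], c("A*02:01", "A*03:01"))
})

test_that("the bundled cohort reproduces the published mismatch counts", {
  reg <- example_registry()
  rep <- suppressWarnings(
    mismatch_report(reg, read_pairs(example_pairs_path()), strict = FALSE))
  expect_equal(rep$n_allele_mismatches, c(1, 1, 2, 1, 1, 2, 1, 1, 2))
  expect_equal(rep$n_eplet_mismatches, c(1, 8, 5, 1, 6, 6, 1, 6, 5))
  expect_equal(rep$eplet_set[[1]], "56R")
  expect_equal(rep$eplet_set[[3]], c("62EE", "65GK", "144KR", "161D", "166DG"))
  expect_equal(rep$eplet_set[[8]],
               c("21H", "73TVS", "163LW", "173K", "193PV", "219W"))
})

test_that("class-wide repertoire scope can cover eplets across loci", {
  reg <- example_registry()
  pairs <- data.frame(
    pair_id = "p1", locus = c("A", "B"),
    recipient_genotype = c("A*25:01/A*32:01", "B*35:01/B*35:03"),
    donor_genotype = c("A*25:01/A*32:01", "B*35:01/B*44:02"),
    stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "pairs_class.tsv")
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_pairs(path)
  per_locus <- mismatch_report(reg, p, scope = "locus")
  class_wide <- mismatch_report(reg, p, scope = "class")
  # 82LR is carried by the recipient's A alleles, so it drops out class-wide
  expect_true("82LR" %in% per_locus$eplet_set[[2]])
  expect_false("82LR" %in% class_wide$eplet_set[[2]])
  expect_true(all(class_wide$eplet_set[[2]] %in% per_locus$eplet_set[[2]]))
})

test_that("graft-versus-host direction swaps the comparison", {
  reg <- example_registry()
  pairs <- read_pairs(example_pairs_path())[1, ]
  hvg <- mismatch_report(reg, pairs)
  gvh <- mismatch_report(reg, pairs, direction = "gvh")
  expect_equal(hvg$allele_set[[1]], "A*30:01")
  expect_equal(gvh$allele_set[[1]], "A*03:01")
})

test_that("reports serialize identically as TSV and Markdown", {
  reg <- example_registry()
  rep <- suppressWarnings(
    mismatch_report(reg, read_pairs(example_pairs_path()), strict = FALSE))
  tsv <- file.path(tempdir(), "mm.tsv")
  md <- file.path(tempdir(), "mm.md")
  write_mismatch_report(rep, tsv)
  write_mismatch_report(rep, md, format = "markdown")
  back <- read.delim(tsv, colClasses = "character")
  lines <- readLines(md)[-(1:2)]
  for (i in seq_len(nrow(back))) {
    cells <- strsplit(gsub("^\\| | \\|$", "", lines[i]), " \\| ")[[1]]
    expect_equal(unname(unlist(back[i, ])), cells)
  }
})
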