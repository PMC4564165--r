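test_that("variant keys are canonical, chr-normalized and injective", {
  expect_identical(variant_key("1", 68904047, "C", "A"), "1:68904047:C:A")
  expect_identical(variant_key("chr1", 68904047, "C", "A"), "1:68904047:C:A")
  # distinct alleles at the same site give distinct keys
  expect_false(variant_key("1", 100, "C", "A") == variant_key("1", 100, "C", "T"))
  expect_error(variant_key("1", 100, "C", "c"), "allele")
  expect_error(variant_key("1", 100, "C", "C"), "differ")
  expect_error(variant_key("1", 0, "C", "A"), "positive")
  expect_error(variant_key("1", 100, "N", "A"), "allele")
})

test_that("variant keys round-trip through parsing for random variants", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    chrom <- sample(c("1", "2", "X", "10"), 1)
    pos <- sample.int(1e8, 1)
    ref <- paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    key <- variant_key(chrom, pos, ref, alt)
    back <- parse_variant_key(key)
    expect_identical(unname(unlist(back)),
                     c(chrom, as.character(pos), ref, alt))
  }
})

test_that("genotype classification is total over well-formed diploid strings", {
  tokens <- c("0", "1", ".")
  seps <- c("/", "|")
  grid <- expand.grid(a = tokens, s = seps, b = tokens,
                      stringsAsFactors = FALSE)
  gts <- paste0(grid$a, grid$s, grid$b)
  out <- classify_genotype(gts)
  expect_length(out, 18L)
  expect_true(all(out %in% c("hom_ref", "het", "hom_alt", "missing")))
  # phase separator is irrelevant
  expect_identical(classify_genotype("0|1"), classify_genotype("0/1"))
  expect_identical(classify_genotype("1/1"), "hom_alt")
  expect_identical(classify_genotype("./."), "missing")
  expect_identical(classify_genotype("0/."), "missing")
  # multi-allelic residue and malformed strings raise
  expect_error(classify_genotype("2/1"), "allele index")
  expect_error(classify_genotype("0/2"), "allele index")
  expect_error(classify_genotype("1"), "malformed")
  expect_error(classify_genotype("0/1/1"), "malformed")
  expect_error(classify_genotype("A/B"), "malformed")
})

test_that("pedigree construction validates structure", {
  ok <- tibble::tibble(
    individual_id = c("F", "M", "C"),
    father_id = c("0", "0", "F"), mother_id = c("0", "0", "M"),
    sex = c("male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected"))
  p <- pedigree("P1", ok, loops = 1L)
  expect_s3_class(p, "ird_pedigree")
  # unresolved parent
  bad <- ok; bad$father_id[3] <- "GHOST"
  expect_error(pedigree("P1", bad), "resolve")
  # one-parent-only
  bad <- ok; bad$father_id[3] <- "0"
  expect_error(pedigree("P1", bad), "both or neither")
  # no affected member
  bad <- ok; bad$affection[3] <- "unaffected"
  expect_error(pedigree("P1", bad), "no affected")
  # parent-child cycle
  bad <- ok
  bad$father_id <- c("C", "0", "F")
  bad$mother_id <- c("M", "0", "M")
  expect_error(pedigree("P1", bad), "cycle")
})

test_that("pedigree identifier prefixes are cosmetic", {
  expect_true(same_pedigree_id("PKRD176", "PKRP176"))
  expect_false(same_pedigree_id("PKRD176", "PKRP142"))
})
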