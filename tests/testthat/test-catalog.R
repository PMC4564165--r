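test_that("tabulation counts distinct pedigrees and keeps SNVs only", {
  carriers <- tibble::tibble(
    pedigree_id = c("P1", "P2", "P2", "P3"),
    variant_key = c("1:100:C:A", "1:100:C:A", "1:100:C:A", "1:200:CT:C"))
  entries <- tabulate_by_pedigree(carriers)
  # duplicate (P2, variant) rows collapse; the indel never enters
  expect_identical(nrow(entries), 1L)
  expect_identical(entries$variant_key, "1:100:C:A")
  expect_identical(entries$pedigree_count, 2L)
  expect_identical(entries$pedigrees, "P1,P2")
})

test_that("population-unique extraction applies recurrence and absence", {
  entries <- tibble::tibble(
    variant_key = c("1:1:A:C", "1:2:A:C", "1:3:A:C"),
    chrom = "1", pos = 1:3, ref = "A", alt = "C",
    pedigree_count = c(5L, 6L, 4L),
    pedigrees = "x")
  membership <- list(dbSNP = tibble::tibble(variant_key = "1:2:A:C",
                                            hom_freq = NA_real_))
  kept <- population_unique_catalog(entries, membership, min_pedigrees = 5L)
  # 5 pedigrees + absent everywhere: kept; 6 but in dbSNP: out; 4: out
  expect_identical(kept$variant_key, "1:1:A:C")
  full <- attr(kept, "full")
  expect_identical(full$in_dbSNP, c(FALSE, TRUE, FALSE))
  expect_error(population_unique_catalog(entries, membership, 0L), "positive")
})

test_that("catalog size is non-increasing in threshold and database count", {
  set.seed(77)
  carriers <- tibble::tibble(
    pedigree_id = sample(paste0("P", 1:12), 600, replace = TRUE),
    variant_key = sample(variant_key("1", 1:40, "A", "G"), 600,
                         replace = TRUE))
  entries <- tabulate_by_pedigree(carriers)
  membership1 <- list(dbSNP = tibble::tibble(
    variant_key = sample(entries$variant_key, 10), hom_freq = NA_real_))
  membership2 <- c(membership1, list(HapMap = tibble::tibble(
    variant_key = sample(entries$variant_key, 10), hom_freq = 0.1)))
  sizes <- vapply(2:6, function(k)
    nrow(population_unique_catalog(entries, membership1, k)), integer(1))
  expect_true(all(diff(sizes) <= 0L))
  expect_lte(nrow(population_unique_catalog(entries, membership2, 3L)),
             nrow(population_unique_catalog(entries, membership1, 3L)))
})

test_that("catalog counts equal a brute-force recount of carrier pairs", {
  set.seed(31)
  raw <- tibble::tibble(
    pedigree_id = sample(paste0("P", 1:8), 400, replace = TRUE),
    variant_key = sample(variant_key("2", 1:25, "G", "T"), 400,
                         replace = TRUE))
  entries <- tabulate_by_pedigree(raw)
  # brute force: distinct pairs, counted per variant
  pairs <- unique(paste(raw$pedigree_id, raw$variant_key))
  brute <- table(sub("^\\S+ ", "", pairs))
  expect_identical(sum(entries$pedigree_count), as.integer(sum(brute)))
  for (k in entries$variant_key) {
    expect_identical(entries$pedigree_count[entries$variant_key == k],
                     as.integer(brute[[k]]))
  }
})
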