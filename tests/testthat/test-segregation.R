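toy_calls <- function(zyg) {
  tibble::tibble(variant_key = "1:1000:A:C", sample_id = names(zyg),
                 zygosity = unname(zyg))
}

test_that("segregation follows the complete-penetrance recessive model", {
  ped <- oracle_toy_pedigree()
  # all affected hom_alt, unaffected carriers or clear: segregates
  ok <- toy_calls(c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "hom_alt",
                    U1 = "hom_ref", X1 = "het"))
  r <- check_segregation(ok, ped)
  expect_true(r$segregates)
  expect_identical(nrow(r$inconsistent_members), 0L)
  # an unaffected homozygote refutes and is named
  bad <- toy_calls(c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "hom_alt",
                     U1 = "hom_alt", X1 = "het"))
  r <- check_segregation(bad, ped)
  expect_false(r$segregates)
  expect_identical(r$inconsistent_members$individual_id, "U1")
  # ...unless non-penetrance is explicitly allowed
  expect_true(check_segregation(bad, ped, allow_nonpenetrant = 1L)$segregates)
  # a heterozygous second affected refutes
  het2 <- toy_calls(c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "het",
                      U1 = "hom_ref", X1 = "het"))
  r <- check_segregation(het2, ped)
  expect_false(r$segregates)
  expect_identical(r$inconsistent_members$individual_id, "A2")
})

test_that("unknown-status members are excluded and ordering is irrelevant", {
  ped <- oracle_toy_pedigree()
  # the unknown-status member may be hom_alt without refuting
  zyg <- c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "hom_alt",
           U1 = "het", X1 = "hom_alt")
  r <- check_segregation(toy_calls(zyg), ped)
  expect_true(r$segregates)
  expect_identical(r$n_informative, 5L)
  # verdict invariant under member reordering
  set.seed(5)
  for (i in 1:20) {
    perm <- sample(names(zyg))
    expect_identical(check_segregation(toy_calls(zyg[perm]), ped)$segregates,
                     r$segregates)
  }
  # missing genotypes drop out of the informative count
  zyg2 <- zyg
  zyg2["U1"] <- "missing"
  expect_identical(check_segregation(toy_calls(zyg2), ped)$n_informative, 4L)
  expect_error(
    check_segregation(toy_calls(c(FA = "het", MO = "het")), ped),
    "no genotyped affected")
})

test_that("control screen policies treat carriers and homozygotes differently", {
  expect_true(screen_controls(96L, 0L, 0L)$novel_in_controls)
  # a heterozygous carrier is tolerated by default, refused under strict
  expect_true(screen_controls(96L, 1L, 0L)$novel_in_controls)
  expect_false(screen_controls(96L, 1L, 0L,
                               policy = "no_carriers")$novel_in_controls)
  expect_false(screen_controls(96L, 0L, 1L)$novel_in_controls)
  expect_error(screen_controls(0L), "non-empty")
  expect_error(screen_controls(96L, 90L, 10L), "exceed")
})

test_that("targeted screening applies the segregation contract to typed-only pedigrees", {
  members <- tibble::tibble(
    individual_id = c("FA", "MO", "A1", "A2", "A3", "U1"),
    father_id = c("0", "0", rep("FA", 4)),
    mother_id = c("0", "0", rep("MO", 4)),
    sex = c("male", "female", "male", "female", "male", "female"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  "affected", "unaffected"),
    genotyped = FALSE, sequenced = FALSE)
  ped <- pedigree("P285", members, loops = 6L)
  calls <- toy_calls(c(FA = "het", MO = "het", A1 = "hom_alt",
                       A2 = "hom_alt", A3 = "hom_alt", U1 = "het"))
  expect_true(targeted_screen(calls, ped)$segregates)
  calls$zygosity[calls$sample_id == "A2"] <- "hom_ref"
  expect_false(targeted_screen(calls, ped)$segregates)
  expect_error(targeted_screen(calls[0, ], ped), "at least one")
})
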