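test_that("pedigree simulation is reproducible and structurally sound", {
  cfg <- small_sim_config()
  p1 <- simulate_pedigree(cfg, seed = 99L, pedigree_id = "S1")
  p2 <- simulate_pedigree(cfg, seed = 99L, pedigree_id = "S1")
  expect_identical(p1$members, p2$members)
  cfg6 <- cohort_sim_config(loops_range = c(6L, 6L),
                            affected_range = c(6L, 6L),
                            genotyped_range = c(12L, 12L), seed = 1L)
  p6 <- simulate_pedigree(cfg6, seed = 7L)
  expect_identical(p6$loops, 6L)
  sim <- attr(p6, "sim")
  expect_identical(nrow(sim$loop_couples), 6L)
  # every loop couple shares the ancestral founder couple
  members <- p6$members
  grandparent <- function(id) {
    f <- members$father_id[members$individual_id == id]
    members$father_id[members$individual_id == f]
  }
  for (i in seq_len(6L)) {
    anc_f <- grandparent(sim$loop_couples$father[i])
    anc_m <- grandparent(sim$loop_couples$mother[i])
    expect_true("I-1" %in% c(anc_f, anc_m) || anc_f == anc_m)
  }
  # affected members arise only as loop-couple offspring
  aff <- members[members$affection == "affected", ]
  expect_true(all(paste(aff$father_id, aff$mother_id) %in%
                    paste(sim$loop_couples$father, sim$loop_couples$mother)))
})

test_that("loop offspring are inbred at least as much as first cousins", {
  cfg <- small_sim_config()
  for (seed in c(3L, 17L)) {
    ped <- simulate_pedigree(cfg, seed = seed)
    phi <- oracle_kinship(ped$members)
    sim <- attr(ped, "sim")
    for (i in seq_len(nrow(sim$loop_couples))) {
      f <- sim$loop_couples$father[i]
      m <- sim$loop_couples$mother[i]
      # child inbreeding coefficient = parental kinship
      expect_gte(phi[f, m], 1 / 16)
    }
  }
})

test_that("gene-dropped genotypes are Mendelian-consistent at every site", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(small_sim_config(n_pedigrees = 2L, seed = 13L), dir)
  for (cohort in gen$cohorts) {
    m <- cohort$pedigree$members
    gt <- cohort$genotypes
    zyg <- function(key, id) {
      z <- gt$zygosity[gt$variant_key == key & gt$sample_id == id]
      if (length(z)) z else "missing" # ungenotyped members are unobserved
    }
    trios <- m[m$father_id != "0" & m$genotyped, ]
    trios <- trios[m$genotyped[match(trios$father_id, m$individual_id)] &
                     m$genotyped[match(trios$mother_id, m$individual_id)], ]
    for (key in unique(gt$variant_key)) {
      for (i in seq_len(nrow(trios))) {
        expect_true(oracle_mendel_ok(zyg(key, trios$individual_id[i]),
                                     zyg(key, trios$father_id[i]),
                                     zyg(key, trios$mother_id[i])),
                    info = paste(cohort$pedigree$pedigree_id, key,
                                 trios$individual_id[i]))
      }
    }
  }
})

test_that("planted sites reach their configured genotype patterns", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(small_sim_config(n_pedigrees = 3L, seed = 59L), dir)
  for (pid in names(gen$cohorts)) {
    cohort <- gen$cohorts[[pid]]
    mp <- gen$manifest$pedigrees[[pid]]
    m <- cohort$pedigree$members
    gt <- cohort$genotypes
    aff <- m$individual_id[m$affection == "affected" & m$genotyped]
    causal <- gt[gt$variant_key == mp$causal_key, ]
    # every genotyped affected member is homozygous alternate at the
    # causal site; no genotyped unaffected member is
    expect_true(all(causal$zygosity[causal$sample_id %in% aff] == "hom_alt"))
    una <- m$individual_id[m$affection == "unaffected" & m$genotyped]
    expect_false(any(causal$zygosity[causal$sample_id %in% una] == "hom_alt"))
    # causal QC metrics always clear the default thresholds
    seq_ids <- m$individual_id[m$sequenced]
    sq <- causal[causal$sample_id %in% seq_ids, ]
    expect_true(all(sq$depth > 10 & sq$mapping_quality > 30 & !sq$strand_bias))
  }
})

test_that("generated annotation distances agree with region classification", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(small_sim_config(n_pedigrees = 1L, seed = 23L), dir)
  cohort <- gen$cohorts[[1L]]
  models <- read_gene_models(file.path(dir, "gene_models.gff3"))
  classified <- classify_region(cohort$variants, models)
  # the generator wrote its own geometric distances into the VCF; the
  # pipeline recomputes them from the gene models - they must agree
  written <- cohort$variants
  has_spl <- !is.na(written$splice_distance)
  expect_identical(classified$splice_distance[has_spl],
                   written$splice_distance[has_spl])
  has_utr <- !is.na(written$dist_upstream_of_start)
  expect_identical(classified$dist_upstream_of_start[has_utr],
                   written$dist_upstream_of_start[has_utr])
  expect_true(all(classified$region_class[has_spl] == "intronic"))
  expect_true(all(classified$region_class[has_utr] == "utr5"))
})

test_that("cohort generation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_sim_config(n_pedigrees = 2L, seed = 400L)
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the emitted genotypes
  d3 <- withr::local_tempdir()
  generate_cohort(small_sim_config(n_pedigrees = 2L, seed = 401L), d3)
  vcfs <- grep("\\.vcf$", files, value = TRUE)
  expect_false(identical(readLines(file.path(d1, vcfs[1])),
                         readLines(file.path(d3, vcfs[1]))))
})

test_that("infeasible simulation configurations are rejected", {
  expect_error(cohort_sim_config(loops_range = c(0L, 3L)), "1-6")
  expect_error(cohort_sim_config(affected_range = c(3L, 20L)), "1-12")
  expect_error(cohort_sim_config(predictor_noise = 1.5), "predictor_noise")
  expect_error(cohort_sim_config(n_pedigrees = 2L), "causal_recurrence")
})
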