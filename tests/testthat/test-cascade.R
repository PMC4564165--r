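seg_calls <- function(zyg) {
  tibble::tibble(sample_id = names(zyg), zygosity = unname(zyg))
}

test_that("recessive filter matches brute force over the affected/sib grid", {
  zygs <- c("hom_ref", "het", "hom_alt", "missing")
  for (aff in zygs) {
    for (sib in zygs) {
      calls <- seg_calls(c(A1 = aff, U1 = sib))
      got <- recessive_filter(calls, "A1", "U1")
      want <- if (aff == "missing") "not_applicable"
        else if (aff == "hom_alt" && sib != "hom_alt") "retained"
        else "eliminated"
      expect_identical(got$verdict, want,
                       info = paste("affected", aff, "sib", sib))
    }
  }
  expect_error(recessive_filter(seg_calls(c(A1 = "hom_alt")), character(0)),
               "no affected member sequenced")
})

test_that("frequency filter is strict at 0.5% and per-database", {
  cfg <- cascade_config()
  expect_identical(frequency_filter(c(`1000Genomes` = 0.006), cfg)$verdict,
                   "eliminated")
  expect_identical(frequency_filter(c(HapMap = 0.005, `1000Genomes` = 0.005,
                                      ESP6500 = 0.005), cfg)$verdict,
                   "retained")
  expect_identical(frequency_filter(stats::setNames(numeric(0), character(0)),
                                    cfg)$verdict, "retained")
  # presence with unknown frequency (dbSNP-style) never triggers the rule
  expect_identical(frequency_filter(c(dbSNP = NA_real_), cfg)$verdict,
                   "retained")
  # a non-configured database is ignored even at high frequency
  expect_identical(frequency_filter(c(ExAC = 0.2), cfg)$verdict, "retained")
  expect_identical(
    frequency_filter(c(ExAC = 0.2),
                     cascade_config(frequency_databases = "ExAC"))$verdict,
    "eliminated")
})

test_that("region classification reproduces hand-computed toy coordinates", {
  models <- toy_gene_models()
  mk <- function(chrom, pos, transcript = NA_character_) {
    v <- irdprior:::blank_annotation(1L)
    dplyr::bind_cols(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                                    ref = "A", alt = "C",
                                    variant_key = paste0(chrom, ":", pos, ":A:C")),
                     v[, setdiff(names(v), "transcript")],
                     tibble::tibble(transcript = transcript))
  }
  # RPE65 (plus strand): exon1 10001-10300, intron1 10301-10700 (1-based),
  # CDS starts at 10101
  r <- classify_region(mk("1", 10340), models)
  expect_identical(r$region_class, "intronic")
  expect_identical(r$splice_distance, 40L)
  # first intronic base on either side has distance 1
  expect_identical(classify_region(mk("1", 10301), models)$splice_distance, 1L)
  expect_identical(classify_region(mk("1", 10700), models)$splice_distance, 1L)
  # 3 bases upstream of the start codon, plus strand
  r <- classify_region(mk("1", 10098), models)
  expect_identical(r$region_class, "utr5")
  expect_identical(r$dist_upstream_of_start, 3L)
  # minus strand (LCA5 on chrom 2): upstream means higher coordinates
  r <- classify_region(mk("2", 11603), models)
  expect_identical(r$region_class, "utr5")
  expect_identical(r$dist_upstream_of_start, 3L)
  # between genes
  expect_identical(classify_region(mk("1", 9000), models)$region_class,
                   "nontranscribed")
  # coding SNV without consequence annotation is an absent state
  expect_identical(classify_region(mk("1", 10800), models)$region_class,
                   "coding_unknown")
})

test_that("missense predictor consensus requires unanimity of benign verdicts", {
  # two damaging / two benign (PROVEAN+MutationTaster vs SIFT+PolyPhen)
  # survives; this pattern reached candidacy in the reference cohort
  expect_identical(cascade_final(mk_variant(verdicts = c("damaging", "benign",
                                                         "damaging", "benign"))),
                   "candidate")
  expect_identical(cascade_final(mk_variant()), "candidate") # all damaging
  expect_identical(cascade_final(mk_variant(verdicts = rep("benign", 4))),
                   "eliminated")
  # a single damaging call among benigns retains
  expect_identical(cascade_final(mk_variant(verdicts = c("benign", "damaging",
                                                         "benign", "benign"))),
                   "candidate")
  # an absent verdict never counts as benign
  expect_identical(cascade_final(mk_variant(verdicts = c("benign", "benign",
                                                         "benign", "absent"))),
                   "candidate")
  # alternative consensus rules
  any_drops <- cascade_config(predictor_rule = "any_benign_drops")
  expect_identical(cascade_final(mk_variant(verdicts = c("damaging", "benign",
                                                         "damaging", "damaging")),
                                 any_drops), "eliminated")
  majority <- cascade_config(predictor_rule = "majority")
  expect_identical(cascade_final(mk_variant(verdicts = c("damaging", "benign",
                                                         "benign", "benign")),
                                 majority), "eliminated")
  expect_identical(cascade_final(mk_variant(verdicts = c("damaging", "benign",
                                                         "damaging", "benign")),
                                 majority), "candidate")
})

test_that("nonsense and indel variants bypass the predictor gate", {
  for (cls in c("coding_nonsense", "coding_indel_frameshift",
                "coding_indel_inframe")) {
    expect_identical(cascade_final(mk_variant(region_class = cls,
                                              verdicts = rep("absent", 4))),
                     "candidate")
  }
})

test_that("UTR, synonymous, intronic and biotype branches follow the rules", {
  # 5'UTR: retained only within 6 bases of the start codon
  expect_identical(cascade_final(mk_variant("utr5", dist_upstream_of_start = 6L)),
                   "candidate")
  expect_identical(cascade_final(mk_variant("utr5", dist_upstream_of_start = 7L)),
                   "eliminated")
  # 3'UTR: retained only in a miRNA-targeted region
  expect_identical(cascade_final(mk_variant("utr3", mirna_target = TRUE)),
                   "candidate")
  expect_identical(cascade_final(mk_variant("utr3", mirna_target = FALSE)),
                   "eliminated")
  # synonymous gated on the splice-alteration prediction
  expect_identical(cascade_final(mk_variant("coding_synonymous",
                                            splice_altering = FALSE)),
                   "eliminated")
  expect_identical(cascade_final(mk_variant("coding_synonymous",
                                            splice_altering = TRUE)),
                   "candidate")
  # intronic: 15-or-more bases from a splice site is out, nearer variants
  # need the splice-altering call
  expect_identical(cascade_final(mk_variant("intronic", splice_distance = 15L,
                                            splice_altering = TRUE)),
                   "eliminated")
  expect_identical(cascade_final(mk_variant("intronic", splice_distance = 14L,
                                            splice_altering = TRUE)),
                   "candidate")
  expect_identical(cascade_final(mk_variant("intronic", splice_distance = 14L,
                                            splice_altering = FALSE)),
                   "eliminated")
  expect_identical(cascade_final(mk_variant("nontranscribed")), "eliminated")
  # excluded biotypes and incomplete transcripts fall at the biotype stage
  for (bt in c("retained intron", "nonsense mediated decay", "pseudogene")) {
    r <- apply_cascade(mk_variant(biotype = bt), clean_calls(), clean_ped())
    expect_identical(r$final, "eliminated")
    expect_identical(r$trace$verdict[r$trace$stage == "biotype"], "eliminated")
  }
  expect_identical(cascade_final(mk_variant(complete_3p = FALSE)), "eliminated")
})

test_that("panel restriction routes off-panel survivors without dropping them", {
  variants <- dplyr::bind_rows(mk_variant(gene = "USH2A"),
                               mk_variant(gene = "NOTAPANELGENE"))
  variants$variant_key <- c("1:1000:A:C", "1:2000:A:C")
  variants$final <- "candidate"
  rp <- restrict_to_panel(variants, toy_gene_panel(), cascade_config())
  expect_identical(rp$candidates$gene, "USH2A")
  expect_identical(rp$off_panel$gene, "NOTAPANELGENE")
  open_cfg <- cascade_config(panel_restrict = FALSE)
  rp2 <- restrict_to_panel(variants, toy_gene_panel(), open_cfg)
  expect_identical(nrow(rp2$candidates), 2L)
  expect_error(restrict_to_panel(variants, character(0), cascade_config()),
               "empty")
})

test_that("enlarging the UTR window or frequency cutoff never shrinks the candidate set", {
  set.seed(123)
  base <- cascade_config()
  wider <- cascade_config(utr5_window = 12L, max_hom_genotype_freq = 0.01)
  ped <- clean_ped()
  calls <- clean_calls()
  for (i in 1:300) {
    v <- random_annotation_bundle()
    v$variant_key <- "1:1000:A:C"
    r0 <- apply_cascade(v, calls, ped, base)$final
    r1 <- apply_cascade(v, calls, ped, wider)$final
    if (r0 == "candidate") expect_identical(r1, "candidate")
  }
})
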