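mk_calls <- function(depth, mq, sb = FALSE, zyg = "hom_alt") {
  n <- max(lengths(list(depth, mq, sb, zyg)))
  tibble::tibble(sample_id = paste0("S", seq_len(n)),
                 zygosity = rep_len(zyg, n), depth = rep_len(depth, n),
                 mapping_quality = rep_len(mq, n),
                 strand_bias = rep_len(sb, n))
}

test_that("site QC thresholds are strict at the boundary", {
  expect_identical(passes_site_qc(mk_calls(c(15L, 22L), 60))$verdict,
                   "retained")
  # depth 10 and MQ 30 sit exactly on the thresholds and fail
  r <- passes_site_qc(mk_calls(c(10L, 22L), 60))
  expect_identical(r$verdict, "eliminated")
  expect_identical(r$reason, "depth")
  r <- passes_site_qc(mk_calls(15L, 30))
  expect_identical(r$verdict, "eliminated")
  expect_identical(r$reason, "mapping quality")
  expect_identical(passes_site_qc(mk_calls(11L, 31))$verdict, "retained")
  r <- passes_site_qc(mk_calls(c(15L, 22L), 60, sb = c(FALSE, TRUE)))
  expect_identical(r$verdict, "eliminated")
  expect_identical(r$reason, "strand bias")
  # strand-bias exclusion is configurable
  lax <- qc_thresholds(exclude_strand_bias = FALSE)
  expect_identical(passes_site_qc(mk_calls(15L, 60, sb = TRUE), lax)$verdict,
                   "retained")
})

test_that("missing calls are ignored; all-missing sites are not assessable", {
  calls <- mk_calls(c(5L, 50L), c(10, 60), zyg = c("missing", "hom_alt"))
  expect_identical(passes_site_qc(calls)$verdict, "retained")
  r <- passes_site_qc(mk_calls(NA_integer_, NA_real_, zyg = "missing"))
  expect_identical(r$verdict, "not_applicable")
  expect_identical(r$reason, "no data")
})

test_that("raising thresholds never converts a failing site to passing", {
  set.seed(9)
  base <- qc_thresholds()
  stricter <- list(qc_thresholds(min_depth_exclusive = 20),
                   qc_thresholds(min_mapping_quality_exclusive = 40),
                   qc_thresholds(min_depth_exclusive = 30,
                                 min_mapping_quality_exclusive = 50))
  for (i in 1:200) {
    calls <- mk_calls(sample(0:40, 3, replace = TRUE),
                      sample(0:60, 3, replace = TRUE),
                      sb = sample(c(TRUE, FALSE), 3, replace = TRUE,
                                  prob = c(.1, .9)),
                      zyg = sample(c("hom_alt", "het", "missing"), 3,
                                   replace = TRUE))
    if (all(calls$zygosity == "missing")) next
    v0 <- passes_site_qc(calls, base)$verdict
    for (th in stricter) {
      if (v0 == "eliminated") {
        expect_identical(passes_site_qc(calls, th)$verdict, "eliminated")
      }
    }
    # verdict does not depend on call ordering
    perm <- calls[sample.int(nrow(calls)), ]
    expect_identical(passes_site_qc(perm, base)$verdict, v0)
  }
})
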