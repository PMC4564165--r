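# Builders for single-variant cascade checks: a minimal trio pedigree,
# clean genotype calls, and an annotation-bundle constructor.

mk_variant <- function(region_class = "coding_missense",
                       verdicts = c("damaging", "damaging", "damaging",
                                    "damaging"),
                       splice_distance = NA_integer_,
                       splice_altering = NA,
                       dist_upstream_of_start = NA_integer_,
                       mirna_target = NA,
                       biotype = "protein coding",
                       complete_5p = TRUE, complete_3p = TRUE,
                       db_hom_freqs = stats::setNames(numeric(0), character(0)),
                       gene = "USH2A") {
  v <- irdprior:::blank_annotation(1L)
  v$gene <- gene
  v$biotype <- biotype
  v$complete_5p <- complete_5p
  v$complete_3p <- complete_3p
  v[c("mutation_taster", "polyphen", "provean", "sift")] <- as.list(verdicts)
  v$splice_distance <- splice_distance
  v$splice_altering <- splice_altering
  v$dist_upstream_of_start <- dist_upstream_of_start
  v$mirna_target <- mirna_target
  v$db_hom_freqs <- list(db_hom_freqs)
  dplyr::bind_cols(tibble::tibble(chrom = "1", pos = 1000L, ref = "A",
                                  alt = "C", variant_key = "1:1000:A:C"),
                   v, tibble::tibble(region_class = region_class))
}

clean_ped <- function() {
  pedigree("P", tibble::tibble(
    individual_id = c("FA", "MO", "A1"),
    father_id = c("0", "0", "FA"), mother_id = c("0", "0", "MO"),
    sex = c("male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected"),
    genotyped = TRUE, sequenced = c(FALSE, FALSE, TRUE)), loops = 1L)
}

clean_calls <- function(zyg = c(FA = "het", MO = "het", A1 = "hom_alt")) {
  tibble::tibble(variant_key = "1:1000:A:C", sample_id = names(zyg),
                 gt = "1/1", zygosity = unname(zyg), depth = 60L,
                 mapping_quality = 60, strand_bias = FALSE)
}

cascade_final <- function(variant, config = cascade_config()) {
  apply_cascade(variant, clean_calls(), clean_ped(), config)$final
}

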