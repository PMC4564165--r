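# Independent oracles used by the property tests. These deliberately
# re-derive each rule as standalone scalar logic, separate from the
# package's vectorized implementation.

ORACLE_DBS <- c("HapMap", "1000Genomes", "ESP6500")

oracle_qc_pass <- function(calls) {
  live <- calls[calls$zygosity != "missing", , drop = FALSE]
  if (nrow(live) == 0L) return(FALSE) # unassessable sites are excluded
  all(live$depth > 10) && all(live$mapping_quality > 30) &&
    !any(live$strand_bias)
}

oracle_recessive_pass <- function(calls, affected_ids, unaffected_ids) {
  aff <- calls[calls$sample_id %in% affected_ids &
                 calls$zygosity != "missing", , drop = FALSE]
  if (nrow(aff) == 0L) return(FALSE)
  una <- calls[calls$sample_id %in% unaffected_ids &
                 calls$zygosity != "missing", , drop = FALSE]
  all(aff$zygosity == "hom_alt") && !any(una$zygosity == "hom_alt")
}

oracle_frequency_pass <- function(freqs, cutoff = 0.005, dbs = ORACLE_DBS) {
  f <- freqs[names(freqs) %in% dbs]
  f <- f[!is.na(f)]
  !any(f > cutoff)
}

oracle_region_pass <- function(v, utr5_window = 6L, splice_cutoff = 15L,
                               rule = "all_benign_drops") {
  verdicts <- c(v$mutation_taster, v$polyphen, v$provean, v$sift)
  benign_gate <- switch(rule,
    all_benign_drops = all(verdicts == "benign"),
    any_benign_drops = any(verdicts == "benign"),
    majority = sum(verdicts == "benign") > sum(verdicts == "damaging"))
  switch(v$region_class,
    nontranscribed = FALSE,
    noncoding_exonic = FALSE,
    coding_unknown = FALSE,
    utr5 = !is.na(v$dist_upstream_of_start) &&
      v$dist_upstream_of_start <= utr5_window,
    utr3 = isTRUE(v$mirna_target),
    coding_missense = !benign_gate,
    coding_nonsense = TRUE,
    coding_indel_frameshift = TRUE,
    coding_indel_inframe = TRUE,
    coding_synonymous = isTRUE(v$splice_altering),
    intronic = !is.na(v$splice_distance) &&
      v$splice_distance < splice_cutoff && isTRUE(v$splice_altering),
    stop("oracle: unknown region class ", v$region_class))
}

oracle_biotype_pass <- function(v,
                                excluded = c("nonsense mediated decay",
                                             "retained intron", "pseudogene")) {
  if (!is.na(v$biotype) && v$biotype %in% excluded) return(FALSE)
  !(isFALSE(v$complete_5p) || isFALSE(v$complete_3p))
}

oracle_segregates <- function(affection, zygosity) {
  # affection, zygosity: named vectors over the genotyped members
  inform <- affection != "unknown" & zygosity != "missing"
  if (!any(inform)) return(FALSE)
  aff <- inform & affection == "affected"
  una <- inform & affection == "unaffected"
  all(zygosity[aff] == "hom_alt") && !any(zygosity[una] == "hom_alt")
}

# Wright's kinship coefficient by recursive tabular method; founders are
# unrelated and non-inbred. members: tibble with individual_id, father_id,
# mother_id (founder marker "0"), ordered parents-before-children.
oracle_kinship <- function(members) {
  ids <- members$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  parent <- function(p) if (p == "0") 0L else idx[[p]]
  for (i in seq_len(n)) {
    fi <- parent(members$father_id[i])
    mi <- parent(members$mother_id[i])
    for (j in seq_len(i - 1L)) {
      v <- if (fi == 0L) 0 else 0.5 * (phi[fi, j] + phi[mi, j])
      phi[i, j] <- phi[j, i] <- v
    }
    phi[i, i] <- if (fi == 0L) 0.5 else 0.5 * (1 + phi[fi, mi])
  }
  phi
}

# Mendelian consistency for one trio in zygosity space
oracle_mendel_ok <- function(child, father, mother) {
  copies <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  if (any(c(child, father, mother) == "missing")) return(TRUE)
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ch <- copies[[child]]
  any(outer(transmit[[as.character(copies[[father]])]],
            transmit[[as.character(copies[[mother]])]], `+`) == ch)
}

# --- randomized inputs -------------------------------------------------

random_annotation_bundle <- function() {
  classes <- c("coding_missense", "coding_nonsense", "coding_synonymous",
               "coding_indel_frameshift", "coding_indel_inframe",
               "coding_unknown", "noncoding_exonic", "intronic", "utr5",
               "utr3", "nontranscribed")
  cls <- sample(classes, 1L)
  verd <- function() sample(c("damaging", "benign", "absent"), 1L,
                            prob = c(0.4, 0.4, 0.2))
  freqs <- stats::setNames(numeric(0), character(0))
  for (db in c(ORACLE_DBS, "dbSNP")) {
    r <- stats::runif(1)
    if (r < 0.3) {
      freqs[db] <- if (db == "dbSNP") NA_real_ else
        sample(c(0.001, 0.004, 0.005, 0.006, 0.02), 1L)
    }
  }
  tibble::tibble(
    chrom = "1", pos = sample.int(100000L, 1L), ref = "A", alt = "C",
    gene = sample(c("USH2A", "RPE65", "OFFP1"), 1L),
    transcript = NA_character_,
    biotype = sample(c("protein coding", "nonsense mediated decay",
                       "retained intron", "pseudogene", NA_character_), 1L),
    complete_5p = sample(c(TRUE, FALSE, NA), 1L),
    complete_3p = sample(c(TRUE, FALSE, NA), 1L),
    mutation_taster = verd(), polyphen = verd(), provean = verd(),
    sift = verd(),
    coding_effect = NA_character_,
    splice_distance = if (cls == "intronic") sample(1:40, 1L) else NA_integer_,
    splice_altering = sample(c(TRUE, FALSE, NA), 1L),
    dist_upstream_of_start = if (cls == "utr5") sample(1:30, 1L) else NA_integer_,
    mirna_target = sample(c(TRUE, FALSE, NA), 1L),
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    db_hom_freqs = list(freqs),
    region_class = cls,
    variant_key = NA_character_
  )
}

oracle_toy_pedigree <- function() {
  pedigree("TOY", tibble::tibble(
    individual_id = c("FA", "MO", "A1", "A2", "U1", "X1"),
    father_id = c("0", "0", "FA", "FA", "FA", "FA"),
    mother_id = c("0", "0", "MO", "MO", "MO", "MO"),
    sex = c("male", "female", "male", "female", "male", "female"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  "unaffected", "unknown"),
    genotyped = TRUE,
    sequenced = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  ), loops = 1L)
}

random_calls <- function(ped) {
  m <- ped$members
  zyg <- sample(c("hom_ref", "het", "hom_alt", "missing"), nrow(m),
                replace = TRUE)
  tibble::tibble(
    variant_key = "1:1000:A:C",
    sample_id = m$individual_id,
    gt = c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
           missing = "./.")[zyg],
    zygosity = zyg,
    depth = sample(c(5L, 10L, 11L, 60L), nrow(m), replace = TRUE,
                   prob = c(0.05, 0.05, 0.1, 0.8)),
    mapping_quality = sample(c(20, 30, 31, 60), nrow(m), replace = TRUE,
                             prob = c(0.05, 0.05, 0.1, 0.8)),
    strand_bias = sample(c(TRUE, FALSE), nrow(m), replace = TRUE,
                         prob = c(0.05, 0.95))
  )
}

# convenience: a small noise-free simulation config for tests
small_sim_config <- function(n_pedigrees = 3L, seed = 101L, ...) {
  cohort_sim_config(n_pedigrees = n_pedigrees,
                    loops_range = c(1L, 3L),
                    affected_range = c(3L, 5L),
                    genotyped_range = c(5L, 9L),
                    n_decoys_per_class = 2L,
                    predictor_noise = 0,
                    causal_recurrence = min(2L, n_pedigrees),
                    seed = seed, ...)
}

run_config_for <- function(gen, dir, ...) {
  run_config(vcf = gen$vcf_paths, ped = gen$ped_paths,
             gene_models = file.path(dir, "gene_models.gff3"),
             panel = file.path(dir, "panel.txt"),
             membership = gen$membership_paths,
             controls = gen$controls_path, ...)
}
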