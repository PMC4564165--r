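# Bundled reference cohort: a code-built encoding of the per-pedigree
# candidate patterns reported for a 26-pedigree consanguineous IRD cohort
# (13 pedigrees resolved by homozygous variants in known IRD genes, one of
# them typed by targeted screening only; 13 with no surviving candidate).
# Pedigree structures are synthetic minimal reconstructions - only the
# genotype patterns that drive filtering, segregation and recurrence are
# encoded. Genomic coordinates live on the package's toy gene scaffold;
# the cDNA/protein labels are carried as annotations, not computed.

fixture_pedigree <- function(id, n_aff, n_una, loops, sequenced,
                             genotyped = NULL) {
  aff <- paste0("A", seq_len(n_aff))
  una <- if (n_una) paste0("U", seq_len(n_una)) else character(0)
  kids <- c(aff, una)
  members <- tibble::tibble(
    individual_id = c("FA", "MO", kids),
    father_id = c("0", "0", rep("FA", length(kids))),
    mother_id = c("0", "0", rep("MO", length(kids))),
    sex = c("male", "female",
            rep(c("male", "female"), length.out = length(kids))),
    affection = c("unaffected", "unaffected",
                  rep(c("affected", "unaffected"), c(n_aff, n_una)))
  )
  members$genotyped <- if (is.null(genotyped)) TRUE else
    members$individual_id %in% genotyped
  members$sequenced <- members$individual_id %in% sequenced
  pedigree(id, members, loops = loops)
}

fixture_variant <- function(models, gene, offset, effect,
                            verdicts = NULL, splice_altering = NA,
                            hgvs_c = NA_character_, hgvs_p = NA_character_,
                            db_hom_freqs = NULL, db_present = character(0)) {
  g <- gene_geom(models, gene)
  pos <- g$e2s + offset # 1-based position inside exon 2 (always CDS)
  if (effect == "frameshift") {
    ref <- paste0(ref_at(pos), ref_at(pos + 1L))
    alt <- ref_at(pos)
  } else if (effect == "delins") {
    ref <- paste0(ref_at(pos), ref_at(pos + 1L), ref_at(pos + 2L),
                  ref_at(pos + 3L), ref_at(pos + 4L))
    alt <- paste0(alt_at(pos), ref_at(pos + 1L), alt_at(pos + 2L))
    effect <- "frameshift" # net length change of 2 bases
  } else {
    ref <- ref_at(pos)
    alt <- alt_at(pos)
  }
  out <- tibble::tibble(chrom = g$tx$chrom, pos = as.integer(pos),
                        ref = ref, alt = alt, gene = gene,
                        transcript = g$tx$transcript)
  out <- fill_annotation_defaults(out, models)
  out$coding_effect <- effect
  out$hgvs_c <- hgvs_c
  out$hgvs_p <- hgvs_p
  out$splice_altering <- splice_altering
  if (!is.null(verdicts)) {
    # verdicts: 4-character string over {D,B} in the order
    # MutationTaster, PolyPhen, PROVEAN, SIFT
    v <- strsplit(verdicts, "")[[1L]]
    out[PREDICTOR_COLS] <- as.list(ifelse(v == "D", "damaging", "benign"))
  }
  freqs <- if (is.null(db_hom_freqs)) stats::setNames(numeric(0), character(0))
    else unlist(db_hom_freqs)
  for (db in db_present) freqs[db] <- NA_real_
  out$db_hom_freqs <- list(freqs)
  out$variant_key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out
}

# genotype patterns over a fixture pedigree; depth/MQ are clean constants
fixture_calls <- function(ped, key, role, breaker = NULL) {
  m <- ped$members
  gt <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    id <- m$individual_id[i]
    gt[i] <- switch(role,
      causal = if (m$affection[i] == "affected") "1/1"
        else if (id %in% c("FA", "MO")) "0/1"
        else if (i %% 2L == 0L) "0/1" else "0/0",
      nonseg = if (identical(id, breaker)) "0/1"
        else if (m$affection[i] == "affected") "1/1"
        else if (id %in% c("FA", "MO")) "0/1"
        else "0/0",
      cascade_fail = if (m$sequenced[i] && m$affection[i] == "affected") "1/1"
        else if (m$affection[i] == "affected") "1/1"
        else "0/1",
      stop("unknown role ", role)
    )
  }
  keep <- m$genotyped
  tibble::tibble(
    variant_key = key,
    sample_id = m$individual_id[keep],
    gt = gt[keep],
    zygosity = classify_genotype(gt[keep]),
    depth = 60L,
    mapping_quality = 60,
    strand_bias = FALSE
  )
}

#' Materialize the bundled reference cohort
#'
#' Writes the packaged encoding of the reference consanguineous IRD cohort
#' to `dir` (per-pedigree VCF + PED, gene models, panel, membership tables,
#' controls, known-variant list) and returns a ready [run_config()] for it:
#' 25 exome-sequenced pedigrees plus one pedigree typed by targeted
#' screening of a recurrent RPE65 variant, with the second co-segregating
#' ALMS1 candidate of one pedigree flagged uncertain in the causality
#' assignment.
#'
#' @param dir Directory to write the cohort files into (created if
#'   needed).
#' @param out_dir Optional report output directory passed through to the
#'   returned config.
#' @return A `run_config` ready for [run_pipeline()].
#' @export
reference_cohort <- function(dir, out_dir = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- toy_gene_models()
  panel <- toy_gene_panel()
  V <- function(...) fixture_variant(models, ...)

  gucy2d_077 <- V("GUCY2D", 10L, "missense", "DDDD",
                  hgvs_c = "c.2384G>T", hgvs_p = "p.Arg795Leu",
                  db_present = "dbSNP")
  col11a1_syn <- V("COL11A1", 16L, "synonymous", splice_altering = FALSE,
                   hgvs_c = "c.3906C>T")
  lca5_fs <- V("LCA5", 10L, "frameshift",
               hgvs_c = "c.1151delC", hgvs_p = "p.Pro384fs",
               db_present = "dbSNP")
  gucy2d_103 <- V("GUCY2D", 13L, "missense", "DDDD",
                  hgvs_c = "c.2189T>C", hgvs_p = "p.Phe730Ser")
  ush2a_fs <- V("USH2A", 20L, "frameshift",
                hgvs_c = "c.11473del", hgvs_p = "p.His3825fs")
  ush2a_stop <- V("USH2A", 23L, "nonsense",
                  hgvs_c = "c.4645C>T", hgvs_p = "p.Arg1549Ter")
  ush2a_mis <- V("USH2A", 26L, "missense", "DDDD",
                 hgvs_c = "c.12523T>G", hgvs_p = "p.Trp4175Gly")
  best1_mis <- V("BEST1", 10L, "missense", "DBDB",
                 hgvs_c = "c.1633C>A", hgvs_p = "p.Pro545Thr")
  cngb1_delins <- V("CNGB1", 10L, "delins",
                    hgvs_c = "c.2493-2_2495delinsGGC", hgvs_p = "p.Ser831fs")
  cep164_mis <- V("CEP164", 10L, "missense", "BDBB",
                  hgvs_c = "c.1702A>C", hgvs_p = "p.Thr568Pro")
  fam161a_stop <- V("FAM161A", 10L, "nonsense",
                    hgvs_c = "c.1600A>T", hgvs_p = "p.Lys534Ter")
  alms1_mis <- V("ALMS1", 10L, "missense", "BDDD",
                 hgvs_c = "c.5242A>G", hgvs_p = "p.Thr1748Ala")
  rax2_mis <- V("RAX2", 10L, "missense", "DDDD",
                hgvs_c = "c.236G>A", hgvs_p = "p.Arg79Gln")
  abhd12_mis <- V("ABHD12", 10L, "missense", "DDBB",
                  hgvs_c = "c.1045G>A", hgvs_p = "p.Ala349Thr")
  rpe65_mis <- V("RPE65", 10L, "missense", "DDDD",
                 hgvs_c = "c.1087C>A", hgvs_p = "p.Pro363Thr",
                 db_present = "dbSNP")
  jag1_mis <- V("JAG1", 10L, "missense", "DDDD",
                hgvs_c = "c.2612C>G", hgvs_p = "p.Pro871Arg")
  cdh23_mis <- V("CDH23", 10L, "missense", "DDDD",
                 hgvs_c = "c.127G>A", hgvs_p = "p.Val43Ile")

  known_variants <- c(gucy2d_077$variant_key, lca5_fs$variant_key,
                      rpe65_mis$variant_key)

  # pedigree_id -> list(pedigree, variants = list(list(variant, role, breaker)))
  specs <- list(
    PKRD077 = list(
      ped = fixture_pedigree("PKRD077", 3L, 1L, 2L, sequenced = "A1"),
      vars = list(list(gucy2d_077, "causal"),
                  list(col11a1_syn, "cascade_fail"))),
    PKRD078 = list(
      ped = fixture_pedigree("PKRD078", 2L, 2L, 3L, sequenced = c("A1", "U1")),
      vars = list(list(lca5_fs, "causal"))),
    PKRD103 = list(
      ped = fixture_pedigree("PKRD103", 3L, 1L, 1L, sequenced = "A1"),
      vars = list(list(gucy2d_103, "causal"))),
    PKRD138 = list(
      ped = fixture_pedigree("PKRD138", 2L, 1L, 1L, sequenced = "A1"),
      vars = list(list(ush2a_fs, "causal"))),
    PKRD141 = list(
      ped = fixture_pedigree("PKRD141", 2L, 1L, 4L, sequenced = "A1"),
      vars = list(list(ush2a_stop, "causal"),
                  list(best1_mis, "nonseg", "A2"))),
    PKRD142 = list(
      ped = fixture_pedigree("PKRD142", 3L, 1L, 6L, sequenced = "A1"),
      vars = list(list(cngb1_delins, "causal"),
                  list(cep164_mis, "nonseg", "A2"))),
    PKRD176 = list(
      ped = fixture_pedigree("PKRD176", 3L, 2L, 3L, sequenced = "A1"),
      vars = list(list(fam161a_stop, "causal"),
                  list(alms1_mis, "causal"),
                  list(rax2_mis, "nonseg", "A2"))),
    PKRD185 = list(
      ped = fixture_pedigree("PKRD185", 2L, 1L, 1L, sequenced = "A1"),
      vars = list(list(ush2a_mis, "causal"),
                  list(abhd12_mis, "nonseg", "A2"))),
    PKRD281 = list(
      ped = fixture_pedigree("PKRD281", 2L, 1L, 2L, sequenced = "A1"),
      vars = list(list(rpe65_mis, "causal"),
                  list(jag1_mis, "nonseg", "A2"))),
    PKRD282 = list(
      ped = fixture_pedigree("PKRD282", 2L, 1L, 2L,
                             sequenced = c("A1", "A2", "U1")),
      vars = list(list(rpe65_mis, "causal"))),
    PKRD283 = list(
      ped = fixture_pedigree("PKRD283", 2L, 1L, 2L, sequenced = c("A1", "A2")),
      vars = list(list(rpe65_mis, "causal"))),
    PKRD284 = list(
      ped = fixture_pedigree("PKRD284", 2L, 1L, 3L, sequenced = c("A1", "U1")),
      vars = list(list(rpe65_mis, "causal"),
                  list(cdh23_mis, "nonseg", "A2")))
  )
  # 13 pedigrees whose exome analysis reveals no surviving candidate:
  # one common variant (eliminated on homozygote frequency) and one
  # missense called benign by all four predictors (eliminated at region)
  for (u in seq_len(13L)) {
    pid <- sprintf("PKRD2%02d", u)
    freq_var <- V("GUCY2D", 40L + 2L * u, "missense", "DDDD",
                  db_hom_freqs = c(HapMap = 0.02))
    benign_var <- V("CERKL", 40L + 2L * u, "missense", "BBBB")
    specs[[pid]] <- list(
      ped = fixture_pedigree(pid, 2L, 1L, 1L, sequenced = "A1"),
      vars = list(list(freq_var, "cascade_fail"),
                  list(benign_var, "cascade_fail")))
  }

  vcf_paths <- character(0)
  ped_paths <- character(0)
  for (pid in names(specs)) {
    sp <- specs[[pid]]
    variants <- dplyr::bind_rows(lapply(sp$vars, `[[`, 1L))
    calls <- dplyr::bind_rows(lapply(sp$vars, function(v) {
      fixture_calls(sp$ped, v[[1L]]$variant_key, v[[2L]],
                    if (length(v) >= 3L) v[[3L]] else NULL)
    }))
    cohort <- cohort_input(sp$ped, variants, calls)
    vcf_paths[pid] <- file.path(dir, paste0(pid, ".vcf"))
    ped_paths[pid] <- file.path(dir, paste0(pid, ".ped"))
    write_cohort_vcf(cohort, vcf_paths[pid])
    write_ped(sp$ped, ped_paths[pid])
  }

  write_gene_models(models, file.path(dir, "gene_models.gff3"))
  write_gene_panel(panel, file.path(dir, "panel.txt"))

  all_vars <- dplyr::bind_rows(lapply(specs, function(sp)
    dplyr::bind_rows(lapply(sp$vars, `[[`, 1L))))
  all_vars <- dplyr::distinct(all_vars, .data$variant_key, .keep_all = TRUE)
  membership_paths <- character(0)
  for (db in c("HapMap", "1000Genomes", "ESP6500", "dbSNP")) {
    listed <- vapply(all_vars$db_hom_freqs, function(f) db %in% names(f),
                     logical(1))
    tab <- tibble::tibble(
      variant_key = all_vars$variant_key[listed],
      hom_freq = vapply(all_vars$db_hom_freqs[listed],
                        function(f) f[[db]], numeric(1)))
    path <- file.path(dir, paste0("db_", db, ".tsv"))
    write_membership_table(tab, path, with_freq = db != "dbSNP")
    membership_paths[db] <- path
  }
  controls <- tibble::tibble(
    variant_key = all_vars$variant_key,
    n_controls = 96L, n_het = 0L, n_hom = 0L)
  controls_path <- file.path(dir, "controls.tsv")
  write_controls(controls, controls_path)
  writeLines(known_variants, file.path(dir, "known_variants.txt"))

  # the 26th pedigree carries no exome data; the recurrent RPE65 variant
  # is typed directly in all participating members
  ped285 <- fixture_pedigree("PKRD285", 3L, 1L, 6L, sequenced = character(0),
                             genotyped = character(0))
  calls285 <- tibble::tibble(
    sample_id = c("FA", "MO", "A1", "A2", "A3", "U1"),
    zygosity = c("het", "het", "hom_alt", "hom_alt", "hom_alt", "het"),
    variant_key = rpe65_mis$variant_key)
  targeted <- list(list(pedigree = ped285,
                        variant_key = rpe65_mis$variant_key,
                        gene = "RPE65", calls = calls285))

  causality <- tibble::tibble(pedigree_id = "PKRD176",
                              variant_key = alms1_mis$variant_key,
                              uncertain = TRUE)

  run_config(
    vcf = vcf_paths, ped = ped_paths,
    gene_models = file.path(dir, "gene_models.gff3"),
    panel = file.path(dir, "panel.txt"),
    membership = membership_paths,
    controls = controls_path,
    known_variants = known_variants,
    causality = causality,
    targeted = targeted,
    out_dir = out_dir
  )
}
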