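# Recessive filter + eight-rule annotation cascade + known-gene panel
# restriction. Stages run in the fixed order
#   qc -> recessive -> frequency -> region -> biotype
# and every stage verdict is recorded in a per-variant FilterTrace, so
# input count = candidates + per-stage eliminations + off-panel survivors
# holds on every run.

#' Cascade configuration
#'
#' @param max_hom_genotype_freq A variant is eliminated when any configured
#'   frequency database reports a homozygous genotype frequency strictly
#'   greater than this (default 0.005, i.e. 0.5%; exactly 0.5% is retained).
#' @param utr5_window 5'UTR variants are retained only within this many
#'   bases upstream of the start codon (default 6; distance 1 = the base
#'   immediately 5' of the A of the ATG, spliced, in transcript
#'   orientation).
#' @param splice_far_cutoff Intronic variants at this distance or further
#'   from the nearest splice site are eliminated (default 15; the first
#'   intronic base has distance 1, so "15 or more" drops distance >= 15).
#' @param frequency_databases Databases consulted by the frequency rule,
#'   each tested separately (default HapMap, 1000Genomes, ESP6500).
#'   Presence with unknown frequency (dbSNP-style) never triggers the rule.
#' @param excluded_biotypes Transcript biotypes eliminated outright
#'   (default nonsense mediated decay, retained intron, pseudogene);
#'   5'- or 3'-incomplete transcripts are eliminated regardless.
#' @param panel_restrict Restrict candidates to the known-IRD gene panel
#'   (default `TRUE`); off-panel survivors are reported separately, never
#'   dropped silently.
#' @param predictor_rule How the four missense predictor verdicts
#'   (MutationTaster, PolyPhen, PROVEAN, SIFT) gate missense SNVs:
#'   `"all_benign_drops"` (default; eliminated only when all four verdicts
#'   are benign — a single damaging call, or an absent verdict, retains),
#'   `"any_benign_drops"`, or `"majority"` (eliminated when benign verdicts
#'   strictly outnumber damaging ones). Nonsense and indel variants bypass
#'   the gate entirely.
#' @param synonymous_splice_gate Retain synonymous variants only when
#'   predicted splice-altering (default `TRUE`).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(max_hom_genotype_freq = 0.005,
                           utr5_window = 6L,
                           splice_far_cutoff = 15L,
                           frequency_databases = c("HapMap", "1000Genomes",
                                                   "ESP6500"),
                           excluded_biotypes = c("nonsense mediated decay",
                                                 "retained intron",
                                                 "pseudogene"),
                           panel_restrict = TRUE,
                           predictor_rule = c("all_benign_drops",
                                              "any_benign_drops", "majority"),
                           synonymous_splice_gate = TRUE) {
  predictor_rule <- match.arg(predictor_rule)
  stopifnot(max_hom_genotype_freq >= 0, max_hom_genotype_freq <= 1,
            utr5_window >= 1, splice_far_cutoff >= 1)
  structure(list(
    max_hom_genotype_freq = max_hom_genotype_freq,
    utr5_window = as.integer(utr5_window),
    splice_far_cutoff = as.integer(splice_far_cutoff),
    frequency_databases = frequency_databases,
    excluded_biotypes = excluded_biotypes,
    panel_restrict = isTRUE(panel_restrict),
    predictor_rule = predictor_rule,
    synonymous_splice_gate = isTRUE(synonymous_splice_gate)
  ), class = "cascade_config")
}

#' Recessive inheritance filter
#'
#' Under the autozygosity presumption the causal allele is homozygous in
#' every affected. A variant is retained when every exome-sequenced
#' affected member with a non-missing call is homozygous alternate and no
#' exome-sequenced unaffected member is.
#'
#' @param calls Tibble of calls for one variant (columns `sample_id`,
#'   `zygosity`).
#' @param affected_ids,unaffected_ids Sample ids of the sequenced affected
#'   / unaffected members.
#' @return List with `verdict` and `reason`.
#' @export
recessive_filter <- function(calls, affected_ids, unaffected_ids = character(0)) {
  if (!length(affected_ids)) {
    stop("no affected member sequenced: recessive filter undefined")
  }
  calls <- tibble::as_tibble(calls)
  aff <- calls[calls$sample_id %in% affected_ids &
                 calls$zygosity != "missing", , drop = FALSE]
  if (nrow(aff) == 0L) {
    return(list(verdict = "not_applicable", reason = "no affected call"))
  }
  if (any(aff$zygosity != "hom_alt")) {
    return(list(verdict = "eliminated",
                reason = "affected member not homozygous alternate"))
  }
  una <- calls[calls$sample_id %in% unaffected_ids &
                 calls$zygosity != "missing", , drop = FALSE]
  if (nrow(una) && any(una$zygosity == "hom_alt")) {
    return(list(verdict = "eliminated",
                reason = "unaffected member homozygous alternate"))
  }
  list(verdict = "retained", reason = "")
}

#' Population homozygote-frequency filter
#'
#' @param db_hom_freqs Named numeric vector: database -> homozygous
#'   genotype frequency (`NA` = present with unknown frequency; absent
#'   name = absent from that database).
#' @param config A [cascade_config()] object.
#' @return List with `verdict` and `reason`.
#' @export
frequency_filter <- function(db_hom_freqs, config = cascade_config()) {
  freqs <- db_hom_freqs[names(db_hom_freqs) %in% config$frequency_databases]
  freqs <- freqs[!is.na(freqs)]
  over <- freqs[freqs > config$max_hom_genotype_freq]
  if (length(over)) {
    return(list(verdict = "eliminated",
                reason = paste0("homozygote frequency ", fmt_num(over[[1L]]),
                                " in ", names(over)[1L])))
  }
  list(verdict = "retained", reason = "")
}

predictor_gate <- function(verdicts, rule) {
  # verdicts: character vector over {damaging, benign, absent}; absent
  # verdicts never count as benign
  n_ben <- sum(verdicts == "benign")
  n_dam <- sum(verdicts == "damaging")
  switch(rule,
    all_benign_drops = n_ben == length(verdicts),
    any_benign_drops = n_ben > 0L,
    majority = n_ben > n_dam
  )
}

#' Classify a variant's transcript region
#'
#' Assigns each variant a region class (`coding_*`, `intronic`, `utr5`,
#' `utr3`, `nontranscribed`) plus the auxiliary distances the cascade
#' needs: the splice distance for intronic variants (first intronic base =
#' distance 1) and the spliced distance upstream of the start codon for
#' 5'UTR variants. The annotation-designated transcript takes precedence;
#' among other overlapping transcripts the one most favorable to retention
#' is chosen so borderline variants survive to segregation rather than
#' being silently lost. Coding SNVs take their missense/nonsense/synonymous
#' subclass from the consequence annotation; indels are subclassified by
#' length difference when unannotated. A coding SNV with no consequence
#' annotation gets class `coding_unknown` (an absent state the region rule
#' eliminates).
#'
#' @param variants Variant tibble (chrom/pos/ref/alt plus annotation
#'   columns).
#' @param gene_models An `ird_gene_models` object.
#' @param config A [cascade_config()] object (used to rank transcripts by
#'   retention).
#' @return The variant tibble with `region_class`, `splice_distance`,
#'   `dist_upstream_of_start` and `transcript_used` recomputed.
#' @export
classify_region <- function(variants, gene_models, config = cascade_config()) {
  variants <- tibble::as_tibble(variants)
  tx_tab <- gene_models$transcripts
  exons_by_tx <- split(gene_models$exons, gene_models$exons$transcript)
  n <- nrow(variants)
  region <- character(n)
  spl <- rep(NA_integer_, n)
  utr5d <- rep(NA_integer_, n)
  tx_used <- rep(NA_character_, n)
  gene_used <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos1 <- variants$pos[i]
    cand <- tx_tab[tx_tab$chrom == variants$chrom[i] &
                     tx_tab$tx_start0 < pos1 & tx_tab$tx_end0 >= pos1, ,
                   drop = FALSE]
    if (nrow(cand) == 0L) {
      region[i] <- "nontranscribed"
      next
    }
    anno_tx <- variants$transcript[i]
    if (!is.na(anno_tx) && anno_tx %in% cand$transcript) {
      cand <- cand[cand$transcript == anno_tx, , drop = FALSE]
    }
    geoms <- lapply(seq_len(nrow(cand)), function(j)
      region_geometry(pos1, cand[j, ], exons_by_tx[[cand$transcript[j]]]))
    classes <- vapply(seq_along(geoms), function(j)
      resolve_coding_class(geoms[[j]]$region, variants[i, ]), character(1))
    verdicts <- vapply(seq_along(geoms), function(j)
      region_rule(classes[j], geoms[[j]]$splice_distance,
                  geoms[[j]]$dist_upstream_of_start,
                  variants[i, ], config)$verdict, character(1))
    ord <- order(verdicts != "retained", cand$transcript)
    pick <- ord[1L]
    region[i] <- classes[pick]
    spl[i] <- geoms[[pick]]$splice_distance
    utr5d[i] <- geoms[[pick]]$dist_upstream_of_start
    tx_used[i] <- cand$transcript[pick]
    gene_used[i] <- cand$gene[pick]
  }
  variants$region_class <- region
  variants$splice_distance <- spl
  variants$dist_upstream_of_start <- utr5d
  variants$transcript_used <- tx_used
  variants$gene <- ifelse(is.na(variants$gene), gene_used, variants$gene)
  variants
}

# map geometry-level region + annotation to the final region class
resolve_coding_class <- function(geom_region, var_row) {
  if (geom_region != "cds") return(geom_region)
  is_indel <- nchar(var_row$ref) != nchar(var_row$alt)
  eff <- var_row$coding_effect
  if (is_indel) {
    if (!is.na(eff) && eff == "inframe") return("coding_indel_inframe")
    if (!is.na(eff) && eff == "frameshift") return("coding_indel_frameshift")
    diff <- abs(nchar(var_row$ref) - nchar(var_row$alt))
    return(if (diff %% 3L == 0L) "coding_indel_inframe" else "coding_indel_frameshift")
  }
  if (is.na(eff)) return("coding_unknown")
  switch(eff,
         missense = "coding_missense",
         nonsense = "coding_nonsense",
         synonymous = "coding_synonymous",
         frameshift = "coding_indel_frameshift",
         inframe = "coding_indel_inframe",
         "coding_unknown")
}

# the region-dispatch rule: exactly one branch applies per class
region_rule <- function(region_class, splice_distance, utr5_dist, var_row,
                        config) {
  verdicts <- c(mutation_taster = var_row$mutation_taster,
                polyphen = var_row$polyphen,
                provean = var_row$provean,
                sift = var_row$sift)
  switch(region_class,
    nontranscribed = list(verdict = "eliminated",
                          reason = "outside any transcribed region"),
    noncoding_exonic = list(verdict = "eliminated",
                            reason = "exonic in a transcript without CDS"),
    utr5 = if (!is.na(utr5_dist) && utr5_dist <= config$utr5_window) {
      list(verdict = "retained", reason = "")
    } else {
      list(verdict = "eliminated",
           reason = paste0("5'UTR more than ", config$utr5_window,
                           " bases upstream of the start codon"))
    },
    utr3 = if (isTRUE(var_row$mirna_target)) {
      list(verdict = "retained", reason = "")
    } else {
      list(verdict = "eliminated", reason = "3'UTR outside miRNA-targeted region")
    },
    coding_missense = if (predictor_gate(verdicts, config$predictor_rule)) {
      list(verdict = "eliminated",
           reason = "missense predicted benign by predictor consensus")
    } else {
      list(verdict = "retained", reason = "")
    },
    coding_nonsense = list(verdict = "retained", reason = ""),
    coding_indel_frameshift = list(verdict = "retained", reason = ""),
    coding_indel_inframe = list(verdict = "retained", reason = ""),
    coding_synonymous = if (!config$synonymous_splice_gate ||
                              isTRUE(var_row$splice_altering)) {
      list(verdict = "retained", reason = "")
    } else {
      list(verdict = "eliminated",
           reason = "synonymous, not predicted to alter splicing")
    },
    coding_unknown = list(verdict = "eliminated",
                          reason = "coding SNV without consequence annotation"),
    intronic = if (is.na(splice_distance) ||
                     splice_distance >= config$splice_far_cutoff) {
      list(verdict = "eliminated",
           reason = paste0("intronic, ", config$splice_far_cutoff,
                           " or more bases from the nearest splice site"))
    } else if (isTRUE(var_row$splice_altering)) {
      list(verdict = "retained", reason = "")
    } else {
      list(verdict = "eliminated",
           reason = "near-splice intronic, not predicted to alter splicing")
    },
    stop("unclassified region: ", region_class)
  )
}

biotype_rule <- function(var_row, config) {
  bt <- var_row$biotype
  if (!is.na(bt) && bt %in% config$excluded_biotypes) {
    return(list(verdict = "eliminated", reason = paste0("biotype ", bt)))
  }
  if (isFALSE(var_row$complete_5p) || isFALSE(var_row$complete_3p)) {
    return(list(verdict = "eliminated", reason = "5'/3'-incomplete transcript"))
  }
  list(verdict = "retained", reason = "")
}

#' Apply the full filter cascade to one variant
#'
#' Runs the fixed stage order (site QC, recessive filter, homozygote
#' frequency, region dispatch, biotype) and records every stage verdict in
#' a FilterTrace. Stages are all evaluated (no short-circuit) so the trace
#' is complete; the variant is a candidate iff no stage eliminated it.
#'
#' @param variant One-row variant tibble with annotation and region columns
#'   (run [classify_region()] first, or supply `region_class` directly).
#' @param calls Genotype calls for this variant (all genotyped members).
#' @param pedigree The `ird_pedigree` the calls belong to.
#' @param config A [cascade_config()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `trace` (tibble: variant_key, stage, verdict, reason)
#'   and `final` (`"candidate"` or `"eliminated"`).
#' @export
apply_cascade <- function(variant, calls, pedigree,
                          config = cascade_config(),
                          thresholds = qc_thresholds()) {
  stopifnot(nrow(variant) == 1L)
  seq_aff <- ped_ids(pedigree, affection = "affected", sequenced = TRUE)
  seq_una <- ped_ids(pedigree, affection = "unaffected", sequenced = TRUE)
  seq_calls <- calls[calls$sample_id %in% c(seq_aff, seq_una), , drop = FALSE]
  qc <- passes_site_qc(seq_calls, thresholds)
  rec <- recessive_filter(seq_calls, seq_aff, seq_una)
  freq <- frequency_filter(variant$db_hom_freqs[[1L]], config)
  reg <- region_rule(variant$region_class, variant$splice_distance,
                     variant$dist_upstream_of_start, variant, config)
  bio <- biotype_rule(variant, config)
  stage_list <- list(qc = qc, recessive = rec, frequency = freq,
                     region = reg, biotype = bio)
  trace <- tibble::tibble(
    variant_key = variant$variant_key,
    stage = CASCADE_STAGES,
    verdict = unname(vapply(stage_list[CASCADE_STAGES], `[[`, "", "verdict")),
    reason = unname(vapply(stage_list[CASCADE_STAGES], `[[`, "", "reason"))
  )
  # a not_applicable QC verdict (all calls missing) excludes the variant
  excluded <- any(trace$verdict == "eliminated") ||
    trace$verdict[trace$stage == "qc"] == "not_applicable" ||
    trace$verdict[trace$stage == "recessive"] == "not_applicable"
  list(trace = trace, final = if (excluded) "eliminated" else "candidate")
}

#' Run the cascade over a whole cohort
#'
#' @param cohort An `ird_cohort`.
#' @param gene_models An `ird_gene_models` object (region classification).
#' @param config,thresholds Cascade and QC settings.
#' @param membership Optional membership tables ([read_membership_tables()])
#'   merged into the variants' frequency maps before filtering.
#' @return List with `variants` (augmented with `final` and
#'   `first_failing_stage`), `traces` (long tibble over all variants and
#'   stages).
#' @export
cascade_trace <- function(cohort, gene_models,
                          config = cascade_config(),
                          thresholds = qc_thresholds(),
                          membership = NULL) {
  variants <- merge_membership(cohort$variants, membership)
  variants <- classify_region(variants, gene_models, config)
  # transcript attributes from the gene models win over VCF INFO copies
  tx_tab <- gene_models$transcripts
  hit <- match(variants$transcript_used, tx_tab$transcript)
  variants$biotype <- ifelse(!is.na(hit), tx_tab$biotype[hit], variants$biotype)
  variants$complete_5p <- ifelse(!is.na(hit), tx_tab$complete_5p[hit],
                                 variants$complete_5p)
  variants$complete_3p <- ifelse(!is.na(hit), tx_tab$complete_3p[hit],
                                 variants$complete_3p)
  gt_by_key <- split(cohort$genotypes, cohort$genotypes$variant_key)
  res <- lapply(seq_len(nrow(variants)), function(i) {
    apply_cascade(variants[i, ], gt_by_key[[variants$variant_key[i]]],
                  cohort$pedigree, config, thresholds)
  })
  traces <- dplyr::bind_rows(lapply(res, `[[`, "trace"))
  variants$final <- vapply(res, `[[`, "", "final")
  variants$first_failing_stage <- vapply(res, function(r) {
    bad <- r$trace$stage[r$trace$verdict %in% c("eliminated", "not_applicable")]
    if (length(bad)) bad[1L] else NA_character_
  }, character(1))
  list(variants = variants, traces = traces)
}

#' Restrict cascade survivors to the known-gene panel
#'
#' @param variants Variant tibble as returned by [cascade_trace()] (with a
#'   `final` column).
#' @param panel Character vector of panel gene symbols.
#' @param config A [cascade_config()] object; with `panel_restrict = FALSE`
#'   the candidate set equals the survivor set.
#' @return List with `candidates` and `off_panel` tibbles.
#' @export
restrict_to_panel <- function(variants, panel, config = cascade_config()) {
  survivors <- variants[variants$final == "candidate", , drop = FALSE]
  if (!config$panel_restrict) {
    return(list(candidates = survivors,
                off_panel = survivors[0, , drop = FALSE]))
  }
  if (!length(panel)) {
    stop("panel restriction requested but the gene panel is empty")
  }
  on_panel <- !is.na(survivors$gene) & toupper(survivors$gene) %in% toupper(panel)
  list(candidates = survivors[on_panel, , drop = FALSE],
       off_panel = survivors[!on_panel, , drop = FALSE])
}
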