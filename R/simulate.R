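# Seeded synthetic-cohort generator: consanguineous pedigrees, Mendelian
# gene-dropping with autozygous planted causal variants, decoy variants
# spanning every filter class, annotation/database/control tables, and a
# truth manifest. Everything is reproducible from the master seed; one RNG
# stream per pedigree is derived from (master seed, pedigree index).

#' Synthetic cohort configuration
#'
#' Defaults mirror the structure of the study cohort the pipeline was
#' designed for: 26 pedigrees with 1-6 consanguineous marriages each,
#' 3-12 affected members, 5-16 genotyped participants, and one causal
#' variant recurring in 5 pedigrees.
#'
#' @param n_pedigrees Number of pedigrees (default 26).
#' @param loops_range Inclusive range of consanguineous marriages per
#'   pedigree (default 1-6).
#' @param affected_range Inclusive range of affected members (default 3-12).
#' @param genotyped_range Inclusive range of genotyped participants
#'   (default 5-16; capped at the pedigree size).
#' @param n_decoys_per_class Decoy variants per filter class (default 20).
#' @param predictor_noise Probability that a damaging-truth missense
#'   variant receives a benign verdict, independently per predictor tool
#'   (default 0.1).
#' @param causal_recurrence Number of pedigrees sharing one recurrent
#'   causal variant (default 5).
#' @param causal_classes Consequence classes cycled over the remaining
#'   pedigrees' causal variants.
#' @param mean_depth Mean sequencing depth for exome calls; depth is drawn
#'   as 11 + a negative binomial, so defaults always clear the depth
#'   threshold (default 63).
#' @param seed Master seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_pedigrees = 26L,
                              loops_range = c(1L, 6L),
                              affected_range = c(3L, 12L),
                              genotyped_range = c(5L, 16L),
                              n_decoys_per_class = 20L,
                              predictor_noise = 0.1,
                              causal_recurrence = 5L,
                              causal_classes = c("missense", "missense",
                                                 "missense", "nonsense",
                                                 "frameshift"),
                              mean_depth = 63,
                              seed = 1L) {
  in_range <- function(r, lo, hi) length(r) == 2L && r[1L] <= r[2L] &&
    r[1L] >= lo && r[2L] <= hi
  if (!in_range(loops_range, 1L, 6L)) {
    stop("loops_range must lie within 1-6")
  }
  if (!in_range(affected_range, 1L, 12L)) {
    stop("affected_range must lie within 1-12")
  }
  if (!in_range(genotyped_range, 2L, 16L)) {
    stop("genotyped_range must lie within 2-16")
  }
  stopifnot(predictor_noise >= 0, predictor_noise <= 1,
            n_pedigrees >= 1L, n_decoys_per_class >= 1L,
            causal_recurrence >= 0L, causal_recurrence <= n_pedigrees,
            all(causal_classes %in% c("missense", "nonsense", "frameshift")))
  structure(list(
    n_pedigrees = as.integer(n_pedigrees),
    loops_range = as.integer(loops_range),
    affected_range = as.integer(affected_range),
    genotyped_range = as.integer(genotyped_range),
    n_decoys_per_class = as.integer(n_decoys_per_class),
    predictor_noise = predictor_noise,
    causal_recurrence = as.integer(causal_recurrence),
    causal_classes = causal_classes,
    mean_depth = mean_depth,
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

DECOY_CLASSES <- c(
  "qc_fail", "recessive_het", "high_frequency", "nontranscribed",
  "utr5_far", "utr3_no_mirna", "missense_all_benign", "deep_intronic",
  "splice_near_non_altering", "nmd_biotype", "non_segregating",
  "off_panel", "control_homozygous"
)

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

pedigree_stream_seed <- function(master, index, salt = 0L) {
  as.integer((as.double(master) * 1000003 + index * 7919 + salt * 104729) %%
               2147483629)
}

#' Toy gene models for simulation and fixtures
#'
#' A small fictitious genomic scaffold: 20 genes on three chromosomes,
#' three 300-bp exons each separated by 400-bp introns, UTRs at the
#' transcript ends, roughly half on the minus strand. Includes one
#' transcript with a "nonsense mediated decay" biotype and one
#' 3'-incomplete transcript so the biotype rule is exercised. The pipeline
#' is coordinate-agnostic; real genome coordinates are deliberately not
#' used.
#'
#' @return An `ird_gene_models` object.
#' @export
toy_gene_models <- function() {
  genes <- tibble::tibble(
    gene = c("RPE65", "LCA5", "USH2A", "CNGB1", "FAM161A", "CERKL",
             "GUCY2D", "BEST1", "CEP164", "ALMS1", "RAX2", "ABHD12",
             "CDH23", "JAG1", "COL11A1", "PRPH2", "NRL", "ACTB", "MYH7",
             "TTN"),
    biotype = c(rep("protein coding", 15), "nonsense mediated decay",
                "protein coding", rep("protein coding", 3)),
    complete_5p = TRUE,
    complete_3p = c(rep(TRUE, 16), FALSE, rep(TRUE, 3))
  )
  n <- nrow(genes)
  genes$chrom <- as.character(rep(1:3, length.out = n))
  genes$strand <- rep(c("+", "-"), length.out = n)
  genes$idx_on_chrom <- stats::ave(seq_len(n), genes$chrom, FUN = seq_along)
  genes$tx_start0 <- 10000L + (genes$idx_on_chrom - 1L) * 5000L
  exon_len <- 300L
  intron_len <- 400L
  tx_len <- 3L * exon_len + 2L * intron_len
  genes$tx_end0 <- genes$tx_start0 + tx_len
  utr5_len <- 100L
  utr3_len <- 150L
  e1s <- genes$tx_start0
  e3s <- genes$tx_start0 + 2L * (exon_len + intron_len)
  genes$cds_start0 <- ifelse(genes$strand == "+", e1s + utr5_len,
                             e1s + utr3_len)
  genes$cds_end0 <- ifelse(genes$strand == "+", e3s + exon_len - utr3_len,
                           e3s + exon_len - utr5_len)
  genes$transcript <- paste0(genes$gene, "-201")
  exons <- tibble::tibble(
    transcript = rep(genes$transcript, each = 3L),
    start0 = as.integer(rep(genes$tx_start0, each = 3L) +
                          rep(0:2, n) * (exon_len + intron_len)),
    end0 = as.integer(rep(genes$tx_start0, each = 3L) +
                        rep(0:2, n) * (exon_len + intron_len) + exon_len)
  )
  tx <- genes[, c("transcript", "gene", "chrom", "strand", "tx_start0",
                  "tx_end0", "cds_start0", "cds_end0", "biotype",
                  "complete_5p", "complete_3p")]
  new_gene_models(tx, exons)
}

#' The bundled known-IRD gene panel used by the simulator and fixtures
#' @return Character vector of panel gene symbols.
#' @export
toy_gene_panel <- function() {
  sort(c("RPE65", "LCA5", "USH2A", "CNGB1", "FAM161A", "CERKL", "GUCY2D",
         "BEST1", "CEP164", "ALMS1", "RAX2", "ABHD12", "CDH23", "JAG1",
         "COL11A1", "PRPH2", "NRL"))
}

# deterministic alleles from position
ref_at <- function(pos) c("A", "C", "G", "T")[pos %% 4L + 1L]
alt_at <- function(pos) c("A", "C", "G", "T")[(pos %% 4L + 1L) %% 4L + 1L]

# geometry lookup for one gene in the toy models
gene_geom <- function(models, gene) {
  tx <- models$transcripts[models$transcripts$gene == gene, ]
  ex <- models$exons[models$exons$transcript == tx$transcript, ]
  ex <- ex[order(ex$start0), ]
  list(tx = tx, exons = ex,
       e1s = ex$start0[1L], e1e = ex$end0[1L],
       e2s = ex$start0[2L], e2e = ex$end0[2L],
       e3s = ex$start0[3L], e3e = ex$end0[3L])
}

#' Simulate one consanguineous pedigree
#'
#' Builds a four-generation pedigree with the configured number of
#' first-cousin marriage loops: an ancestral founder couple, their
#' children married to unrelated spouses, grandchild first-cousin couples
#' (the loops), and the loop couples' children, among whom all affected
#' members arise. Structure is reproducible given the seed.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Integer seed for this pedigree's stream.
#' @param pedigree_id Identifier for the emitted pedigree.
#' @return An `ird_pedigree` carrying a `sim` attribute with the loop
#'   structure used by [drop_genotypes()].
#' @export
simulate_pedigree <- function(config, seed, pedigree_id = "SIM001") {
  set.seed(seed)
  L <- sample_range(config$loops_range)
  A <- sample_range(config$affected_range)
  G <- sample_range(config$genotyped_range)
  n_sib <- L + 1L
  rows <- list()
  add <- function(id, father, mother, sex, affection) {
    rows[[length(rows) + 1L]] <<- list(individual_id = id, father_id = father,
                                       mother_id = mother, sex = sex,
                                       affection = affection)
  }
  add("I-1", "0", "0", "male", "unaffected")
  add("I-2", "0", "0", "female", "unaffected")
  sib_sex <- rep(c("male", "female"), length.out = n_sib)
  for (j in seq_len(n_sib)) {
    add(paste0("II-", j), "I-1", "I-2", sib_sex[j], "unaffected")
    add(paste0("II-S", j), "0", "0",
        if (sib_sex[j] == "male") "female" else "male", "unknown")
  }
  chain_edges <- tibble::tibble(child = paste0("II-", seq_len(n_sib)),
                                parent = "I-1")
  for (j in seq_len(n_sib)) {
    fa <- if (sib_sex[j] == "male") paste0("II-", j) else paste0("II-S", j)
    mo <- if (sib_sex[j] == "male") paste0("II-S", j) else paste0("II-", j)
    add(paste0("III-", 2L * j - 1L), fa, mo, "male", "unaffected")
    add(paste0("III-", 2L * j), fa, mo, "female", "unaffected")
  }
  loop_couples <- tibble::tibble(
    father = paste0("III-", 2L * seq_len(L) - 1L),
    mother = paste0("III-", 2L * (seq_len(L) + 1L))
  )
  chain_edges <- dplyr::bind_rows(
    chain_edges,
    tibble::tibble(child = loop_couples$father,
                   parent = paste0("II-", seq_len(L))),
    tibble::tibble(child = loop_couples$mother,
                   parent = paste0("II-", seq_len(L) + 1L))
  )
  # the mother-side chain child is III-(2j); its carrier parent is II-j,
  # which may be the father or the mother of that child depending on sex
  n_children <- A + max(L, 2L)
  couple_of <- rep(seq_len(L), length.out = n_children)
  gen4 <- paste0("IV-", seq_len(n_children))
  for (t in seq_len(n_children)) {
    cp <- couple_of[t]
    add(gen4[t], loop_couples$father[cp], loop_couples$mother[cp],
        rep(c("male", "female"), length.out = n_children)[t],
        if (t <= A) "affected" else "unaffected")
  }
  members <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  affected <- gen4[seq_len(A)]
  unaffected_gen4 <- setdiff(gen4, affected)
  seq_n <- min(sample(1:3, 1L), A)
  sequenced <- sample(affected, seq_n)
  if (length(unaffected_gen4) && stats::runif(1) < 0.25) {
    sequenced <- c(sequenced, sample(unaffected_gen4, 1L))
  }
  priority <- unique(c(sequenced, affected,
                       unique(c(loop_couples$father, loop_couples$mother)),
                       unaffected_gen4, paste0("II-", seq_len(n_sib)),
                       c("I-1", "I-2")))
  genotyped <- priority[seq_len(min(G, length(priority)))]
  genotyped <- unique(c(genotyped, sequenced))
  members$genotyped <- members$individual_id %in% genotyped
  members$sequenced <- members$individual_id %in% sequenced
  ped <- pedigree(pedigree_id, members, loops = L)
  attr(ped, "sim") <- list(
    top_founder = "I-1",
    chain_edges = chain_edges,
    loop_couples = loop_couples,
    gen4 = gen4,
    affected = affected,
    unaffected_gen4 = unaffected_gen4
  )
  ped
}

# pick the non-segregating "victim": preferably a genotyped non-sequenced
# affected member (forced het), else a genotyped non-sequenced unaffected
# loop child (forced hom_alt); NULL if neither exists.
pick_victim <- function(ped) {
  sim <- attr(ped, "sim")
  m <- ped$members
  cand_aff <- m$individual_id[m$affection == "affected" & m$genotyped &
                                !m$sequenced]
  if (length(cand_aff)) {
    return(list(id = cand_aff[1L], mode = "het"))
  }
  cand_una <- intersect(sim$unaffected_gen4,
                        m$individual_id[m$genotyped & !m$sequenced])
  if (length(cand_una)) {
    return(list(id = cand_una[1L], mode = "hom"))
  }
  NULL
}

#' Gene-drop genotypes through a simulated pedigree
#'
#' Performs Mendelian gene-dropping of each site's alternate allele from
#' the ancestral founder through the pedigree: every child allele is drawn
#' from its parent's two alleles, with transmissions along the
#' founder-to-loop-couple paths constrained so that planted sites reach
#' their configured genotype pattern (all affected homozygous alternate
#' for causal-style sites, heterozygous affected for recessive-filter
#' decoys, one discordant member for non-segregating decoys). Unaffected
#' loop children are rejection-sampled away from homozygosity. Per-call
#' depth and mapping quality are drawn for genotyped members; QC-failure
#' decoys get one broken sequenced call.
#'
#' @param ped A pedigree from [simulate_pedigree()].
#' @param sites Tibble with columns `variant_key`, `constraint` (one of
#'   `"hom_affected"`, `"het_affected"`, `"non_segregating"`), `qc_mode`
#'   (`NA`, `"depth"`, `"mq"`, `"sb"`).
#' @param seed Integer seed.
#' @param mean_depth Mean exome depth (see [cohort_sim_config()]).
#' @return Genotype tibble for the genotyped members (long form).
#' @export
drop_genotypes <- function(ped, sites, seed, mean_depth = 63) {
  set.seed(seed)
  sim <- attr(ped, "sim")
  if (is.null(sim)) stop("pedigree lacks simulation structure (use simulate_pedigree)")
  m <- ped$members
  ids <- m$individual_id
  idx <- stats::setNames(seq_along(ids), ids)
  founder <- m$father_id == FOUNDER_MARKER
  victim <- pick_victim(ped)
  geno_rows <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    constraint <- sites$constraint[s]
    force_alt <- stats::setNames(vector("list", length(ids)), ids)
    force_ref <- stats::setNames(vector("list", length(ids)), ids)
    note_force <- function(store, child, parent) {
      store[[child]] <- c(store[[child]], parent)
      store
    }
    for (e in seq_len(nrow(sim$chain_edges))) {
      force_alt <- note_force(force_alt, sim$chain_edges$child[e],
                              sim$chain_edges$parent[e])
    }
    not_hom <- character(0)
    if (constraint == "hom_affected") {
      for (a in sim$affected) {
        force_alt <- note_force(force_alt, a, m$father_id[idx[a]])
        force_alt <- note_force(force_alt, a, m$mother_id[idx[a]])
      }
      not_hom <- sim$unaffected_gen4
    } else if (constraint == "het_affected") {
      for (a in sim$affected) {
        force_alt <- note_force(force_alt, a, m$father_id[idx[a]])
        force_ref <- note_force(force_ref, a, m$mother_id[idx[a]])
      }
      not_hom <- sim$unaffected_gen4
    } else if (constraint == "non_segregating") {
      for (a in sim$affected) {
        force_alt <- note_force(force_alt, a, m$father_id[idx[a]])
        force_alt <- note_force(force_alt, a, m$mother_id[idx[a]])
      }
      not_hom <- sim$unaffected_gen4
      if (!is.null(victim)) {
        v <- victim$id
        force_alt[[v]] <- NULL
        force_ref[[v]] <- NULL
        if (victim$mode == "het") {
          force_alt <- note_force(force_alt, v, m$father_id[idx[v]])
          force_ref <- note_force(force_ref, v, m$mother_id[idx[v]])
        } else {
          force_alt <- note_force(force_alt, v, m$father_id[idx[v]])
          force_alt <- note_force(force_alt, v, m$mother_id[idx[v]])
          not_hom <- setdiff(not_hom, v)
        }
      }
    } else {
      stop("unknown genotype constraint: ", constraint)
    }
    a1 <- integer(length(ids)) # allele from father
    a2 <- integer(length(ids)) # allele from mother
    a1[founder] <- 0L
    a2[founder] <- 0L
    a1[idx[sim$top_founder]] <- 1L
    draw_from <- function(parent, child) {
      alleles <- c(a1[idx[parent]], a2[idx[parent]])
      if (parent %in% force_alt[[child]]) {
        if (!any(alleles == 1L)) stop("forced transmission from non-carrier")
        return(1L)
      }
      if (parent %in% force_ref[[child]]) {
        if (!any(alleles == 0L)) stop("forced ref transmission impossible")
        return(0L)
      }
      alleles[sample.int(2L, 1L)]
    }
    for (i in seq_along(ids)) {
      if (founder[i]) next
      child <- ids[i]
      a1[i] <- draw_from(m$father_id[i], child)
      a2[i] <- draw_from(m$mother_id[i], child)
      if (child %in% not_hom) {
        tries <- 0L
        while (a1[i] + a2[i] == 2L && tries < 100L) {
          a1[i] <- draw_from(m$father_id[i], child)
          a2[i] <- draw_from(m$mother_id[i], child)
          tries <- tries + 1L
        }
        if (a1[i] + a2[i] == 2L) {
          stop("rejection budget exhausted while conditioning ", child)
        }
      }
    }
    keep <- m$genotyped
    gt <- paste0(a1[keep], "/", a2[keep])
    n_keep <- sum(keep)
    depth <- 11L + stats::rnbinom(n_keep, size = 12,
                                  mu = max(mean_depth - 11, 1))
    mq <- 40 + round(stats::runif(n_keep, 0, 20), 1)
    sb <- rep(FALSE, n_keep)
    qc_mode <- sites$qc_mode[s]
    if (!is.na(qc_mode)) {
      seq_pos <- which(m$sequenced[keep])
      tgt <- seq_pos[1L]
      if (qc_mode == "depth") depth[tgt] <- sample(0:10, 1L)
      if (qc_mode == "mq") mq[tgt] <- sample(0:30, 1L)
      if (qc_mode == "sb") sb[tgt] <- TRUE
    }
    geno_rows[[s]] <- tibble::tibble(
      variant_key = sites$variant_key[s],
      sample_id = ids[keep],
      gt = gt,
      zygosity = classify_genotype(gt),
      depth = as.integer(depth),
      mapping_quality = mq,
      strand_bias = sb
    )
  }
  dplyr::bind_rows(geno_rows)
}

# cohort-wide variant catalog: decoys for every filter class plus the
# causal variant of each pedigree; annotations (including sampled
# predictor verdicts) are cohort-level so shared variants are identical
# across pedigrees.
build_variant_catalog <- function(config, models, seed) {
  set.seed(seed)
  panel <- toy_gene_panel()
  cds_genes <- c("LCA5", "USH2A", "CNGB1", "FAM161A", "CERKL", "GUCY2D",
                 "BEST1", "CEP164", "ALMS1", "RAX2", "ABHD12", "CDH23")
  off_genes <- c("ACTB", "MYH7", "TTN")
  nd <- config$n_decoys_per_class
  p_noise <- config$predictor_noise

  sample_verdicts <- function(truth) {
    # truth: "damaging" or "benign"; noise flips damaging-truth to benign
    if (truth == "benign") {
      return(stats::setNames(rep("benign", 4L), PREDICTOR_COLS))
    }
    flips <- stats::runif(4L) < p_noise
    stats::setNames(ifelse(flips, "benign", "damaging"), PREDICTOR_COLS)
  }

  base_row <- function(gene, pos, ref, alt, class) {
    g <- if (is.na(gene)) NULL else gene_geom(models, gene)
    tibble::tibble(
      chrom = if (is.na(gene)) "1" else g$tx$chrom,
      pos = as.integer(pos), ref = ref, alt = alt,
      gene = gene,
      transcript = if (is.na(gene)) NA_character_ else g$tx$transcript,
      class = class
    )
  }

  decoys <- list()
  cds_pos <- function(gene, band, i) {
    g <- gene_geom(models, gene)
    g$e2s + 1L + band + (i - 1L) %/% length(cds_genes) * 3L
  }
  mk_cds_decoy <- function(class, band, truth, genes = cds_genes) {
    lapply(seq_len(nd), function(i) {
      gene <- genes[(i - 1L) %% length(genes) + 1L]
      pos <- cds_pos(gene, band, i)
      row <- base_row(gene, pos, ref_at(pos), alt_at(pos), class)
      v <- sample_verdicts(truth)
      row[PREDICTOR_COLS] <- as.list(v)
      row$coding_effect <- "missense"
      row
    })
  }
  decoys$qc_fail <- mk_cds_decoy("qc_fail", 0L, "damaging")
  decoys$recessive_het <- mk_cds_decoy("recessive_het", 45L, "damaging")
  decoys$high_frequency <- mk_cds_decoy("high_frequency", 90L, "damaging")
  decoys$missense_all_benign <- mk_cds_decoy("missense_all_benign", 135L,
                                             "benign")
  decoys$non_segregating <- mk_cds_decoy("non_segregating", 180L, "damaging")
  decoys$control_homozygous <- mk_cds_decoy("control_homozygous", 225L,
                                            "damaging")
  decoys$nmd_biotype <- lapply(seq_len(nd), function(i) {
    g <- gene_geom(models, "PRPH2")
    pos <- g$e2s + 1L + (i - 1L) * 3L
    row <- base_row("PRPH2", pos, ref_at(pos), alt_at(pos), "nmd_biotype")
    row[PREDICTOR_COLS] <- as.list(sample_verdicts("damaging"))
    row$coding_effect <- "missense"
    row
  })
  decoys$off_panel <- lapply(seq_len(nd), function(i) {
    gene <- off_genes[(i - 1L) %% length(off_genes) + 1L]
    g <- gene_geom(models, gene)
    pos <- g$e2s + 1L + (i - 1L) %/% length(off_genes) * 3L
    row <- base_row(gene, pos, ref_at(pos), alt_at(pos), "off_panel")
    row[PREDICTOR_COLS] <- as.list(sample_verdicts("damaging"))
    row$coding_effect <- "missense"
    row
  })
  decoys$nontranscribed <- lapply(seq_len(nd), function(i) {
    gene <- cds_genes[(i - 1L) %% length(cds_genes) + 1L]
    g <- gene_geom(models, gene)
    pos <- g$tx$tx_end0 + 1000L + i * 7L
    base_row(NA_character_, pos, ref_at(pos), alt_at(pos), "nontranscribed") |>
      within_chrom(g$tx$chrom)
  })
  decoys$utr5_far <- lapply(seq_len(nd), function(i) {
    gene <- cds_genes[(i - 1L) %% length(cds_genes) + 1L]
    g <- gene_geom(models, gene)
    d <- 10L + (i - 1L) %/% length(cds_genes) * 5L # distance > 6 window
    pos <- if (g$tx$strand == "+") g$tx$cds_start0 + 1L - d
           else g$tx$cds_end0 + d
    row <- base_row(gene, pos, ref_at(pos), alt_at(pos), "utr5_far")
    row$dist_upstream_of_start <- d
    row
  })
  decoys$utr3_no_mirna <- lapply(seq_len(nd), function(i) {
    gene <- cds_genes[(i - 1L) %% length(cds_genes) + 1L]
    g <- gene_geom(models, gene)
    k <- 10L + (i - 1L) %/% length(cds_genes) * 5L
    pos <- if (g$tx$strand == "+") g$tx$cds_end0 + k else g$tx$cds_start0 + 1L - k
    row <- base_row(gene, pos, ref_at(pos), alt_at(pos), "utr3_no_mirna")
    row$mirna_target <- FALSE
    row
  })
  decoys$deep_intronic <- lapply(seq_len(nd), function(i) {
    gene <- cds_genes[(i - 1L) %% length(cds_genes) + 1L]
    g <- gene_geom(models, gene)
    d <- 15L + (i - 1L) %/% length(cds_genes) * 9L
    pos <- g$e1e + d
    row <- base_row(gene, pos, ref_at(pos), alt_at(pos), "deep_intronic")
    row$splice_distance <- d
    row$splice_altering <- TRUE # distance rule dominates the NNSplice call
    row
  })
  decoys$splice_near_non_altering <- lapply(seq_len(nd), function(i) {
    gene <- cds_genes[(i - 1L) %% length(cds_genes) + 1L]
    g <- gene_geom(models, gene)
    d <- 3L + (i - 1L) %/% length(cds_genes) * 4L
    pos <- g$e2e + d # intron 2, left edge
    row <- base_row(gene, pos, ref_at(pos), alt_at(pos),
                    "splice_near_non_altering")
    row$splice_distance <- d
    row$splice_altering <- FALSE
    row
  })
  decoy_tbl <- dplyr::bind_rows(unlist(decoys, recursive = FALSE))
  decoy_tbl <- fill_annotation_defaults(decoy_tbl, models)

  # database frequencies and control counts per class
  decoy_tbl$db_hom_freqs <- lapply(seq_len(nrow(decoy_tbl)), function(i) {
    cls <- decoy_tbl$class[i]
    if (cls == "high_frequency") {
      c(HapMap = 0.01 + (i %% 5L) * 0.005, `1000Genomes` = 0.01)
    } else if (cls == "missense_all_benign") {
      c(ESP6500 = 0.004) # common enough to be listed, under the 0.5% bar
    } else if (cls == "utr3_no_mirna") {
      c(dbSNP = NA_real_) # presence-only listing
    } else {
      stats::setNames(numeric(0), character(0))
    }
  })
  decoy_tbl$control_n_hom <- ifelse(decoy_tbl$class == "control_homozygous",
                                    1L + seq_len(nrow(decoy_tbl)) %% 2L, 0L)
  decoy_tbl$control_n_het <- seq_len(nrow(decoy_tbl)) %% 3L
  decoy_tbl$variant_key <- variant_key(decoy_tbl$chrom, decoy_tbl$pos,
                                       decoy_tbl$ref, decoy_tbl$alt)

  # causal variants: one recurrent missense shared by the first
  # causal_recurrence pedigrees, unique causal variants elsewhere
  causal_genes <- setdiff(cds_genes, character(0))
  rec_g <- gene_geom(models, "RPE65")
  rec_pos <- rec_g$e2s + 281L
  causal <- vector("list", config$n_pedigrees)
  rec_verdicts <- sample_verdicts("damaging")
  for (p in seq_len(config$n_pedigrees)) {
    if (p <= config$causal_recurrence) {
      row <- base_row("RPE65", rec_pos, ref_at(rec_pos), alt_at(rec_pos),
                      "causal")
      row[PREDICTOR_COLS] <- as.list(rec_verdicts)
      row$coding_effect <- "missense"
      row$causal_class <- "missense"
    } else {
      k <- p - config$causal_recurrence
      gene <- causal_genes[(k - 1L) %% length(causal_genes) + 1L]
      cls <- config$causal_classes[(k - 1L) %% length(config$causal_classes) + 1L]
      g <- gene_geom(models, gene)
      pos <- g$e2s + 270L + (k - 1L) %/% length(causal_genes) * 2L
      if (cls == "frameshift") {
        ref <- paste0(ref_at(pos), ref_at(pos + 1L))
        alt <- ref_at(pos)
        row <- base_row(gene, pos, ref, alt, "causal")
        row$coding_effect <- "frameshift"
      } else {
        row <- base_row(gene, pos, ref_at(pos), alt_at(pos), "causal")
        row$coding_effect <- cls
        if (cls == "missense") {
          row[PREDICTOR_COLS] <- as.list(sample_verdicts("damaging"))
        }
      }
      row$causal_class <- cls
    }
    causal[[p]] <- row
  }
  causal_tbl <- dplyr::bind_rows(causal)
  causal_tbl <- fill_annotation_defaults(causal_tbl, models)
  causal_tbl$db_hom_freqs <- replicate(nrow(causal_tbl),
                                       stats::setNames(numeric(0), character(0)),
                                       simplify = FALSE)
  causal_tbl$control_n_hom <- 0L
  causal_tbl$control_n_het <- 0L
  causal_tbl$variant_key <- variant_key(causal_tbl$chrom, causal_tbl$pos,
                                        causal_tbl$ref, causal_tbl$alt)
  list(decoys = decoy_tbl, causal = causal_tbl)
}

within_chrom <- function(row, chrom) { row$chrom <- chrom; row }

# complete missing annotation columns with absent states and transcript
# attributes from the gene models
fill_annotation_defaults <- function(tbl, models) {
  blank <- blank_annotation(nrow(tbl))
  for (col in setdiff(names(blank), c(names(tbl), "db_hom_freqs"))) {
    tbl[[col]] <- blank[[col]]
  }
  for (col in PREDICTOR_COLS) {
    tbl[[col]][is.na(tbl[[col]])] <- "absent"
  }
  tx_tab <- models$transcripts
  hit <- match(tbl$transcript, tx_tab$transcript)
  tbl$biotype <- ifelse(!is.na(hit), tx_tab$biotype[hit], NA_character_)
  tbl$complete_5p <- ifelse(!is.na(hit), tx_tab$complete_5p[hit], NA)
  tbl$complete_3p <- ifelse(!is.na(hit), tx_tab$complete_3p[hit], NA)
  tbl
}

# expected first failing stage for a decoy given its (possibly
# noise-flipped) verdicts; generator-side bookkeeping for the manifest
expected_first_fail <- function(class, verdicts) {
  all_benign <- all(verdicts == "benign")
  switch(class,
    qc_fail = "qc",
    recessive_het = "recessive",
    high_frequency = "frequency",
    nontranscribed = , utr5_far = , utr3_no_mirna = ,
    missense_all_benign = , deep_intronic = ,
    splice_near_non_altering = "region",
    nmd_biotype = if (all_benign) "region" else "biotype",
    off_panel = if (all_benign) "region" else "panel",
    non_segregating = if (all_benign) "region" else "segregation",
    control_homozygous = if (all_benign) "region" else "control",
    stop("unknown decoy class ", class)
  )
}

site_constraint <- function(class) {
  switch(class,
    recessive_het = "het_affected",
    non_segregating = "non_segregating",
    "hom_affected"
  )
}

#' Generate a complete synthetic cohort on disk
#'
#' Emits, under `out_dir`: one VCF + PED per pedigree, the toy gene models
#' (GFF3), the gene panel, membership tables for HapMap / 1000Genomes /
#' ESP6500 / dbSNP, a control genotype table, and a truth manifest
#' (`manifest.json`) recording each pedigree's planted causal variant, the
#' expected candidate set, expected segregation outcomes, and each decoy's
#' expected first failing stage. Regeneration with the same config is
#' byte-identical.
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `manifest`, `cohorts` (in-memory
#'   `ird_cohort` list), `gene_models`, `panel`, file path vectors.
#' @export
generate_cohort <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  models <- toy_gene_models()
  panel <- toy_gene_panel()
  catalog <- build_variant_catalog(config, models,
                                   pedigree_stream_seed(config$seed, 0L))
  decoys <- catalog$decoys
  pedigree_ids <- sprintf("SIM%03d", seq_len(config$n_pedigrees))
  cohorts <- list()
  manifest_peds <- list()
  vcf_paths <- character(config$n_pedigrees)
  ped_paths <- character(config$n_pedigrees)
  decoy_sites <- tibble::tibble(
    variant_key = decoys$variant_key,
    constraint = vapply(decoys$class, site_constraint, character(1)),
    qc_mode = ifelse(decoys$class == "qc_fail",
                     c("depth", "mq", "sb")[seq_len(nrow(decoys)) %% 3L + 1L],
                     NA_character_)
  )
  for (p in seq_len(config$n_pedigrees)) {
    pid <- pedigree_ids[p]
    ped <- simulate_pedigree(config, pedigree_stream_seed(config$seed, p),
                             pedigree_id = pid)
    causal_row <- catalog$causal[p, ]
    sites <- dplyr::bind_rows(
      tibble::tibble(variant_key = causal_row$variant_key,
                     constraint = "hom_affected", qc_mode = NA_character_),
      decoy_sites
    )
    genotypes <- drop_genotypes(ped, sites,
                                pedigree_stream_seed(config$seed, p, 1L),
                                mean_depth = config$mean_depth)
    variants <- dplyr::bind_rows(causal_row, decoys)
    variants <- variants[, c("chrom", "pos", "ref", "alt", "variant_key",
                             ANNOTATION_COLS, "db_hom_freqs")]
    cohort <- cohort_input(ped, variants, genotypes)
    cohorts[[pid]] <- cohort
    vcf_paths[p] <- file.path(out_dir, paste0(pid, ".vcf"))
    ped_paths[p] <- file.path(out_dir, paste0(pid, ".ped"))
    write_cohort_vcf(cohort, vcf_paths[p])
    write_ped(ped, ped_paths[p])

    victim <- pick_victim(ped)
    dec_verdicts <- as.matrix(decoys[, PREDICTOR_COLS])
    first_fail <- vapply(seq_len(nrow(decoys)), function(i) {
      ff <- expected_first_fail(decoys$class[i], dec_verdicts[i, ])
      if (ff == "segregation" && is.null(victim)) ff <- "control" # no victim: it segregates; still novel-screens clean, so it confirms
      ff
    }, character(1))
    # decoys whose cascade survives (they fail only at/after segregation)
    surviving <- decoys$variant_key[first_fail %in% c("segregation", "control")]
    causal_lost <- causal_row$causal_class == "missense" &&
      all(unlist(causal_row[1, PREDICTOR_COLS]) == "benign")
    expected_candidates <- c(
      if (!causal_lost) causal_row$variant_key,
      surviving
    )
    seg_expect <- stats::setNames(
      !first_fail[match(surviving, decoys$variant_key)] %in% "segregation",
      surviving)
    if (!causal_lost) {
      seg_expect <- c(stats::setNames(TRUE, causal_row$variant_key), seg_expect)
    }
    manifest_peds[[pid]] <- list(
      causal_key = causal_row$variant_key,
      causal_gene = causal_row$gene,
      causal_class = causal_row$causal_class,
      causal_expected_candidate = !causal_lost,
      expected_candidates = sort(unname(expected_candidates)),
      expected_segregation = as.list(seg_expect[sort(names(seg_expect))]),
      decoy_first_fail = stats::setNames(as.list(first_fail),
                                         decoys$variant_key)
    )
  }
  write_gene_models(models, file.path(out_dir, "gene_models.gff3"))
  write_gene_panel(panel, file.path(out_dir, "panel.txt"))
  all_vars <- dplyr::bind_rows(decoys,
                               dplyr::distinct(catalog$causal, .data$variant_key,
                                               .keep_all = TRUE))
  db_names <- c("HapMap", "1000Genomes", "ESP6500", "dbSNP")
  membership_paths <- character(0)
  for (db in db_names) {
    listed <- vapply(all_vars$db_hom_freqs, function(f) db %in% names(f),
                     logical(1))
    tab <- tibble::tibble(
      variant_key = all_vars$variant_key[listed],
      hom_freq = vapply(all_vars$db_hom_freqs[listed], function(f) f[[db]],
                        numeric(1))
    )
    path <- file.path(out_dir, paste0("db_", db, ".tsv"))
    write_membership_table(tab, path, with_freq = db != "dbSNP")
    membership_paths[db] <- path
  }
  controls <- tibble::tibble(
    variant_key = all_vars$variant_key,
    n_controls = 96L,
    n_het = all_vars$control_n_het,
    n_hom = all_vars$control_n_hom
  )
  controls_path <- file.path(out_dir, "controls.tsv")
  write_controls(controls, controls_path)
  manifest <- list(
    seed = config$seed,
    n_pedigrees = config$n_pedigrees,
    predictor_noise = config$predictor_noise,
    causal_recurrence = config$causal_recurrence,
    n_decoys_per_class = config$n_decoys_per_class,
    decoy_classes = stats::setNames(as.list(decoys$class),
                                    decoys$variant_key),
    pedigrees = manifest_peds
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    dir = out_dir,
    manifest = manifest,
    cohorts = cohorts,
    gene_models = models,
    panel = panel,
    vcf_paths = stats::setNames(vcf_paths, pedigree_ids),
    ped_paths = stats::setNames(ped_paths, pedigree_ids),
    membership_paths = membership_paths,
    controls_path = controls_path
  ))
}
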