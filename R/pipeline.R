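# Orchestration: per-pedigree QC -> recessive -> cascade -> panel
# restriction -> segregation -> control screen, then cohort-level
# recurrence tabulation and the causal-variant summary.

#' Pipeline run configuration
#'
#' @param vcf,ped Parallel vectors of per-pedigree VCF and PED paths.
#' @param gene_models Path to gene models (GFF3/TSV) or an
#'   `ird_gene_models` object.
#' @param panel Path to the gene panel file or a character vector of
#'   symbols.
#' @param membership Named vector of membership-table paths (or the list
#'   returned by [read_membership_tables()]).
#' @param controls Path to the control genotype table or a tibble from
#'   [read_controls()].
#' @param thresholds A [qc_thresholds()] object.
#' @param cascade A [cascade_config()] object.
#' @param control_policy Control-screen policy, see [screen_controls()].
#' @param allow_nonpenetrant Unaffected homozygotes tolerated in
#'   segregation (default 0).
#' @param min_pedigrees Recurrence threshold of the population-unique
#'   catalog (default 5).
#' @param catalog_dbs Databases whose membership excludes a variant from
#'   the population-unique catalog (default: all of `membership`).
#' @param known_variants Character vector of previously reported causal
#'   variant keys (or a path, one key per line); everything else is novel.
#' @param causality Optional tibble (`pedigree_id`, `variant_key`,
#'   `uncertain`) designating causal assignments; variants flagged
#'   uncertain are reported but excluded from the causal count.
#' @param targeted Optional list of targeted single-variant screens for
#'   pedigrees without exome data: each element a list with `pedigree`
#'   (an `ird_pedigree`), `variant_key`, `gene`, and `calls` (tibble
#'   `sample_id`, `zygosity`).
#' @param out_dir Optional output directory for the report files.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, ped, gene_models, panel,
                       membership = NULL, controls = NULL,
                       thresholds = qc_thresholds(),
                       cascade = cascade_config(),
                       control_policy = "hom_refutes",
                       allow_nonpenetrant = 0L,
                       min_pedigrees = 5L,
                       catalog_dbs = NULL,
                       known_variants = character(0),
                       causality = NULL,
                       targeted = NULL,
                       out_dir = NULL) {
  stopifnot(length(vcf) == length(ped))
  for (path in c(vcf, ped)) {
    if (!file.exists(path)) stop("input path does not exist: ", path)
  }
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    panel <- read_gene_panel(panel)
  }
  if (is.character(membership)) {
    membership <- read_membership_tables(membership)
  }
  if (is.character(controls)) controls <- read_controls(controls)
  if (is.character(known_variants) && length(known_variants) == 1L &&
      file.exists(known_variants)) {
    known_variants <- readLines(known_variants)
    known_variants <- known_variants[nzchar(known_variants)]
  }
  if (is.null(catalog_dbs)) catalog_dbs <- names(membership)
  structure(list(
    vcf = vcf, ped = ped, gene_models = gene_models,
    panel = toupper(panel), membership = membership, controls = controls,
    thresholds = thresholds, cascade = cascade,
    control_policy = control_policy,
    allow_nonpenetrant = as.integer(allow_nonpenetrant),
    min_pedigrees = as.integer(min_pedigrees),
    catalog_dbs = catalog_dbs,
    known_variants = known_variants,
    causality = causality, targeted = targeted, out_dir = out_dir
  ), class = "run_config")
}

#' Run the full prioritization pipeline over a cohort
#'
#' Per pedigree: site QC, recessive filter, annotation cascade, panel
#' restriction, co-segregation verification of every candidate across the
#' genotyped members, and the control screen for novel segregating
#' candidates. Cohort level: recurrence tabulation of QC-passing SNVs, the
#' population-unique catalog, and the causal-variant summary. A pedigree
#' yielding zero candidates is a normal outcome, not an error.
#'
#' @param config A [run_config()] object.
#' @return An `ird_run` list: `report` (per-variant tibble),
#'   `candidate_results`, `traces`, `catalog`, `catalog_unique`, `summary`,
#'   `sidecar`. When `config$out_dir` is set the report, catalog and
#'   sidecar files are written there deterministically.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report_rows <- list()
  cand_rows <- list()
  trace_list <- list()
  carrier_rows <- list()
  controls <- config$controls
  for (i in seq_along(config$vcf)) {
    cohort <- tryCatch(
      read_cohort_vcf(config$vcf[i], config$ped[i]),
      error = function(e) stop("pedigree input ", basename(config$vcf[i]),
                               ": ", conditionMessage(e)))
    pid <- cohort$pedigree$pedigree_id
    ct <- cascade_trace(cohort, config$gene_models, config$cascade,
                        config$thresholds, config$membership)
    rp <- restrict_to_panel(ct$variants, config$panel, config$cascade)
    trace_list[[pid]] <- dplyr::mutate(ct$traces, pedigree_id = pid,
                                       .before = 1L)

    qc_pass <- ct$traces$variant_key[ct$traces$stage == "qc" &
                                       ct$traces$verdict == "retained"]
    carried <- cohort$genotypes |>
      dplyr::filter(.data$variant_key %in% qc_pass,
                    .data$zygosity %in% c("het", "hom_alt")) |>
      dplyr::distinct(.data$variant_key)
    if (nrow(carried)) {
      carrier_rows[[pid]] <- tibble::tibble(pedigree_id = pid,
                                            variant_key = carried$variant_key)
    }

    variants <- ct$variants
    gt_by_key <- split(cohort$genotypes, cohort$genotypes$variant_key)
    for (j in seq_len(nrow(variants))) {
      v <- variants[j, ]
      is_cand <- v$variant_key %in% rp$candidates$variant_key
      is_off <- v$variant_key %in% rp$off_panel$variant_key
      status <- if (is_cand) "candidate" else if (is_off) "off_panel" else "eliminated"
      seg <- NA
      n_inc <- NA_integer_
      ctrl_hom <- NA_integer_
      novel <- NA
      causal_lab <- NA_character_
      if (is_cand) {
        seg_res <- check_segregation(gt_by_key[[v$variant_key]],
                                     cohort$pedigree,
                                     config$allow_nonpenetrant)
        seg <- seg_res$segregates
        n_inc <- nrow(seg_res$inconsistent_members)
        novel <- !v$variant_key %in% config$known_variants
        control_ok <- TRUE
        if (novel && seg) {
          hit <- if (is.null(controls)) NA_integer_ else
            match(v$variant_key, controls$variant_key)
          if (!is.na(hit)) {
            scr <- screen_controls(controls$n_controls[hit],
                                   controls$n_het[hit], controls$n_hom[hit],
                                   policy = config$control_policy,
                                   variant_key = v$variant_key)
            ctrl_hom <- scr$n_hom_alt
            control_ok <- scr$novel_in_controls
          } else {
            ctrl_hom <- 0L # not observed in the screened controls
          }
        }
        confirmed <- isTRUE(seg) && control_ok
        causal_lab <- if (!seg) "refuted_by_segregation"
          else if (!control_ok) "refuted_by_controls" else "causal"
        cand_rows[[length(cand_rows) + 1L]] <- tibble::tibble(
          pedigree_id = pid, variant_key = v$variant_key, gene = v$gene,
          segregates = seg, novel = novel, control_ok = control_ok,
          confirmed = confirmed, targeted = FALSE)
      }
      report_rows[[length(report_rows) + 1L]] <- tibble::tibble(
        pedigree_id = pid, gene = v$gene, variant_key = v$variant_key,
        hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p, region_class = v$region_class,
        status = status, first_failing_stage = v$first_failing_stage,
        segregates = seg, n_inconsistent = n_inc, control_hom = ctrl_hom,
        novel = novel, causal = causal_lab)
    }
  }
  # targeted single-variant screens (pedigrees without exome data)
  for (tg in config$targeted %||% list()) {
    seg_res <- targeted_screen(tg$calls, tg$pedigree,
                               config$allow_nonpenetrant)
    pid <- tg$pedigree$pedigree_id
    novel <- !tg$variant_key %in% config$known_variants
    cand_rows[[length(cand_rows) + 1L]] <- tibble::tibble(
      pedigree_id = pid, variant_key = tg$variant_key, gene = tg$gene,
      segregates = seg_res$segregates, novel = novel, control_ok = TRUE,
      confirmed = seg_res$segregates, targeted = TRUE)
    report_rows[[length(report_rows) + 1L]] <- tibble::tibble(
      pedigree_id = pid, gene = tg$gene, variant_key = tg$variant_key,
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      region_class = NA_character_, status = "targeted",
      first_failing_stage = NA_character_,
      segregates = seg_res$segregates,
      n_inconsistent = nrow(seg_res$inconsistent_members),
      control_hom = NA_integer_, novel = novel,
      causal = if (seg_res$segregates) "causal" else "refuted_by_segregation")
  }
  report <- dplyr::bind_rows(report_rows)
  candidate_results <- dplyr::bind_rows(cand_rows)
  carriers <- dplyr::bind_rows(carrier_rows)
  catalog <- if (nrow(carriers)) tabulate_by_pedigree(carriers) else
    tibble::tibble(variant_key = character(0), chrom = character(0),
                   pos = integer(0), ref = character(0), alt = character(0),
                   pedigree_count = integer(0), pedigrees = character(0))
  catalog_membership <- config$membership[
    intersect(config$catalog_dbs, names(config$membership))]
  catalog_unique <- population_unique_catalog(catalog, catalog_membership,
                                              config$min_pedigrees)
  n_peds_total <- length(config$vcf) +
    length(unique(vapply(config$targeted %||% list(),
                         function(tg) tg$pedigree$pedigree_id, character(1))))
  summary <- summarize_causal_set(candidate_results, config$causality,
                                  config$known_variants,
                                  n_pedigrees = n_peds_total)
  sidecar <- list(
    settings = list(
      thresholds = unclass(config$thresholds),
      cascade = unclass(config$cascade),
      control_policy = config$control_policy,
      allow_nonpenetrant = config$allow_nonpenetrant,
      min_pedigrees = config$min_pedigrees,
      catalog_dbs = config$catalog_dbs
    ),
    summary = summary[c("n_pedigrees", "n_solved", "n_causal_variants",
                        "n_novel", "n_known", "max_recurrence_count",
                        "max_recurrence_key")]
  )
  res <- structure(list(
    report = report, candidate_results = candidate_results,
    traces = dplyr::bind_rows(trace_list), catalog = catalog,
    catalog_unique = catalog_unique, summary = summary, sidecar = sidecar
  ), class = "ird_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_report(report, sidecar,
                           file.path(config$out_dir, "report.tsv"))
    write_catalog(catalog, file.path(config$out_dir, "catalog.tsv"))
    write_catalog(catalog_unique,
                  file.path(config$out_dir, "catalog_population_unique.tsv"))
  }
  res
}

#' @export
print.ird_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<ird_run> %d pedigrees: %d solved; %d distinct causal variants",
           " (%d novel, %d known); max recurrence %s in %d pedigrees\n"),
    s$n_pedigrees, s$n_solved, s$n_causal_variants, s$n_novel, s$n_known,
    s$max_recurrence_key %||% "-", s$max_recurrence_count))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize the causal-variant set
#'
#' Counts distinct confirmed causal variants (segregating candidates that,
#' when novel, also pass the control screen), their novel/known split, and
#' the per-variant recurrence across pedigrees. Variants flagged uncertain
#' by the causality assignment (e.g. a second co-segregating candidate
#' whose contribution is unresolved) stay in the report but are excluded
#' from the causal count and from "solved" determination.
#'
#' @param candidate_results Tibble from [run_pipeline()] (columns
#'   `pedigree_id`, `variant_key`, `gene`, `segregates`, `novel`,
#'   `control_ok`, `confirmed`).
#' @param causality Optional tibble (`pedigree_id`, `variant_key`,
#'   `uncertain`).
#' @param known_variants Character vector of previously reported keys.
#' @return List with counts, the recurrence table, and the recurrence
#'   histogram.
#' @export
summarize_causal_set <- function(candidate_results, causality = NULL,
                                 known_variants = character(0),
                                 n_pedigrees = NULL) {
  cr <- tibble::as_tibble(candidate_results)
  if (nrow(cr) == 0L) {
    return(list(n_pedigrees = n_pedigrees %||% 0L, n_solved = 0L,
                n_causal_variants = 0L,
                n_novel = 0L, n_known = 0L,
                recurrence = tibble::tibble(variant_key = character(0),
                                            gene = character(0),
                                            n_pedigrees = integer(0)),
                recurrence_histogram = table(integer(0)),
                max_recurrence_key = NULL, max_recurrence_count = 0L))
  }
  cr$uncertain <- FALSE
  if (!is.null(causality)) {
    causality <- tibble::as_tibble(causality)
    hit <- mapply(function(p, k) any(same_pedigree_id(causality$pedigree_id, p) &
                                       causality$variant_key == k &
                                       causality$uncertain),
                  cr$pedigree_id, cr$variant_key)
    cr$uncertain <- as.logical(hit)
    orphan <- !causality$variant_key %in% cr$variant_key
    if (any(orphan)) {
      stop("causality assignment references a variant absent from the candidates: ",
           causality$variant_key[orphan][1L])
    }
  }
  causal <- cr[cr$confirmed & !cr$uncertain, , drop = FALSE]
  recurrence <- causal |>
    dplyr::group_by(.data$variant_key, .data$gene) |>
    dplyr::summarise(n_pedigrees = dplyr::n_distinct(.data$pedigree_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_pedigrees), .data$variant_key)
  keys <- recurrence$variant_key
  n_known <- sum(keys %in% known_variants)
  list(
    n_pedigrees = n_pedigrees %||% dplyr::n_distinct(cr$pedigree_id),
    n_solved = dplyr::n_distinct(causal$pedigree_id),
    n_causal_variants = length(keys),
    n_novel = length(keys) - n_known,
    n_known = n_known,
    recurrence = recurrence,
    recurrence_histogram = table(recurrence$n_pedigrees),
    max_recurrence_key = if (length(keys)) recurrence$variant_key[1L] else NULL,
    max_recurrence_count = if (length(keys)) recurrence$n_pedigrees[1L] else 0L
  )
}
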