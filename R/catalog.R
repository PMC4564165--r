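# Cohort-level tabulation of QC-passing single-nucleotide variants across
# pedigrees, and extraction of the population-unique recurrent catalog
# (variants recurrent in unrelated pedigrees yet absent from the public
# databases - interpreted as common in, and unique to, the study
# population).

#' Tabulate QC-passing SNVs by pedigree
#'
#' One catalog entry per distinct variant; the recurrence count is the
#' number of distinct pedigrees in which at least one genotyped member
#' carries a non-reference genotype. Indels are excluded (the catalog is
#' defined over single nucleotide variants only).
#'
#' @param carriers Tibble with columns `pedigree_id` and `variant_key`,
#'   one row per (pedigree, QC-passing carried variant); duplicates are
#'   tolerated and collapsed.
#' @return Tibble with `variant_key`, `chrom`, `pos`, `ref`, `alt`,
#'   `pedigree_count`, `pedigrees` (comma-joined sorted ids), ordered by
#'   (chrom, pos, ref, alt).
#' @export
tabulate_by_pedigree <- function(carriers) {
  carriers <- tibble::as_tibble(carriers)
  carriers <- dplyr::distinct(carriers, .data$pedigree_id, .data$variant_key)
  parsed <- parse_variant_key(carriers$variant_key)
  carriers <- dplyr::bind_cols(carriers, parsed)
  carriers <- carriers[is_snv(carriers$ref, carriers$alt), , drop = FALSE]
  out <- carriers |>
    dplyr::group_by(.data$variant_key, .data$chrom, .data$pos, .data$ref,
                    .data$alt) |>
    dplyr::summarise(
      pedigree_count = dplyr::n_distinct(.data$pedigree_id),
      pedigrees = paste(sort(unique(.data$pedigree_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  out
}

#' Extract the population-unique recurrent catalog
#'
#' Keeps catalog entries observed in at least `min_pedigrees` distinct
#' pedigrees and absent from every configured database (any listing,
#' with or without a frequency, counts as present).
#'
#' @param entries Catalog tibble from [tabulate_by_pedigree()].
#' @param membership Named list of membership tables
#'   ([read_membership_tables()]).
#' @param min_pedigrees Recurrence threshold, inclusive (default 5, the
#'   "five or more unrelated pedigrees" reading).
#' @return The filtered catalog with one `in_<db>` logical column per
#'   database and a `population_unique` column (all `TRUE` after
#'   filtering); attribute `full` carries the annotated unfiltered catalog.
#' @export
population_unique_catalog <- function(entries, membership,
                                      min_pedigrees = 5L) {
  min_pedigrees <- as.integer(min_pedigrees)
  if (is.na(min_pedigrees) || min_pedigrees < 1L) {
    stop("min_pedigrees must be a positive integer")
  }
  entries <- tibble::as_tibble(entries)
  present_any <- rep(FALSE, nrow(entries))
  for (db in names(membership)) {
    hit <- entries$variant_key %in% membership[[db]]$variant_key
    entries[[paste0("in_", db)]] <- hit
    present_any <- present_any | hit
  }
  entries$population_unique <-
    entries$pedigree_count >= min_pedigrees & !present_any
  filtered <- entries[entries$population_unique, , drop = FALSE]
  attr(filtered, "full") <- entries
  filtered
}

#' Write the recurrent-variant catalog
#'
#' @param catalog Tibble from [tabulate_by_pedigree()] or
#'   [population_unique_catalog()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  tab <- as.data.frame(catalog)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
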