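# Database membership tables, control genotype tables, and the candidate
# report (tab-separated + JSON sidecar).

#' Read database membership tables
#'
#' Each table is tab-separated with columns chrom, pos, ref, alt and an
#' optional fifth column carrying the homozygous genotype frequency.
#' Tables without the frequency column (dbSNP-style presence lists) map
#' every listed variant to "present, frequency unknown" (`NA`).
#'
#' @param paths Named character vector of file paths; names are database
#'   names (e.g. `c(HapMap = "...", dbSNP = "...")`).
#' @return Named list: database name -> tibble with columns `variant_key`,
#'   `hom_freq` (`NA` = present with unknown frequency).
#' @export
read_membership_tables <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("membership table paths must be named by database")
  }
  out <- lapply(seq_along(paths), function(i) {
    path <- paths[[i]]
    first <- readLines(path, n = 1L)
    if (!length(first)) {
      return(tibble::tibble(variant_key = character(0), hom_freq = numeric(0)))
    }
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!ncol(tab) %in% c(4L, 5L)) {
      stop("membership table must have 4 or 5 columns: ", path)
    }
    key <- variant_key(tab[[1L]], as.integer(tab[[2L]]), tab[[3L]], tab[[4L]])
    freq <- if (ncol(tab) == 5L) as.numeric(tab[[5L]]) else rep(NA_real_, nrow(tab))
    bad <- !is.na(freq) & (freq < 0 | freq > 1)
    if (any(bad)) {
      stop("homozygous genotype frequency outside [0,1] in ", path,
           " for ", key[bad][1L])
    }
    tibble::tibble(variant_key = key, hom_freq = freq)
  })
  stats::setNames(out, names(paths))
}

#' Write one database membership table
#'
#' @param tab Tibble with `variant_key` and optionally `hom_freq`.
#' @param path Output path.
#' @param with_freq Write the frequency column? Set `FALSE` for
#'   presence-only databases.
#' @return `path`, invisibly.
#' @export
write_membership_table <- function(tab, path, with_freq = TRUE) {
  parsed <- parse_variant_key(tab$variant_key)
  ord <- order(parsed$chrom, parsed$pos, parsed$ref, parsed$alt)
  lines <- if (with_freq) {
    paste(parsed$chrom, parsed$pos, parsed$ref, parsed$alt,
          fmt_num(tab$hom_freq), sep = "\t")[ord]
  } else {
    paste(parsed$chrom, parsed$pos, parsed$ref, parsed$alt, sep = "\t")[ord]
  }
  writeLines(lines, path)
  invisible(path)
}

# merge membership-table frequencies into each variant's db_hom_freqs map;
# VCF-carried INFO frequencies win on conflict.
merge_membership <- function(variants, membership) {
  if (is.null(membership) || !length(membership)) return(variants)
  variants$db_hom_freqs <- lapply(seq_len(nrow(variants)), function(i) {
    freqs <- variants$db_hom_freqs[[i]]
    for (db in names(membership)) {
      if (db %in% names(freqs)) next
      hit <- match(variants$variant_key[i], membership[[db]]$variant_key)
      if (!is.na(hit)) freqs[db] <- membership[[db]]$hom_freq[hit]
    }
    freqs
  })
  variants
}

#' Read control genotype counts
#'
#' One variant per row, tab-separated with header: chrom, pos, ref, alt,
#' n_controls, n_het, n_hom.
#'
#' @param path Path to the control table.
#' @return Tibble with `variant_key`, `n_controls`, `n_het`, `n_hom`.
#' @export
read_controls <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "n_controls", "n_het", "n_hom")
  if (!all(required %in% names(tab))) {
    stop("control table must have columns ", paste(required, collapse = ", "))
  }
  if (any(tab$n_het + tab$n_hom > tab$n_controls)) {
    stop("control carrier counts exceed panel size in ", path)
  }
  tibble::tibble(
    variant_key = variant_key(tab$chrom, tab$pos, tab$ref, tab$alt),
    n_controls = as.integer(tab$n_controls),
    n_het = as.integer(tab$n_het),
    n_hom = as.integer(tab$n_hom)
  )
}

#' Write control genotype counts
#' @param controls Tibble as returned by [read_controls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_controls <- function(controls, path) {
  parsed <- parse_variant_key(controls$variant_key)
  tab <- cbind(parsed, controls[, c("n_controls", "n_het", "n_hom")])
  tab <- tab[order(tab$chrom, tab$pos, tab$ref, tab$alt), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

REPORT_COLS <- c(
  "pedigree_id", "gene", "variant_key", "hgvs_c", "hgvs_p", "region_class",
  "status", "first_failing_stage", "segregates", "n_inconsistent",
  "control_hom", "novel", "causal"
)

#' Write the candidate report
#'
#' Tab-separated per-variant report (every input variant appears: candidates,
#' off-panel survivors, and eliminated variants with their first failing
#' stage) plus a JSON sidecar holding the run configuration echo and summary
#' counts. Rows are sorted by (pedigree, gene, variant key); two runs on the
#' same input produce byte-identical files.
#'
#' @param report Tibble with the columns listed in the vignette (one row per
#'   pedigree x variant).
#' @param sidecar List serialized to JSON alongside the table.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, sidecar, path) {
  report <- tibble::as_tibble(report)
  missing_cols <- setdiff(REPORT_COLS, names(report))
  for (col in missing_cols) report[[col]] <- NA
  report <- report[, REPORT_COLS]
  report <- dplyr::arrange(report, .data$pedigree_id, .data$gene,
                           .data$variant_key)
  body <- if (nrow(report)) {
    fmt <- vapply(report, function(col) {
      out <- as.character(col)
      out[is.na(col)] <- "."
      out
    }, character(nrow(report)))
    fmt <- matrix(fmt, nrow = nrow(report),
                  dimnames = list(NULL, REPORT_COLS))
    apply(fmt, 1L, paste, collapse = "\t")
  } else {
    character(0)
  }
  lines <- c(paste(REPORT_COLS, collapse = "\t"), body)
  writeLines(lines, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a candidate report back
#'
#' @param path Path written by [write_candidate_report()].
#' @return List with `report` (tibble) and `sidecar` (list).
#' @export
read_candidate_report <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = ".",
                           colClasses = "character")
  report <- tibble::as_tibble(tab)
  for (col in c("segregates", "novel")) {
    report[[col]] <- as.logical(report[[col]])
  }
  for (col in c("n_inconsistent", "control_hom")) {
    report[[col]] <- as.integer(report[[col]])
  }
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL
  list(report = report, sidecar = sidecar)
}
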