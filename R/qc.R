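# Per-variant site quality screening, applied to the exome-sequenced
# samples of a pedigree before any biological filtering.

#' Site QC thresholds
#'
#' Thresholds are exclusive, following the literal reading of "read depth
#' >10, mapping quality score >30": a call at exactly the threshold fails.
#'
#' @param min_depth_exclusive Depth must be strictly greater (default 10).
#' @param min_mapping_quality_exclusive Mapping quality must be strictly
#'   greater (default 30, Phred-scaled).
#' @param exclude_strand_bias Fail sites with any strand-bias-flagged call
#'   (default `TRUE`).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_depth_exclusive = 10,
                          min_mapping_quality_exclusive = 30,
                          exclude_strand_bias = TRUE) {
  stopifnot(min_depth_exclusive >= 0, min_mapping_quality_exclusive >= 0,
            is.logical(exclude_strand_bias))
  structure(list(
    min_depth_exclusive = min_depth_exclusive,
    min_mapping_quality_exclusive = min_mapping_quality_exclusive,
    exclude_strand_bias = isTRUE(exclude_strand_bias)
  ), class = "qc_thresholds")
}

#' Site-level quality verdict for one variant
#'
#' A site passes when every non-missing call among the supplied (exome-
#' sequenced) samples has depth and mapping quality strictly above the
#' thresholds and, if strand-bias exclusion is on, no call is flagged.
#' Missing calls are ignored; a site with only missing calls is not
#' assessable and is excluded with reason `"no data"`.
#'
#' @param calls Tibble of genotype calls for one variant in one pedigree
#'   (columns `zygosity`, `depth`, `mapping_quality`, `strand_bias`).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `verdict` (`"retained"`, `"eliminated"`, or
#'   `"not_applicable"`) and `reason`.
#' @export
passes_site_qc <- function(calls, thresholds = qc_thresholds()) {
  calls <- tibble::as_tibble(calls)
  live <- calls[calls$zygosity != "missing", , drop = FALSE]
  if (nrow(live) == 0L) {
    return(list(verdict = "not_applicable", reason = "no data"))
  }
  if (any(is.na(live$depth)) || any(live$depth <= thresholds$min_depth_exclusive)) {
    return(list(verdict = "eliminated", reason = "depth"))
  }
  if (any(is.na(live$mapping_quality)) ||
      any(live$mapping_quality <= thresholds$min_mapping_quality_exclusive)) {
    return(list(verdict = "eliminated", reason = "mapping quality"))
  }
  if (thresholds$exclude_strand_bias && any(live$strand_bias %in% TRUE)) {
    return(list(verdict = "eliminated", reason = "strand bias"))
  }
  list(verdict = "retained", reason = "")
}
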