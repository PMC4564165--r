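# Co-segregation verification across all genotyped pedigree members (the
# in-silico counterpart of Sanger confirmation) and the screen of novel
# candidates against ethnicity-matched controls.

#' Check co-segregation of a variant with affection status
#'
#' Under complete penetrance and no phenocopies a variant segregates iff
#' every genotyped affected member with known status is homozygous
#' alternate and no genotyped unaffected member is. Heterozygous unaffected
#' parents and siblings are consistent (carriers). Members with unknown
#' affection or a missing genotype are excluded from the verdict and not
#' counted as informative.
#'
#' @param calls Tibble of calls for one variant with columns `sample_id`
#'   and `zygosity`, covering the genotyped members.
#' @param ped An `ird_pedigree`; membership and affection are taken from it.
#' @param allow_nonpenetrant Number of unaffected homozygous-alternate
#'   members tolerated before the verdict fails (escape hatch for reduced
#'   penetrance; default 0).
#' @return List of class `segregation_result`: `variant_key` (if present in
#'   `calls`), `segregates`, `inconsistent_members` (tibble: individual_id,
#'   observed, required), `n_informative`.
#' @export
check_segregation <- function(calls, ped, allow_nonpenetrant = 0L) {
  calls <- tibble::as_tibble(calls)
  m <- ped$members
  geno <- m[m$genotyped, , drop = FALSE]
  if (!any(geno$affection == "affected" &
             geno$individual_id %in% calls$sample_id)) {
    stop("pedigree ", ped$pedigree_id,
         " has no genotyped affected member with a call for this variant")
  }
  obs <- calls[match(geno$individual_id, calls$sample_id), "zygosity",
               drop = TRUE]
  informative <- !is.na(obs) & obs != "missing" & geno$affection != "unknown"
  geno <- geno[informative, , drop = FALSE]
  obs <- obs[informative]
  bad_aff <- geno$affection == "affected" & obs != "hom_alt"
  bad_una <- geno$affection == "unaffected" & obs == "hom_alt"
  inconsistent <- tibble::tibble(
    individual_id = geno$individual_id[bad_aff | bad_una],
    observed = obs[bad_aff | bad_una],
    required = ifelse(bad_aff[bad_aff | bad_una],
                      "hom_alt (affected)", "not hom_alt (unaffected)")
  )
  n_nonpen <- sum(bad_una)
  segregates <- sum(bad_aff) == 0L && n_nonpen <= allow_nonpenetrant &&
    nrow(geno) >= 1L
  structure(list(
    variant_key = if ("variant_key" %in% names(calls))
      calls$variant_key[1L] else NA_character_,
    segregates = segregates,
    inconsistent_members = inconsistent,
    n_informative = nrow(geno)
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> %s: %s (%d informative members, %d inconsistent)\n",
              x$variant_key, if (x$segregates) "segregates" else "does NOT segregate",
              x$n_informative, nrow(x$inconsistent_members)))
  invisible(x)
}

#' Screen a variant against unrelated controls
#'
#' A novel recessive candidate is expected to be absent in the homozygous
#' state from ethnicity-matched unrelated controls. Under the default
#' policy heterozygous carriers are permitted (rare recessive allele);
#' the strict policy refuses any carrier.
#'
#' @param n_controls Number of controls screened (default 96).
#' @param n_het Heterozygous carriers observed among controls.
#' @param n_hom Homozygous-alternate controls observed.
#' @param policy `"hom_refutes"` (default) or `"no_carriers"`.
#' @param variant_key Optional identifier carried through.
#' @return List of class `control_screen_result` with `novel_in_controls`.
#' @export
screen_controls <- function(n_controls = 96L, n_het = 0L, n_hom = 0L,
                            policy = c("hom_refutes", "no_carriers"),
                            variant_key = NA_character_) {
  policy <- match.arg(policy)
  n_controls <- as.integer(n_controls)
  if (is.na(n_controls) || n_controls < 1L) {
    stop("control screen requires a non-empty control panel")
  }
  if (n_het + n_hom > n_controls) {
    stop("control carrier counts exceed the control panel size")
  }
  ok <- if (policy == "hom_refutes") n_hom == 0L else n_hom == 0L && n_het == 0L
  structure(list(
    variant_key = variant_key,
    n_controls = n_controls,
    n_carriers = as.integer(n_het),
    n_hom_alt = as.integer(n_hom),
    novel_in_controls = ok,
    policy = policy
  ), class = "control_screen_result")
}

#' Targeted single-variant screen of a pedigree without exome data
#'
#' Supports the workflow where a variant recurrent in other pedigrees is
#' typed directly (e.g. by dideoxy sequencing) in a new pedigree: the
#' supplied genotypes cover the named variant only, and the segregation
#' contract is identical to [check_segregation()].
#'
#' @param calls Tibble with `sample_id` and `zygosity` for the one typed
#'   variant (optionally a `variant_key` column).
#' @param ped An `ird_pedigree`. Members appearing in `calls` are treated
#'   as genotyped.
#' @param allow_nonpenetrant See [check_segregation()].
#' @return A `segregation_result`.
#' @export
targeted_screen <- function(calls, ped, allow_nonpenetrant = 0L) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0L) {
    stop("targeted screen requires at least one genotyped member")
  }
  m <- ped$members
  m$genotyped <- m$genotyped | m$individual_id %in% calls$sample_id
  ped2 <- pedigree(ped$pedigree_id, m, ped$loops)
  check_segregation(calls, ped2, allow_nonpenetrant)
}
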