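#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Marker used in pedigree tables for "no parent recorded" (PED dialect).
FOUNDER_MARKER <- "0"

# Fixed stage order of the filter cascade; every FilterTrace records a
# verdict for each of these, in this order.
CASCADE_STAGES <- c("qc", "recessive", "frequency", "region", "biotype")

REGION_CLASSES <- c(
  "coding_missense", "coding_nonsense", "coding_synonymous",
  "coding_indel_frameshift", "coding_indel_inframe",
  "coding_unknown", "noncoding_exonic",
  "intronic", "utr5", "utr3", "nontranscribed"
)

PREDICTOR_COLS <- c("mutation_taster", "polyphen", "provean", "sift")

#' Canonical variant identifier
#'
#' Builds the `"chrom:pos:ref:alt"` key used throughout the pipeline to
#' identify one normalized alternate allele at a genomic site. Chromosome
#' names are normalized by stripping a leading `"chr"` so hg19-style and
#' Ensembl-style inputs collide onto the same key.
#'
#' @param chrom Chromosome name(s); a leading `"chr"` is stripped.
#' @param pos 1-based position(s), positive integers.
#' @param ref,alt Reference / alternate alleles, non-empty uppercase ACGT
#'   strings with `ref != alt`.
#' @return Character vector of keys, one per input variant.
#' @examples
#' variant_key("chr1", 68904047, "C", "A")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- suppressWarnings(as.integer(pos))
  ref <- as.character(ref)
  alt <- as.character(alt)
  bad_allele <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad_allele)) {
    stop("malformed allele characters (alleles must be non-empty uppercase ACGT): ",
         paste(unique(paste0(ref[bad_allele], ">", alt[bad_allele])), collapse = ", "))
  }
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant position must be a positive 1-based integer")
  }
  if (any(ref == alt)) {
    stop("ref and alt allele must differ")
  }
  if (any(chrom == "" | grepl("[:[:space:]]", chrom))) {
    stop("chromosome names must be non-empty and contain no ':' or whitespace")
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Parse a canonical variant key back into its fields
#'
#' @param key Character vector of `"chrom:pos:ref:alt"` keys.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  if (!length(key)) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0)))
  }
  parts <- strsplit(as.character(key), ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("malformed variant key: ", key[lengths(parts) != 4L][1L])
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  out <- tibble::tibble(
    chrom = m[, 1L],
    pos   = as.integer(m[, 2L]),
    ref   = m[, 3L],
    alt   = m[, 4L]
  )
  # re-validate through the constructor so parse() is the inverse of key()
  variant_key(out$chrom, out$pos, out$ref, out$alt)
  out
}

#' Is a variant a single-nucleotide variant?
#'
#' @param ref,alt Allele strings.
#' @return Logical vector; `TRUE` where both alleles have length 1.
#' @export
is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L
}

#' Classify a raw diploid genotype string
#'
#' Maps VCF-style genotype strings onto zygosity states. Phased (`|`) and
#' unphased (`/`) separators are treated identically; a partially missing
#' genotype counts as missing. The function is total over the nine
#' well-formed diploid strings built from alleles `{0, 1, .}` and raises on
#' anything else, in particular on allele indices greater than 1 (residue of
#' an unsplit multi-allelic record).
#'
#' @param gt Character vector of genotype strings, e.g. `"0/1"`, `"1|1"`.
#' @return Character vector over `{"hom_ref", "het", "hom_alt", "missing"}`.
#' @examples
#' classify_genotype(c("1/1", "0|1", "./."))
#' @export
classify_genotype <- function(gt) {
  gt <- as.character(gt)
  shaped <- grepl("^[0-9.]+[/|][0-9.]+$", gt)
  multi <- shaped & grepl("[2-9]", gt)
  if (any(multi)) {
    stop("allele index > 1 in genotype ", shQuote(gt[multi][1L]),
         ": multi-allelic record must be split before classification")
  }
  ok <- grepl("^[01.][/|][01.]$", gt)
  if (any(!ok)) {
    stop("malformed diploid genotype string: ", shQuote(gt[!ok][1L]))
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  out <- rep("het", length(gt))
  out[a1 == "." | a2 == "."] <- "missing"
  out[a1 == "0" & a2 == "0"] <- "hom_ref"
  out[a1 == "1" & a2 == "1"] <- "hom_alt"
  out
}

#' Construct a pedigree
#'
#' A pedigree is a directed family graph with affection status. Members are
#' held in a tibble; consanguinity is summarized by the loop count (number
#' of consanguineous marriages).
#'
#' @param pedigree_id Identifier string. Identifier prefixes are cosmetic:
#'   two ids match if their numeric suffixes match (see [same_pedigree_id()]).
#' @param members Data frame with columns `individual_id`, `father_id`,
#'   `mother_id` (`"0"` = founder), `sex` (`"male"`, `"female"`,
#'   `"unknown"`), `affection` (`"affected"`, `"unaffected"`, `"unknown"`),
#'   and optionally `genotyped` and `sequenced` (logical; `sequenced`
#'   marks exome-sequenced members, a subset of `genotyped`).
#' @param loops Count of consanguineous marriages (integer >= 0).
#' @return An object of class `ird_pedigree`.
#' @export
pedigree <- function(pedigree_id, members, loops = 0L) {
  members <- tibble::as_tibble(members)
  required <- c("individual_id", "father_id", "mother_id", "sex", "affection")
  missing_cols <- setdiff(required, names(members))
  if (length(missing_cols)) {
    stop("pedigree members table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"genotyped" %in% names(members)) members$genotyped <- FALSE
  if (!"sequenced" %in% names(members)) members$sequenced <- FALSE
  members$individual_id <- as.character(members$individual_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  if (anyDuplicated(members$individual_id)) {
    stop("duplicate individual_id in pedigree ", pedigree_id)
  }
  if (!all(members$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of male/female/unknown")
  }
  if (!all(members$affection %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be one of affected/unaffected/unknown")
  }
  known <- c(FOUNDER_MARKER, members$individual_id)
  unresolved <- !(members$father_id %in% known) | !(members$mother_id %in% known)
  if (any(unresolved)) {
    stop("parent reference does not resolve within pedigree ", pedigree_id,
         ": ", members$individual_id[unresolved][1L])
  }
  half <- xor(members$father_id == FOUNDER_MARKER,
              members$mother_id == FOUNDER_MARKER)
  if (any(half)) {
    stop("individual must have both or neither parent recorded: ",
         members$individual_id[half][1L])
  }
  if (any(members$sequenced & !members$genotyped)) {
    stop("sequenced members must be genotyped")
  }
  if (!any(members$affection == "affected")) {
    stop("pedigree ", pedigree_id, " has no affected member")
  }
  assert_acyclic(members, pedigree_id)
  loops <- as.integer(loops)
  if (is.na(loops) || loops < 0L) stop("loops must be a non-negative integer")
  structure(
    list(pedigree_id = as.character(pedigree_id),
         members = members,
         loops = loops),
    class = "ird_pedigree"
  )
}

assert_acyclic <- function(members, pedigree_id) {
  # peel founders repeatedly; leftovers imply a parent-child cycle
  placed <- character(0)
  remaining <- members
  repeat {
    ready <- (remaining$father_id %in% c(FOUNDER_MARKER, placed)) &
      (remaining$mother_id %in% c(FOUNDER_MARKER, placed))
    if (!any(ready)) break
    placed <- c(placed, remaining$individual_id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
    if (nrow(remaining) == 0L) return(invisible(TRUE))
  }
  stop("pedigree ", pedigree_id, " contains a parent-child cycle")
}

#' @export
print.ird_pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf(
    "<ird_pedigree> %s: %d members (%d affected, %d genotyped, %d sequenced), %d consanguineous loop(s)\n",
    x$pedigree_id, nrow(m), sum(m$affection == "affected"),
    sum(m$genotyped), sum(m$sequenced), x$loops))
  invisible(x)
}

#' Compare pedigree identifiers on their numeric suffix
#'
#' Cohort records sometimes alternate letter prefixes for the same family
#' (e.g. `PKRD176` vs `PKRP176`); prefixes are cosmetic and identifiers
#' match when the trailing digits match.
#'
#' @param a,b Pedigree identifier vectors.
#' @return Logical vector.
#' @export
same_pedigree_id <- function(a, b) {
  num <- function(x) sub("^[^0-9]*", "", as.character(x))
  num(a) == num(b)
}

# internal accessors ---------------------------------------------------------

ped_members <- function(ped) ped$members

ped_ids <- function(ped, affection = NULL, genotyped = NULL, sequenced = NULL) {
  m <- ped$members
  keep <- rep(TRUE, nrow(m))
  if (!is.null(affection)) keep <- keep & m$affection %in% affection
  if (!is.null(genotyped)) keep <- keep & m$genotyped == genotyped
  if (!is.null(sequenced)) keep <- keep & m$sequenced == sequenced
  m$individual_id[keep]
}

#' Assemble a cohort input object
#'
#' Bundles one pedigree with its variant table and genotype calls; the
#' in-memory form of one family's VCF + PED pair.
#'
#' @param pedigree An [pedigree()] object.
#' @param variants Tibble of variants (one row per normalized alternate
#'   allele) carrying the annotation columns used by the cascade.
#' @param genotypes Long tibble of per-call data with columns `variant_key`,
#'   `sample_id`, `zygosity`, `depth`, `mapping_quality`, `strand_bias`.
#' @return An object of class `ird_cohort`.
#' @export
cohort_input <- function(pedigree, variants, genotypes) {
  stopifnot(inherits(pedigree, "ird_pedigree"))
  variants <- tibble::as_tibble(variants)
  genotypes <- tibble::as_tibble(genotypes)
  if (!"variant_key" %in% names(variants)) {
    variants$variant_key <- variant_key(variants$chrom, variants$pos,
                                        variants$ref, variants$alt)
  }
  gt_samples <- unique(genotypes$sample_id)
  ok <- gt_samples %in% ped_ids(pedigree, genotyped = TRUE)
  if (any(!ok)) {
    stop("genotyped sample absent from pedigree (or not flagged genotyped): ",
         gt_samples[!ok][1L])
  }
  orphan <- !genotypes$variant_key %in% variants$variant_key
  if (any(orphan)) {
    stop("genotype refers to unknown variant: ",
         genotypes$variant_key[orphan][1L])
  }
  structure(
    list(pedigree = pedigree, variants = variants, genotypes = genotypes),
    class = "ird_cohort"
  )
}

#' @export
print.ird_cohort <- function(x, ...) {
  cat(sprintf("<ird_cohort> pedigree %s: %d variants, %d genotype calls\n",
              x$pedigree$pedigree_id, nrow(x$variants), nrow(x$genotypes)))
  invisible(x)
}

# An empty per-variant filter trace skeleton.
empty_trace <- function() {
  tibble::tibble(
    variant_key = character(0),
    stage = character(0),
    verdict = character(0),
    reason = character(0)
  )
}
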