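# Cohort VCF + PED input/output.
#
# Annotation transport: the pipeline consumes externally computed
# annotations (predictor verdicts, splice-alteration calls, miRNA-target
# overlap, database homozygote frequencies) as structured INFO keys rather
# than recomputing them:
#
#   GENE, TX, BIOTYPE (underscored), TC5/TC3 (0/1 completeness),
#   MT/PP/PV/SF in {D,B,.} (MutationTaster/PolyPhen/PROVEAN/SIFT),
#   EFF in {missense,nonsense,synonymous,frameshift,inframe} (coding
#   consequence), SPLDIST (int), SPLALT (0/1), UTR5DIST (int),
#   MIRTGT (0/1), HOMFREQ_<DB>=<freq>, PRESENT_<DB> (flag, presence-only
#   databases), HGVSC/HGVSP (labels only).
#
# Missing keys yield "absent" states, never defaults that pass filters.
# Exome-sequenced samples (the subset with meaningful depth/MQ) are named
# in a "##exome_samples=" header line; remaining VCF samples are treated as
# Sanger-genotyped relatives.

INFO_HEADER <- c(
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=TX,Number=1,Type=String,Description="Transcript identifier">',
  '##INFO=<ID=BIOTYPE,Number=1,Type=String,Description="Transcript biotype (underscored)">',
  '##INFO=<ID=TC5,Number=1,Type=Integer,Description="Transcript 5-prime complete (1) or incomplete (0)">',
  '##INFO=<ID=TC3,Number=1,Type=Integer,Description="Transcript 3-prime complete (1) or incomplete (0)">',
  '##INFO=<ID=MT,Number=1,Type=Character,Description="MutationTaster verdict D/B">',
  '##INFO=<ID=PP,Number=1,Type=Character,Description="PolyPhen verdict D/B">',
  '##INFO=<ID=PV,Number=1,Type=Character,Description="PROVEAN verdict D/B">',
  '##INFO=<ID=SF,Number=1,Type=Character,Description="SIFT verdict D/B">',
  '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding consequence">',
  '##INFO=<ID=SPLDIST,Number=1,Type=Integer,Description="Bases to nearest splice site (intronic)">',
  '##INFO=<ID=SPLALT,Number=1,Type=Integer,Description="Predicted splice-altering (1) or not (0)">',
  '##INFO=<ID=UTR5DIST,Number=1,Type=Integer,Description="Bases upstream of the start codon (5-prime UTR)">',
  '##INFO=<ID=MIRTGT,Number=1,Type=Integer,Description="Within a miRNA-targeted region (1) or not (0)">',
  '##INFO=<ID=HGVSC,Number=1,Type=String,Description="cDNA change label">',
  '##INFO=<ID=HGVSP,Number=1,Type=String,Description="Protein change label">'
)

FORMAT_HEADER <- c(
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
  '##FORMAT=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
  '##FORMAT=<ID=SB,Number=1,Type=Integer,Description="Strand bias flag">'
)

# annotation columns every variant table carries (filled with absent states
# when the corresponding INFO key is missing)
ANNOTATION_COLS <- c(
  "gene", "transcript", "biotype", "complete_5p", "complete_3p",
  "mutation_taster", "polyphen", "provean", "sift", "coding_effect",
  "splice_distance", "splice_altering", "dist_upstream_of_start",
  "mirna_target", "hgvs_c", "hgvs_p"
)

blank_annotation <- function(n) {
  tibble::tibble(
    gene = rep(NA_character_, n),
    transcript = NA_character_,
    biotype = NA_character_,
    complete_5p = NA,
    complete_3p = NA,
    mutation_taster = "absent",
    polyphen = "absent",
    provean = "absent",
    sift = "absent",
    coding_effect = NA_character_,
    splice_distance = NA_integer_,
    splice_altering = NA,
    dist_upstream_of_start = NA_integer_,
    mirna_target = NA,
    hgvs_c = NA_character_,
    hgvs_p = NA_character_,
    db_hom_freqs = replicate(n, stats::setNames(numeric(0), character(0)),
                             simplify = FALSE)
  )
}

#' Read a cohort VCF with its pedigree file
#'
#' Parses one family's multi-sample VCF (annotation INFO keys documented in
#' the package vignette) together with its six-column PED file.
#' Multi-allelic records are split into one variant per alternate allele
#' with genotypes re-expressed against the split allele (other alternate
#' alleles count as reference). Samples present in the VCF are flagged
#' `genotyped`; samples named in the `##exome_samples=` header line are
#' additionally flagged `sequenced`.
#'
#' @param vcf_path Path to a VCF v4.x file.
#' @param ped_path Path to a whitespace-delimited 6-column PED file
#'   (family, individual, father, mother, sex, affection; affection coded
#'   2 = affected, 1 = unaffected, 0/-9 = unknown).
#' @param loops Consanguineous-loop count to record on the pedigree
#'   (defaults to a `##consanguineous_loops=` header line if present, else 0).
#' @return An `ird_cohort` object (see [cohort_input()]).
#' @export
read_cohort_vcf <- function(vcf_path, ped_path, loops = NULL) {
  ped_tab <- read_ped(ped_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  meta <- v@meta
  samples <- colnames(v@gt)[-1L]
  absent <- setdiff(samples, ped_tab$individual_id)
  if (length(absent)) {
    stop("VCF sample absent from PED file: ", absent[1L])
  }
  exo_line <- grep("^##exome_samples=", meta, value = TRUE)
  exome_samples <- if (length(exo_line)) {
    strsplit(sub("^##exome_samples=", "", exo_line[1L]), ",", fixed = TRUE)[[1L]]
  } else samples
  if (is.null(loops)) {
    loop_line <- grep("^##consanguineous_loops=", meta, value = TRUE)
    loops <- if (length(loop_line)) {
      as.integer(sub("^##consanguineous_loops=", "", loop_line[1L]))
    } else 0L
  }
  ped_tab$genotyped <- ped_tab$individual_id %in% samples
  ped_tab$sequenced <- ped_tab$individual_id %in% exome_samples
  ped <- pedigree(attr(ped_tab, "family_id"), ped_tab, loops = loops)

  fix <- v@fix
  n_rec <- nrow(fix)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- vcfR::extract.gt(v, element = "DP")
  mq_raw <- vcfR::extract.gt(v, element = "MQ")
  sb_raw <- vcfR::extract.gt(v, element = "SB")

  var_rows <- list()
  gt_rows <- list()
  for (i in seq_len(n_rec)) {
    chrom <- unname(sub("^chr", "", fix[i, "CHROM"]))
    pos <- unname(as.integer(fix[i, "POS"]))
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1L]]
    info <- parse_info(fix[i, "INFO"], record = i)
    for (k in seq_along(alts)) {
      key <- tryCatch(
        variant_key(chrom, pos, ref, alts[k]),
        error = function(e) stop("record ", i, " of ", basename(vcf_path),
                                 ": ", conditionMessage(e)))
      ann <- info_to_annotation(info, record = i)
      var_rows[[length(var_rows) + 1L]] <- c(
        list(chrom = chrom, pos = pos, ref = ref, alt = alts[k],
             variant_key = key),
        ann)
      gt_split <- split_genotype(gt_raw[i, ], k)
      gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
        variant_key = key,
        sample_id = samples,
        gt = unname(gt_split),
        zygosity = classify_genotype(gt_split),
        depth = suppressWarnings(as.integer(dp_raw[i, ])),
        mapping_quality = suppressWarnings(as.numeric(mq_raw[i, ])),
        strand_bias = !is.na(sb_raw[i, ]) & sb_raw[i, ] == "1"
      )
    }
  }
  variants <- dplyr::bind_rows(lapply(var_rows, tibble::as_tibble))
  genotypes <- dplyr::bind_rows(gt_rows)
  cohort_input(ped, variants, genotypes)
}

# re-express a raw GT vector against split allele k (others -> reference)
split_genotype <- function(gt, k) {
  gt[is.na(gt)] <- "./."
  map_tok <- function(tok) {
    ifelse(tok == ".", ".", ifelse(tok == as.character(k), "1", "0"))
  }
  sep <- ifelse(grepl("|", gt, fixed = TRUE), "|", "/")
  parts <- strsplit(gt, "[/|]")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("non-diploid genotype string: ", shQuote(gt[bad][1L]))
  a1 <- map_tok(vapply(parts, `[[`, "", 1L))
  a2 <- map_tok(vapply(parts, `[[`, "", 2L))
  paste0(a1, sep, a2)
}

parse_info <- function(info_str, record) {
  if (is.na(info_str) || info_str == "." || info_str == "") {
    return(stats::setNames(list(), character(0)))
  }
  fields <- strsplit(info_str, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) >= 2L) x[[2L]] else NA_character_,
                 character(1))
  if (anyDuplicated(keys)) {
    stop("malformed INFO (duplicate key) at record ", record)
  }
  stats::setNames(as.list(vals), keys)
}

info_to_annotation <- function(info, record) {
  get <- function(key) if (key %in% names(info)) info[[key]] else NA_character_
  as_flag <- function(x) if (is.na(x)) NA else x == "1"
  as_int <- function(x, key) {
    if (is.na(x)) return(NA_integer_)
    v <- suppressWarnings(as.integer(x))
    if (is.na(v)) stop("malformed INFO ", key, " at record ", record)
    v
  }
  verdict <- function(x, key) {
    if (is.na(x) || x == ".") return("absent")
    if (!x %in% c("D", "B")) stop("malformed INFO ", key, " at record ",
                                  record, " (expected D, B or .)")
    c(D = "damaging", B = "benign")[[x]]
  }
  eff <- get("EFF")
  if (!is.na(eff) &&
      !eff %in% c("missense", "nonsense", "synonymous", "frameshift", "inframe")) {
    stop("malformed INFO EFF at record ", record, ": ", eff)
  }
  freqs <- stats::setNames(numeric(0), character(0))
  hf_keys <- grep("^HOMFREQ_", names(info), value = TRUE)
  for (k in hf_keys) {
    val <- suppressWarnings(as.numeric(info[[k]]))
    if (is.na(val) || val < 0 || val > 1) {
      stop("malformed INFO ", k, " at record ", record,
           ": homozygous genotype frequency must be in [0,1]")
    }
    freqs[sub("^HOMFREQ_", "", k)] <- val
  }
  for (k in grep("^PRESENT_", names(info), value = TRUE)) {
    freqs[sub("^PRESENT_", "", k)] <- NA_real_ # present, frequency unknown
  }
  list(
    gene = get("GENE"),
    transcript = get("TX"),
    biotype = decode_biotype(get("BIOTYPE")),
    complete_5p = as_flag(get("TC5")),
    complete_3p = as_flag(get("TC3")),
    mutation_taster = verdict(get("MT"), "MT"),
    polyphen = verdict(get("PP"), "PP"),
    provean = verdict(get("PV"), "PV"),
    sift = verdict(get("SF"), "SF"),
    coding_effect = eff,
    splice_distance = as_int(get("SPLDIST"), "SPLDIST"),
    splice_altering = as_flag(get("SPLALT")),
    dist_upstream_of_start = as_int(get("UTR5DIST"), "UTR5DIST"),
    mirna_target = as_flag(get("MIRTGT")),
    hgvs_c = get("HGVSC"),
    hgvs_p = get("HGVSP"),
    db_hom_freqs = list(freqs)
  )
}

#' Write a cohort to a plain-text VCF
#'
#' Deterministic counterpart of [read_cohort_vcf()]: records sorted by
#' (chrom, pos, ref, alt), annotations serialized to the documented INFO
#' keys, genotype calls as `GT:DP:MQ:SB`. Identical inputs produce
#' byte-identical files.
#'
#' @param cohort An `ird_cohort` object.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  ped <- cohort$pedigree
  samples <- ped_ids(ped, genotyped = TRUE)
  exome <- ped_ids(ped, sequenced = TRUE)
  variants <- dplyr::arrange(cohort$variants, .data$chrom, .data$pos,
                             .data$ref, .data$alt)
  gt <- cohort$genotypes
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##exome_samples=", paste(exome, collapse = ",")),
    paste0("##consanguineous_loops=", ped$loops),
    INFO_HEADER,
    db_info_header(variants),
    FORMAT_HEADER,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    row <- variants[i, ]
    calls <- gt[gt$variant_key == row$variant_key, ]
    calls <- calls[match(samples, calls$sample_id), ]
    fmt <- paste(
      calls$gt,
      ifelse(is.na(calls$depth), ".", as.character(calls$depth)),
      ifelse(is.na(calls$mapping_quality), ".",
             fmt_num(calls$mapping_quality)),
      ifelse(is.na(calls$strand_bias), ".",
             as.integer(calls$strand_bias)),
      sep = ":")
    body[i] <- paste(c(row$chrom, row$pos, ".", row$ref, row$alt, ".", ".",
                       serialize_info(row), "GT:DP:MQ:SB", fmt),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

db_info_header <- function(variants) {
  if (!"db_hom_freqs" %in% names(variants)) return(character(0))
  maps <- variants$db_hom_freqs
  dbs <- sort(unique(unlist(lapply(maps, names))))
  vals <- unlist(maps)
  present_only <- dbs[vapply(dbs, function(d)
    all(is.na(vals[names(vals) == d])), logical(1))]
  freq_dbs <- setdiff(dbs, present_only)
  c(
    sprintf('##INFO=<ID=HOMFREQ_%s,Number=1,Type=Float,Description="Homozygous genotype frequency in %s">',
            freq_dbs, freq_dbs),
    sprintf('##INFO=<ID=PRESENT_%s,Number=0,Type=Flag,Description="Present in %s (frequency unknown)">',
            present_only, present_only)
  )
}

fmt_num <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  out <- ifelse(grepl(".", out, fixed = TRUE), sub("0+$", "", out), out)
  sub("\\.$", "", out)
}

serialize_info <- function(row) {
  kv <- character(0)
  add <- function(kv, key, val) {
    if (length(val) == 1L && !is.na(val)) c(kv, paste0(key, "=", val)) else kv
  }
  verd <- function(x) c(damaging = "D", benign = "B", absent = NA_character_)[[x]]
  kv <- add(kv, "GENE", row$gene)
  kv <- add(kv, "TX", row$transcript)
  kv <- add(kv, "BIOTYPE",
            if (is.na(row$biotype)) NA_character_ else encode_biotype(row$biotype))
  kv <- add(kv, "TC5", if (is.na(row$complete_5p)) NA else as.integer(row$complete_5p))
  kv <- add(kv, "TC3", if (is.na(row$complete_3p)) NA else as.integer(row$complete_3p))
  kv <- add(kv, "MT", verd(row$mutation_taster))
  kv <- add(kv, "PP", verd(row$polyphen))
  kv <- add(kv, "PV", verd(row$provean))
  kv <- add(kv, "SF", verd(row$sift))
  kv <- add(kv, "EFF", row$coding_effect)
  kv <- add(kv, "SPLDIST", row$splice_distance)
  kv <- add(kv, "SPLALT", if (is.na(row$splice_altering)) NA else as.integer(row$splice_altering))
  kv <- add(kv, "UTR5DIST", row$dist_upstream_of_start)
  kv <- add(kv, "MIRTGT", if (is.na(row$mirna_target)) NA else as.integer(row$mirna_target))
  kv <- add(kv, "HGVSC", row$hgvs_c)
  kv <- add(kv, "HGVSP", row$hgvs_p)
  freqs <- row$db_hom_freqs[[1L]]
  for (db in names(freqs)) {
    kv <- if (is.na(freqs[[db]])) {
      c(kv, paste0("PRESENT_", db))
    } else {
      c(kv, paste0("HOMFREQ_", db, "=", fmt_num(freqs[[db]])))
    }
  }
  if (!length(kv)) "." else paste(kv, collapse = ";")
}

#' Read a six-column PED file
#'
#' @param path Whitespace-delimited PED file (family, individual, father,
#'   mother, sex, affection).
#' @return A tibble of members with attribute `family_id`.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 6L) {
    stop("PED file must have exactly six columns: ", path)
  }
  names(tab) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex_code", "affection_code")
  fam <- unique(tab$family_id)
  if (length(fam) != 1L) {
    stop("PED file must describe a single family: ", path)
  }
  out <- tibble::tibble(
    individual_id = tab$individual_id,
    father_id = tab$father_id,
    mother_id = tab$mother_id,
    sex = dplyr::case_match(tab$sex_code, "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    affection = dplyr::case_match(tab$affection_code, "2" ~ "affected",
                                  "1" ~ "unaffected", .default = "unknown")
  )
  attr(out, "family_id") <- fam
  out
}

#' Write a pedigree to a PED file
#'
#' @param ped An `ird_pedigree` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  m <- ped$members
  sex_code <- dplyr::case_match(m$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  aff_code <- dplyr::case_match(m$affection, "affected" ~ "2",
                                "unaffected" ~ "1", .default = "0")
  lines <- paste(ped$pedigree_id, m$individual_id, m$father_id, m$mother_id,
                 sex_code, aff_code, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
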