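# Gene models: transcript interval sets used for region classification.
# Internally all intervals are 0-based half-open ([start0, end0)); the VCF
# and report surfaces are 1-based. A 1-based position p occupies the
# half-open interval [p-1, p).

new_gene_models <- function(transcripts, exons) {
  transcripts <- tibble::as_tibble(transcripts)
  exons <- tibble::as_tibble(exons)
  required_tx <- c("transcript", "gene", "chrom", "strand", "tx_start0",
                   "tx_end0", "cds_start0", "cds_end0", "biotype",
                   "complete_5p", "complete_3p")
  stopifnot(all(required_tx %in% names(transcripts)),
            all(c("transcript", "start0", "end0") %in% names(exons)))
  transcripts$chrom <- sub("^chr", "", transcripts$chrom)
  bad <- !exons$transcript %in% transcripts$transcript
  if (any(bad)) stop("exon for unknown transcript: ", exons$transcript[bad][1L])
  span <- merge(exons, transcripts[, c("transcript", "tx_start0", "tx_end0")],
                by = "transcript")
  out_of_span <- span$start0 < span$tx_start0 | span$end0 > span$tx_end0
  if (any(out_of_span)) {
    stop("exon outside its transcript span: ",
         span$transcript[out_of_span][1L])
  }
  # transcripts with no CDS are noncoding
  transcripts <- transcripts[, c(required_tx,
                                 setdiff(names(transcripts), required_tx))]
  transcripts$noncoding <- is.na(transcripts$cds_start0)
  exons <- dplyr::arrange(exons, .data$transcript, .data$start0)
  transcripts <- dplyr::arrange(transcripts, .data$transcript)
  structure(list(transcripts = transcripts, exons = exons),
            class = "ird_gene_models")
}

#' @export
print.ird_gene_models <- function(x, ...) {
  cat(sprintf("<ird_gene_models> %d transcripts in %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene)),
              nrow(x$exons)))
  invisible(x)
}

#' Read gene models
#'
#' Reads transcript/exon/CDS structures either from GFF3 (feature types
#' `gene`, `mRNA`/`transcript`, `exon`, `CDS`; attributes `biotype`,
#' `five_prime_complete`, `three_prime_complete` on the transcript) or from
#' the tab-separated fallback written by [write_gene_models()] with
#' `format = "tsv"`. Intervals are stored 0-based half-open internally;
#' transcripts without CDS features are flagged noncoding.
#'
#' @param path Path to a `.gff3`/`.gff` file or the TSV fallback.
#' @return An `ird_gene_models` object.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    read_gene_models_gff3(path)
  } else {
    read_gene_models_tsv(path)
  }
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(tx_rows) == 0L) stop("no transcript features in ", path)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  gene_name <- stats::setNames(
    if ("Name" %in% names(gene_rows)) gene_rows$Name else gene_rows$ID,
    gene_rows$ID)
  flag <- function(x) {
    if (is.null(x)) rep(NA, nrow(tx_rows)) else x %in% c("1", "true", "TRUE")
  }
  tx <- tibble::tibble(
    transcript = tx_rows$ID,
    gene = unname(gene_name[tx_rows$Parent]),
    chrom = tx_rows$seqnames,
    strand = tx_rows$strand,
    tx_start0 = tx_rows$start - 1L,
    tx_end0 = tx_rows$end,
    biotype = decode_biotype(tx_rows$biotype),
    complete_5p = flag(tx_rows$five_prime_complete),
    complete_3p = flag(tx_rows$three_prime_complete)
  )
  exon_rows <- df[df$type == "exon", , drop = FALSE]
  exons <- tibble::tibble(
    transcript = exon_rows$Parent,
    start0 = exon_rows$start - 1L,
    end0 = exon_rows$end
  )
  cds_rows <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds_rows)) {
    cds <- tibble::as_tibble(stats::aggregate(
      cbind(cds_start1 = cds_rows$start, cds_end1 = cds_rows$end),
      by = list(transcript = cds_rows$Parent),
      FUN = function(x) x[1L]))
    cds$cds_start1 <- vapply(split(cds_rows$start, cds_rows$Parent), min,
                             numeric(1))[cds$transcript]
    cds$cds_end1 <- vapply(split(cds_rows$end, cds_rows$Parent), max,
                           numeric(1))[cds$transcript]
  } else {
    cds <- tibble::tibble(transcript = character(0),
                          cds_start1 = numeric(0), cds_end1 = numeric(0))
  }
  tx$cds_start0 <- as.integer(cds$cds_start1[match(tx$transcript, cds$transcript)] - 1L)
  tx$cds_end0 <- as.integer(cds$cds_end1[match(tx$transcript, cds$transcript)])
  new_gene_models(tx, exons)
}

read_gene_models_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  required <- c("transcript", "gene", "chrom", "strand", "tx_start0",
                "tx_end0", "cds_start0", "cds_end0", "biotype",
                "complete_5p", "complete_3p", "exon_starts0", "exon_ends0")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("gene-model TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)
  starts <- split_ints(tab$exon_starts0)
  ends <- split_ints(tab$exon_ends0)
  exons <- tibble::tibble(
    transcript = rep(tab$transcript, lengths(starts)),
    start0 = unlist(starts),
    end0 = unlist(ends)
  )
  tx <- tibble::as_tibble(tab[, setdiff(required, c("exon_starts0", "exon_ends0"))])
  tx$biotype <- decode_biotype(tx$biotype)
  tx$cds_start0 <- ifelse(tx$cds_start0 < 0, NA_integer_, tx$cds_start0)
  tx$cds_end0 <- ifelse(tx$cds_end0 < 0, NA_integer_, tx$cds_end0)
  tx$complete_5p <- as.logical(tx$complete_5p)
  tx$complete_3p <- as.logical(tx$complete_3p)
  new_gene_models(tx, exons)
}

#' Write gene models
#'
#' Emits the transcript interval set as GFF3 (default) or as the
#' tab-separated fallback. Output is deterministic: transcripts sorted by
#' (chrom, start, transcript).
#'
#' @param models An `ird_gene_models` object.
#' @param path Output path.
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  tx <- dplyr::arrange(models$transcripts, .data$chrom, .data$tx_start0,
                       .data$transcript)
  if (format == "tsv") {
    ex <- split(models$exons, models$exons$transcript)
    tab <- tx
    tab$cds_start0 <- ifelse(is.na(tab$cds_start0), -1L, tab$cds_start0)
    tab$cds_end0 <- ifelse(is.na(tab$cds_end0), -1L, tab$cds_end0)
    tab$biotype <- encode_biotype(tab$biotype)
    tab$exon_starts0 <- vapply(tab$transcript, function(t)
      paste(ex[[t]]$start0, collapse = ","), character(1))
    tab$exon_ends0 <- vapply(tab$transcript, function(t)
      paste(ex[[t]]$end0, collapse = ","), character(1))
    tab$noncoding <- NULL
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  lines <- c("##gff-version 3")
  genes <- unique(tx[, c("gene", "chrom")])
  for (g in seq_len(nrow(genes))) {
    gt <- tx[tx$gene == genes$gene[g], , drop = FALSE]
    g_start <- min(gt$tx_start0) + 1L
    g_end <- max(gt$tx_end0)
    strand <- gt$strand[1L]
    lines <- c(lines, sprintf(
      "%s\tirdprior\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
      genes$chrom[g], g_start, g_end, strand, genes$gene[g], genes$gene[g]))
    for (t in seq_len(nrow(gt))) {
      row <- gt[t, ]
      lines <- c(lines, sprintf(
        "%s\tirdprior\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;biotype=%s;five_prime_complete=%d;three_prime_complete=%d",
        row$chrom, row$tx_start0 + 1L, row$tx_end0, row$strand,
        row$transcript, row$gene, encode_biotype(row$biotype),
        as.integer(row$complete_5p), as.integer(row$complete_3p)))
      ex <- models$exons[models$exons$transcript == row$transcript, ]
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\tirdprior\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          row$chrom, ex$start0[e] + 1L, ex$end0[e], row$strand,
          row$transcript))
      }
      if (!is.na(row$cds_start0)) {
        # CDS emitted per overlapping exon chunk
        for (e in seq_len(nrow(ex))) {
          cs <- max(ex$start0[e], row$cds_start0)
          ce <- min(ex$end0[e], row$cds_end0)
          if (cs < ce) {
            lines <- c(lines, sprintf(
              "%s\tirdprior\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
              row$chrom, cs + 1L, ce, row$strand, row$transcript))
          }
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Biotype strings carry underscores on file surfaces (VCF INFO forbids
# spaces); internal canonical form uses spaces, matching the usual
# spelled-out Ensembl labels ("nonsense mediated decay").
decode_biotype <- function(x) gsub("_", " ", as.character(x))
encode_biotype <- function(x) gsub(" ", "_", as.character(x))

# Geometry-level classification of one 1-based position against one
# transcript. Returns list(region, splice_distance, dist_upstream_of_start).
# region here is one of nontranscribed / intronic / utr5 / utr3 / cds /
# noncoding_exonic; the coding subclass is resolved by classify_region().
region_geometry <- function(pos1, tx_row, exons) {
  p0 <- pos1 - 1L # 0-based
  if (p0 < tx_row$tx_start0 || p0 >= tx_row$tx_end0) {
    return(list(region = "nontranscribed", splice_distance = NA_integer_,
                dist_upstream_of_start = NA_integer_))
  }
  in_exon <- any(p0 >= exons$start0 & p0 < exons$end0)
  if (!in_exon) {
    # intronic: distance 1 = first intronic base next to an exon
    ends1 <- exons$end0[exons$end0 <= p0]        # exons fully left of pos
    starts1 <- exons$start0[exons$start0 > p0]   # exons right of pos
    d_left <- if (length(ends1)) pos1 - max(ends1) else NA_integer_
    d_right <- if (length(starts1)) min(starts1) + 1L - pos1 else NA_integer_
    spl <- min(c(d_left, d_right), na.rm = TRUE)
    return(list(region = "intronic", splice_distance = as.integer(spl),
                dist_upstream_of_start = NA_integer_))
  }
  if (is.na(tx_row$cds_start0)) {
    return(list(region = "noncoding_exonic", splice_distance = NA_integer_,
                dist_upstream_of_start = NA_integer_))
  }
  cds_start1 <- tx_row$cds_start0 + 1L
  cds_end1 <- tx_row$cds_end0
  if (pos1 >= cds_start1 && pos1 <= cds_end1) {
    return(list(region = "cds", splice_distance = NA_integer_,
                dist_upstream_of_start = NA_integer_))
  }
  plus <- tx_row$strand != "-"
  five_prime <- if (plus) pos1 < cds_start1 else pos1 > cds_end1
  if (five_prime) {
    # spliced distance to the first base of the start codon, in transcript
    # orientation; distance 1 = exonic base immediately 5' of the ATG
    d <- if (plus) {
      exonic_span(exons, pos1, cds_start1 - 1L)
    } else {
      exonic_span(exons, cds_end1 + 1L, pos1)
    }
    return(list(region = "utr5", splice_distance = NA_integer_,
                dist_upstream_of_start = as.integer(d)))
  }
  list(region = "utr3", splice_distance = NA_integer_,
       dist_upstream_of_start = NA_integer_)
}

# number of exonic bases within the 1-based closed interval [lo1, hi1]
exonic_span <- function(exons, lo1, hi1) {
  if (hi1 < lo1) return(0L)
  lo0 <- lo1 - 1L
  hi0 <- hi1
  ov <- pmax(0L, pmin(exons$end0, hi0) - pmax(exons$start0, lo0))
  sum(ov)
}

#' Read a gene panel
#'
#' One gene symbol per line; symbols are uppercased and deduplicated.
#'
#' @param path Plain-text file, one symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of panel symbols.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("gene panel file is empty: ", path)
  sort(unique(toupper(lines)))
}

#' Write a gene panel
#' @param symbols Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(symbols, path) {
  writeLines(sort(unique(toupper(symbols))), path)
  invisible(path)
}
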