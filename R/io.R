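#' Pipeline configuration with all analysis thresholds
#'
#' Every cut-off used by the pipeline lives here exactly once: the
#' dual-threshold prioritization (supporting-method count >= 9, SpliceAI
#' >= 0.5), the common-variant allele frequency filter (> 0.01 drops), the
#' lenient comp-het partner frequency ceiling, the CADD damaging threshold
#' (> 20), the PVS1 disrupted-fraction rule (> 0.10), and the splicing
#' consensus windows (donor -3..+8, acceptor -12..+2).
#'
#' @param spcards_min,spliceai_min prioritization thresholds (inclusive).
#' @param af_max strict allele-frequency ceiling for NCSV candidates.
#' @param partner_af_max lenient ceiling for comp-het trans partners.
#' @param cadd_damaging CADD score above which a call counts as damaging.
#' @param pvs1_fraction disrupted fraction above which LoF-type
#'   consequences reach PVS1_Strong.
#' @param donor_window,acceptor_window consensus windows `c(lo, hi)`.
#' @param seed default seed for simulation subcommands.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(spcards_min = 9L, spliceai_min = 0.5,
                            af_max = 0.01, partner_af_max = 0.05,
                            cadd_damaging = 20, pvs1_fraction = 0.10,
                            donor_window = c(-3L, 8L),
                            acceptor_window = c(-12L, 2L), seed = 1L) {
  stopifnot(spcards_min > 0, spliceai_min > 0, af_max > 0,
            partner_af_max > 0, cadd_damaging > 0, pvs1_fraction > 0,
            donor_window[1] <= donor_window[2],
            acceptor_window[1] <= acceptor_window[2])
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read / write a genome reference as FASTA
#'
#' @param path FASTA file.
#' @return [read_genome_fasta()]: a [genome_ref()].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  genome_ref(setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' @rdname read_genome_fasta
#' @param genome a [genome_ref()].
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write transcript models as a TSV exon table
#'
#' One row per exon with columns `transcript_id`, `gene`, `contig`,
#' `strand`, `exon_start`, `exon_end`, `cds_start`, `cds_end` (genomic,
#' 1-based inclusive).
#'
#' @param path TSV file.
#' @param genome optional [genome_ref()]; when supplied, models are built
#'   (sequences derived and validated) on read.
#' @return list of [transcript_model()]s.
#' @export
read_transcripts_tsv <- function(path, genome = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "contig", "strand", "exon_start",
            "exon_end", "cds_start", "cds_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("transcript table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1], d$gene[1], d$contig[1], d$strand[1],
                     data.frame(start = d$exon_start, end = d$exon_end),
                     d$cds_start[1], d$cds_end[1])
  })
  if (!is.null(genome)) out <- lapply(out, function(m) build_transcript(genome, m))
  out[order(names(out))]
}

#' @rdname read_transcripts_tsv
#' @param transcripts list of [transcript_model()]s.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  rows <- lapply(transcripts, function(t) {
    data.frame(transcript_id = t$transcript_id, gene = t$gene,
               contig = t$contig, strand = t$strand,
               exon_start = t$exons$start, exon_end = t$exons$end,
               cds_start = t$cds_start, cds_end = t$cds_end,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write transcript models as GTF
#'
#' Thin wrappers over `rtracklayer` emitting/consuming `exon` and `CDS`
#' features with `transcript_id` and `gene_name` attributes.
#'
#' @param path GTF file.
#' @param genome optional [genome_ref()] to build models on read.
#' @return list of [transcript_model()]s.
#' @export
read_transcripts_gtf <- function(path, genome = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_transcripts_gtf requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", ]
    cds <- d[d$type == "CDS", ]
    if (nrow(cds) == 0L) stop("GTF transcript without CDS features", call. = FALSE)
    strand <- as.character(ex$strand[1])
    cds_start <- if (strand == "+") min(cds$start) else max(cds$end)
    cds_end <- if (strand == "+") max(cds$end) else min(cds$start)
    transcript_model(d$transcript_id[1],
                     if ("gene_name" %in% names(d)) d$gene_name[1] else NA,
                     as.character(ex$seqnames[1]), strand,
                     data.frame(start = ex$start, end = ex$end),
                     cds_start, cds_end)
  })
  if (!is.null(genome)) out <- lapply(out, function(m) build_transcript(genome, m))
  out[order(names(out))]
}

#' @rdname read_transcripts_gtf
#' @param transcripts list of built [transcript_model()]s (the CDS span is
#'   re-derived from the stored coordinates).
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("write_transcripts_gtf requires the rtracklayer package", call. = FALSE)
  }
  rows <- lapply(transcripts, function(t) {
    ex <- data.frame(seqnames = t$contig, start = t$exons$start,
                     end = t$exons$end, strand = t$strand, type = "exon",
                     transcript_id = t$transcript_id, gene_name = t$gene,
                     stringsAsFactors = FALSE)
    cds <- data.frame(seqnames = t$contig,
                      start = min(t$cds_start, t$cds_end),
                      end = max(t$cds_start, t$cds_end), strand = t$strand,
                      type = "CDS", transcript_id = t$transcript_id,
                      gene_name = t$gene, stringsAsFactors = FALSE)
    ## clip the CDS feature rows to the exon intervals
    cds_rows <- ex
    cds_rows$type <- "CDS"
    cds_rows$start <- pmax(cds_rows$start, cds$start)
    cds_rows$end <- pmin(cds_rows$end, cds$end)
    cds_rows <- cds_rows[cds_rows$start <= cds_rows$end, ]
    ## GFF phase: bases to skip to reach the next codon boundary
    ord <- if (t$strand == "+") order(cds_rows$start)
           else order(-cds_rows$start)
    lens <- (cds_rows$end - cds_rows$start + 1L)[ord]
    phase <- integer(length(lens))
    cum <- 0L
    for (i in seq_along(lens)) {
      phase[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + lens[i]
    }
    cds_rows$phase[ord] <- phase
    ex$phase <- NA_integer_
    rbind(ex, cds_rows)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$transcript_id <- df$transcript_id
  gr$gene_name <- df$gene_name
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

variant_table_columns <- c("variant_key", "gene", "hgvs_c",
                           "consequence_class", "spliceai", "spcards")

#' Read a variant annotation table (TSV)
#'
#' The schema mirrors a published-style variant table: `variant_key`
#' (`contig:pos:ref:alt`), `gene`, `hgvs_c`, `consequence_class`,
#' `spliceai`, `spcards`, optional `af*`, `sift`, `pp2`, `mt`, `cadd`,
#' `zygosity`, `prior_validation` and any extra columns (preserved).
#' `NA`/`.`/`-`/empty score fields become `NA`; malformed variant keys are
#' reported with their line number.
#'
#' @param path TSV file.
#' @return data.frame with parsed `contig`, `pos`, `ref`, `alt` columns
#'   added.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ".", "-", ""))
  missing <- setdiff(variant_table_columns, names(df))
  if (length(missing)) {
    stop("variant table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(as.character(df$variant_key), ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4L |
                 !vapply(parts, function(p) {
                   length(p) == 4L && !is.na(suppressWarnings(as.integer(p[2]))) &&
                     grepl("^[ACGTN]+$", p[3]) && grepl("^[ACGTN]+$", p[4])
                 }, logical(1)))
  if (length(bad)) {
    stop("malformed variant_key at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df$contig <- vapply(parts, `[`, "", 1L)
  df$pos <- as.integer(vapply(parts, `[`, "", 2L))
  df$ref <- vapply(parts, `[`, "", 3L)
  df$alt <- vapply(parts, `[`, "", 4L)
  df$spliceai <- as.numeric(df$spliceai)
  df$spcards <- as.integer(df$spcards)
  df
}

#' @rdname read_variant_table
#' @param df variant data.frame.
#' @export
write_variant_table <- function(df, path) {
  drop <- intersect(c("contig", "pos", "ref", "alt"), names(df))
  out <- df[, setdiff(names(df), drop), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a variant table from a VCF file
#'
#' Site-level parsing via `vcfR`; annotations are taken from INFO keys
#' `GENE`, `HGVSC`, `CLASS`, `SPLICEAI`, `SPCARDS` when present.
#'
#' @param path VCF file (plain text).
#' @return data.frame in the [read_variant_table()] schema.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variant_vcf requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  df <- data.frame(
    variant_key = sprintf("%s:%s:%s:%s", fix$CHROM, fix$POS, fix$REF, fix$ALT),
    gene = info_get("GENE"), hgvs_c = info_get("HGVSC"),
    consequence_class = info_get("CLASS"),
    spliceai = suppressWarnings(as.numeric(info_get("SPLICEAI"))),
    spcards = suppressWarnings(as.integer(info_get("SPCARDS"))),
    stringsAsFactors = FALSE)
  df$contig <- fix$CHROM
  df$pos <- as.integer(fix$POS)
  df$ref <- fix$REF
  df$alt <- fix$ALT
  df
}

#' Read / write splice event descriptor tables
#'
#' Columns: `variant_key`, `event_type`, `element_index`,
#' `sub_interval_start`, `sub_interval_end` (the sub-interval columns may
#' be `NA` for whole-element events).
#'
#' @param path TSV file.
#' @return data.frame; [as_splice_events()] converts rows to
#'   [splice_event()] objects.
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ".", ""))
  need <- c("variant_key", "event_type", "element_index")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_event_table
#' @param df event data.frame.
#' @export
write_event_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname read_event_table
#' @export
as_splice_events <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    sub <- if (!"sub_interval_start" %in% names(df) ||
               is.na(df$sub_interval_start[i])) NULL
           else c(df$sub_interval_start[i], df$sub_interval_end[i])
    splice_event(df$event_type[i], df$element_index[i], sub)
  })
}

#' Read / write cohort genotype tables
#'
#' Columns as consumed by [inheritance_screen()].
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_cohort_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ".", ""))
}

#' @rdname read_cohort_table
#' @param df cohort calls data.frame.
#' @export
write_cohort_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a summary report as JSON (machine) and TSV (human)
#'
#' @param report named list of report sections.
#' @param json_path,tsv_path output paths (`NULL` skips either form; the
#'   TSV form writes the headline-rate table only).
#' @return invisible list of written paths.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json_path)
  }
  if (!is.null(tsv_path) && !is.null(report$headline_rates)) {
    write.table(report$headline_rates, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
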