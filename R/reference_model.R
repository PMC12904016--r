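#' Construct a genome reference from named contig sequences
#'
#' A `GenomeRef` is a named set of contig sequences. Contig names must be
#' unique, sequences non-empty, and the alphabet restricted to IUPAC DNA
#' (in practice A/C/G/T/N for the toy genomes used here).
#'
#' @param contigs named character vector or named list of DNA strings.
#' @return an object of class `GenomeRef`.
#' @export
#' @examples
#' g <- genome_ref(c(chr1 = "ACGTACGTAA"))
genome_ref <- function(contigs) {
  contigs <- vapply(contigs, toupper, character(1))
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs)))) {
    stop("GenomeRef: contig names must be present and unique", call. = FALSE)
  }
  if (any(!nzchar(contigs))) stop("GenomeRef: empty contig sequence", call. = FALSE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", contigs)
  if (any(bad)) {
    stop("GenomeRef: non-IUPAC characters in contig(s): ",
         paste(names(contigs)[bad], collapse = ", "), call. = FALSE)
  }
  structure(as.list(contigs), class = "GenomeRef")
}

#' @export
print.GenomeRef <- function(x, ...) {
  cat("<GenomeRef> ", length(x), " contig(s): ",
      paste(sprintf("%s (%d nt)", names(x), nchar(unlist(x))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    stop("contig not in genome: ", contig, call. = FALSE)
  }
  genome[[contig]]
}

#' Define a transcript model
#'
#' Exons are genomic intervals, 1-based inclusive, non-overlapping. They may
#' be supplied in any order; they are stored sorted 5'->3' in transcript
#' orientation (ascending start for `+`, descending for `-`). `cds_start` is
#' the genomic position of the first base of the start codon and `cds_end`
#' the genomic position of the last base of the stop codon (so for `-`
#' strand transcripts `cds_start > cds_end` numerically). The CDS span
#' includes the stop codon; the derived `protein_length` excludes it.
#'
#' @param transcript_id,gene identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 1-based
#'   inclusive).
#' @param cds_start,cds_end genomic coordinates of translation start/stop.
#' @return an unvalidated `TranscriptModel`; pass through [build_transcript()]
#'   to derive sequences and check invariants.
#' @export
transcript_model <- function(transcript_id, gene, contig, strand, exons,
                             cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) stop("TranscriptModel: need >= 1 exon", call. = FALSE)
  if (any(exons$end < exons$start)) {
    stop("TranscriptModel: exon end < start", call. = FALSE)
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("TranscriptModel: overlapping exons", call. = FALSE)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(
    transcript_id = transcript_id, gene = gene, contig = contig,
    strand = strand, exons = exons,
    cds_start = cds_start, cds_end = cds_end
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("<TranscriptModel> %s (%s) %s:%s strand %s, %d exon(s)",
              x$transcript_id, x$gene, x$contig,
              paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand, nrow(x$exons)))
  if (!is.null(x$protein)) {
    cat(sprintf(", protein %d aa", x$protein_length))
  }
  cat("\n")
  invisible(x)
}

n_exons <- function(t) nrow(t$exons)

exon_lengths <- function(t) t$exons$end - t$exons$start + 1L

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## exon sequences in transcript orientation (already reverse-complemented
## for minus-strand transcripts)
exon_seqs <- function(genome, t) {
  seq <- contig_seq(genome, t$contig)
  out <- character(n_exons(t))
  for (i in seq_len(n_exons(t))) {
    s <- substr(seq, t$exons$start[i], t$exons$end[i])
    out[i] <- if (t$strand == "-") revcomp(s) else s
  }
  out
}

## intron i lies between exon i and exon i+1 in transcript orientation;
## returned in transcript orientation
intron_seq <- function(genome, t, i) {
  if (i < 1L || i >= n_exons(t)) stop("no intron ", i, call. = FALSE)
  seq <- contig_seq(genome, t$contig)
  if (t$strand == "+") {
    substr(seq, t$exons$end[i] + 1L, t$exons$start[i + 1L] - 1L)
  } else {
    revcomp(substr(seq, t$exons$end[i + 1L] + 1L, t$exons$start[i] - 1L))
  }
}

intron_length <- function(t, i) {
  if (t$strand == "+") {
    t$exons$start[i + 1L] - t$exons$end[i] - 1L
  } else {
    t$exons$start[i] - t$exons$end[i + 1L] - 1L
  }
}

## genomic position -> transcript (mRNA) coordinate, NA if intronic/outside
g_to_t <- function(t, gpos) {
  lens <- exon_lengths(t)
  off <- cumsum(c(0L, lens))[seq_len(n_exons(t))]
  for (i in seq_len(n_exons(t))) {
    if (gpos >= t$exons$start[i] && gpos <= t$exons$end[i]) {
      within <- if (t$strand == "+") gpos - t$exons$start[i] else t$exons$end[i] - gpos
      return(off[i] + within + 1L)
    }
  }
  NA_integer_
}

t_to_g <- function(t, tpos) {
  lens <- exon_lengths(t)
  ends <- cumsum(lens)
  i <- which(tpos <= ends)[1L]
  if (is.na(i) || tpos < 1L) stop("transcript position out of range: ", tpos, call. = FALSE)
  within <- tpos - c(0L, ends)[i] - 1L
  if (t$strand == "+") t$exons$start[i] + within else t$exons$end[i] - within
}

#' Translate a coding sequence
#'
#' Translation uses the standard genetic code and stops at the first stop
#' codon; whether a stop was reached is reported. Trailing bases that do not
#' fill a codon are ignored.
#'
#' @param cds DNA string, length >= 3.
#' @return list with `protein` (residues up to but excluding the stop) and
#'   `stop_found` (logical).
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK", stop found
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("translate_cds: need length >= 3", call. = FALSE)
  if (grepl("[^ACGT]", cds)) {
    stop("translate_cds: non-ACGT character in CDS", call. = FALSE)
  }
  n <- 3L * (nchar(cds) %/% 3L)
  ## no.init.codon: translate literally (no alternative-initiator M)
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                          no.init.codon = TRUE)
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at - 1L), stop_found = TRUE)
  } else {
    list(protein = aa, stop_found = FALSE)
  }
}

#' Derive mRNA, CDS and protein for a transcript model
#'
#' Concatenates the exon sequences in transcript orientation (reverse
#' complemented for `-` strand), locates the CDS span, translates it and
#' verifies the model invariants: CDS length divisible by 3, translation
#' starting with M, no internal stop, a terminal stop codon, and no N/IUPAC
#' ambiguity inside the CDS.
#'
#' @param genome a [genome_ref()].
#' @param model a [transcript_model()].
#' @return the model with derived fields `mrna`, `cds`, `protein`,
#'   `cds_offset` (position of the first CDS base in the mRNA),
#'   `protein_length`.
#' @export
build_transcript <- function(genome, model) {
  t <- model
  seqlen <- nchar(contig_seq(genome, t$contig))
  if (min(t$exons$start) < 1L || max(t$exons$end) > seqlen) {
    stop("build_transcript: exons outside contig bounds", call. = FALSE)
  }
  seqs <- exon_seqs(genome, t)
  mrna <- paste(seqs, collapse = "")
  c1 <- g_to_t(t, t$cds_start)
  c2 <- g_to_t(t, t$cds_end)
  if (is.na(c1) || is.na(c2) || c2 <= c1) {
    stop("build_transcript: CDS boundaries not within exon union", call. = FALSE)
  }
  cds <- substr(mrna, c1, c2)
  if (nchar(cds) %% 3L != 0L) {
    stop("build_transcript: CDS length not divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("build_transcript: ambiguous base inside CDS", call. = FALSE)
  }
  tr <- translate_cds(cds)
  if (!tr$stop_found || nchar(tr$protein) != nchar(cds) / 3L - 1L) {
    if (tr$stop_found) {
      stop("build_transcript: internal stop codon in CDS", call. = FALSE)
    }
    stop("build_transcript: CDS does not end with a stop codon", call. = FALSE)
  }
  if (substr(tr$protein, 1L, 1L) != "M") {
    stop("build_transcript: CDS does not begin with a start codon (M)", call. = FALSE)
  }
  t$mrna <- mrna
  t$cds <- cds
  t$cds_offset <- c1
  t$protein <- tr$protein
  t$protein_length <- nchar(tr$protein)
  t
}

#' A cDNA (HGVS-c style) position
#'
#' `base` is the 1-based coding-sequence offset (the base of `c.N`);
#' `offset` is 0 for exonic positions, positive for intronic positions
#' anchored to the upstream exon's last base (after a donor), negative for
#' intronic positions anchored to the downstream exon's first base (before
#' an acceptor). `region` distinguishes coding, UTR and intronic positions.
#'
#' @param base integer coding offset.
#' @param offset signed intron offset (0 if exonic).
#' @param region one of `"cds"`, `"utr5"`, `"utr3"`, `"intron"`.
#' @return object of class `CdnaPosition`.
#' @export
cdna_position <- function(base, offset = 0L, region = if (offset == 0L) "cds" else "intron") {
  structure(list(base = as.integer(base), offset = as.integer(offset),
                 region = region), class = "CdnaPosition")
}

#' @export
print.CdnaPosition <- function(x, ...) {
  cat("<CdnaPosition> ", format_hgvs_c(x), " (", x$region, ")\n", sep = "")
  invisible(x)
}

#' Map a genomic position to cDNA (HGVS-c) coordinates
#'
#' Exonic positions return `offset = 0`. Intronic positions anchor to the
#' nearest junction per HGVS convention: the first half of an intron anchors
#' to the last base of the upstream exon (`c.N+k`), the second half to the
#' first base of the downstream exon (`c.N-k`); the exact midpoint of an
#' even-length intron anchors to the donor. Positions in the UTRs are
#' flagged (`region` `"utr5"`/`"utr3"`) with `base` holding the signed
#' distance from the CDS (negative before `c.1`, `protein*3+3+k` style
#' offsets are not emitted; see Details).
#'
#' @details UTR positions are reported with `base` equal to the CDS-relative
#' offset (0 or negative for the 5' UTR; beyond the stop for the 3' UTR) so
#' they round-trip through [map_c_to_g()], but no `c.-N`/`c.*N` HGVS string
#' is generated for them.
#'
#' @param t a built [transcript_model()].
#' @param gpos genomic position (1-based) on the transcript's contig.
#' @return a [cdna_position()].
#' @export
map_g_to_c <- function(t, gpos) {
  stopifnot(!is.null(t$cds_offset))
  span_lo <- min(t$exons$start)
  span_hi <- max(t$exons$end)
  if (gpos < span_lo || gpos > span_hi) {
    stop("map_g_to_c: position outside transcript span: ", gpos, call. = FALSE)
  }
  tpos <- g_to_t(t, gpos)
  cds_len <- nchar(t$cds)
  if (!is.na(tpos)) {
    base <- tpos - t$cds_offset + 1L
    region <- if (base < 1L) "utr5" else if (base > cds_len) "utr3" else "cds"
    return(cdna_position(base, 0L, region))
  }
  ## intronic: find the flanking intron in transcript orientation
  for (i in seq_len(n_exons(t) - 1L)) {
    lo <- min(t$exons$end[i], t$exons$start[i + 1L])
    hi <- max(t$exons$end[i], t$exons$start[i + 1L])
    if (gpos > lo && gpos < hi) {
      don_g <- if (t$strand == "+") t$exons$end[i] else t$exons$start[i]
      acc_g <- if (t$strand == "+") t$exons$start[i + 1L] else t$exons$end[i + 1L]
      d_don <- abs(gpos - don_g)            # distance into intron from donor
      d_acc <- abs(acc_g - gpos)            # distance from acceptor
      don_t <- g_to_t(t, don_g) - t$cds_offset + 1L
      acc_t <- g_to_t(t, acc_g) - t$cds_offset + 1L
      if (d_don <= d_acc) {
        region <- if (don_t < 1L) "utr5" else if (don_t > cds_len) "utr3" else "intron"
        return(cdna_position(don_t, d_don, region))
      } else {
        region <- if (acc_t < 1L) "utr5" else if (acc_t > cds_len) "utr3" else "intron"
        return(cdna_position(acc_t, -d_acc, region))
      }
    }
  }
  stop("map_g_to_c: position not locatable: ", gpos, call. = FALSE)
}

#' Map a cDNA (HGVS-c) position to a genomic position
#'
#' Inverse of [map_g_to_c()] on its full valid domain.
#'
#' @param t a built [transcript_model()].
#' @param cpos a [cdna_position()], or an integer coding offset.
#' @param offset intron offset if `cpos` is given as a plain integer.
#' @return genomic position (1-based).
#' @export
map_c_to_g <- function(t, cpos, offset = 0L) {
  if (inherits(cpos, "CdnaPosition")) {
    base <- cpos$base; offset <- cpos$offset
  } else {
    base <- as.integer(cpos)
  }
  tpos <- base + t$cds_offset - 1L
  anchor_g <- t_to_g(t, tpos)
  if (offset == 0L) return(anchor_g)
  dirn <- if (t$strand == "+") 1L else -1L
  anchor_g + dirn * offset
}

#' Format a cDNA position as an HGVS-c string
#'
#' @param cpos a [cdna_position()].
#' @param ref,alt optional alleles (transcript strand) to append, giving
#'   e.g. `"c.2859+4A>G"`.
#' @return character scalar.
#' @export
format_hgvs_c <- function(cpos, ref = NULL, alt = NULL) {
  off <- if (cpos$offset > 0L) paste0("+", cpos$offset)
         else if (cpos$offset < 0L) as.character(cpos$offset)
         else ""
  s <- paste0("c.", cpos$base, off)
  if (!is.null(ref) && !is.null(alt)) s <- paste0(s, ref, ">", alt)
  s
}

#' Parse an HGVS-c substitution string
#'
#' Accepts forms like `"c.2859+4A>G"`, `"c.634-8T>A"`, `"c.265A>T"`.
#' Unicode hyphen/minus variants are normalized. Whitespace is ignored.
#'
#' @param x character scalar.
#' @return list with `base`, `offset`, `ref`, `alt` (alleles `NA` if absent).
#' @export
parse_hgvs_c <- function(x) {
  s <- gsub("‐|‒|–|—|−", "-", x)
  s <- gsub("[[:space:]]", "", s)
  m <- regmatches(s, regexec(
    "^c\\.(\\d+)([+-]\\d+)?(?:([ACGT]+)>([ACGT]+))?$", s))[[1]]
  if (length(m) == 0L) stop("cannot parse HGVS-c: ", x, call. = FALSE)
  list(base = as.integer(m[2]),
       offset = if (nzchar(m[3])) as.integer(m[3]) else 0L,
       ref = if (nzchar(m[4])) m[4] else NA_character_,
       alt = if (nzchar(m[5])) m[5] else NA_character_)
}
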