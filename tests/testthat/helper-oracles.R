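## independent oracles used across the suite; deliberately written with
## different primitives than the package implementation

## hand-written standard genetic code
CODON_ORACLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  out <- character(0)
  stop_found <- FALSE
  for (i in seq_len(n)) {
    aa <- CODON_ORACLE[[substr(cds, 3L * i - 2L, 3L * i)]]
    if (aa == "*") { stop_found <- TRUE; break }
    out <- c(out, aa)
  }
  list(protein = paste(out, collapse = ""), stop_found = stop_found)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## splice a transcript by hand from its stored coordinates and translate
oracle_spliced_protein <- function(genome, t) {
  seqc <- genome[[t$contig]]
  ex <- t$exons[order(t$exons$start), , drop = FALSE]
  mrna <- paste(substring(seqc, ex$start, ex$end), collapse = "")
  if (t$strand == "-") mrna <- oracle_revcomp(mrna)
  ## locate CDS start within the spliced mRNA by walking the exon list
  g_offset <- function(g) {
    tot <- 0L
    exo <- if (t$strand == "+") ex else ex[rev(seq_len(nrow(ex))), ]
    for (i in seq_len(nrow(exo))) {
      if (g >= exo$start[i] && g <= exo$end[i]) {
        w <- if (t$strand == "+") g - exo$start[i] else exo$end[i] - g
        return(tot + w + 1L)
      }
      tot <- tot + exo$end[i] - exo$start[i] + 1L
    }
    stop("position not exonic")
  }
  c1 <- g_offset(t$cds_start); c2 <- g_offset(t$cds_end)
  oracle_translate(substr(mrna, c1, c2))$protein
}

## two-sided Fisher p by direct enumeration over tables with fixed margins,
## probabilities from log-factorials (not dhyper)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  logp <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  }
  xs <- max(0, c1 - r2):min(c1, r1)
  ps <- exp(vapply(xs, logp, numeric(1)))
  sum(ps[ps <= exp(logp(a)) * (1 + 1e-7)])
}

## percentage at 2 dp, half-up, in exact integer arithmetic
oracle_pct2 <- function(num, den) {
  floor((10000 * num) / den + 0.5) / 100
}

## tiny 3-exon gene whose CDS "ATGAAATAA" is split across the exons;
## returns a built transcript plus its genome
make_tiny_tx <- function(strand = "+") {
  ex <- c("CCATGA", "AAT", "AAGG")        # exon1 has 2 nt 5'UTR, exon3 2 nt 3'UTR
  introns <- c("GTAAGCATAG", "GTTTTCCAAG")
  premrna <- paste0(ex[1], introns[1], ex[2], introns[2], ex[3])
  pad <- "ACGTA"
  if (strand == "+") {
    contig <- paste0(pad, premrna, pad)
    off <- nchar(pad)
    s1 <- off + 1L
    e1 <- off + nchar(ex[1])
    s2 <- e1 + nchar(introns[1]) + 1L
    e2 <- s2 + nchar(ex[2]) - 1L
    s3 <- e2 + nchar(introns[2]) + 1L
    e3 <- s3 + nchar(ex[3]) - 1L
    exons <- data.frame(start = c(s1, s2, s3), end = c(e1, e2, e3))
    cds_start <- s1 + 2L                  # the A of ATG
    cds_end <- e3 - 2L                    # last base of TAA
  } else {
    L <- nchar(premrna)
    contig <- paste0(pad, oracle_revcomp(premrna), pad)
    off <- nchar(pad)
    flip <- function(p) off + L - p + 1L
    s1 <- 1L; e1 <- nchar(ex[1])
    s2 <- e1 + nchar(introns[1]) + 1L; e2 <- s2 + nchar(ex[2]) - 1L
    s3 <- e2 + nchar(introns[2]) + 1L; e3 <- s3 + nchar(ex[3]) - 1L
    exons <- data.frame(start = flip(c(e1, e2, e3)), end = flip(c(s1, s2, s3)))
    cds_start <- flip(s1 + 2L)
    cds_end <- flip(e3 - 2L)
  }
  genome <- genome_ref(setNames(contig, "toy"))
  t <- build_transcript(genome, transcript_model(
    "TOY1", "TOYGENE", "toy", strand, exons, cds_start, cds_end))
  list(genome = genome, t = t)
}

## catalog rows usable for golden consequence checks
golden_rows <- function() {
  cat_df <- ncsv_catalog()
  cat_df[cat_df$count_ok | cat_df$pct_ok, ]
}

## cohort genotype fixture joined with catalog scores, in the
## inheritance_screen() column contract
cohort_calls_fixture <- function() {
  g <- ncsv_cohort_genotypes()
  cat_df <- ncsv_catalog()
  idx <- match(g$position, cat_df$position)
  cls <- c(Mis = "missense", Syn = "synonymous", Intron = "intronic",
           Stopgain = "stop_gain")
  data.frame(
    patient_id = g$patient_id, sex = "male",
    contig = sub(":.*$", "", g$position), gene = g$gene,
    variant_key = g$position,
    consequence_class = unname(cls[g$type]),
    zygosity = tolower(g$genotype),
    spliceai = cat_df$spliceai[idx], spcards = cat_df$spcards[idx],
    af_1kgp = g$af_1kgp, af_gnomad = g$af_gnomad_eas,
    sift = g$sift, pp2 = g$pp2, mt = g$mt, cadd = g$cadd,
    stringsAsFactors = FALSE)
}
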