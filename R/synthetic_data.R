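## seeded evaluation that restores the caller's RNG state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## safe single draw from a vector (avoids sample()'s 1:n surprise)
pick1 <- function(x) x[sample.int(length(x), 1L)]

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                              c("A","C","G","T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

## random CDS of `n_res` residues plus a stop codon, start codon ATG,
## no internal stop by construction
random_cds <- function(n_res) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_res - 1L, replace = TRUE), collapse = ""),
         pick1(STOP_CODONS))
}

random_intron <- function(n) {
  stopifnot(n >= 4L)
  paste0("GT", random_dna(n - 4L), "AG")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around: a
#' latent score correlation of 0.83 between the supporting-method count and
#' the SpliceAI-like score, 70% of spiked variants placed inside splicing
#' consensus windows, and a 34-patient screening cohort carrying 7
#' homozygous, 9 compound-heterozygous and 1 hemizygous planted
#' configuration (the remaining patients are decoys).
#'
#' @param seed integer seed; all generator functions are deterministic
#'   given the config.
#' @param n_transcripts number of toy transcripts (one per contig; the last
#'   is placed on contig `"chrX"`).
#' @param exon_count_range,exon_length_range,intron_length_range,utr_length_range
#'   integer ranges for transcript geometry (nt; exon lengths apply to the
#'   mRNA split).
#' @param protein_length_range residues per toy protein.
#' @param n_variants catalog size for score generation.
#' @param spike_fraction fraction of catalog variants that are
#'   splice-altering spikes.
#' @param rho latent Gaussian-copula correlation between the two scores.
#' @param spike_mean,decoy_mean latent mean shifts for spiked/decoy
#'   variants (probit scale).
#' @param consensus_placement fraction of spiked variants placed inside
#'   consensus windows.
#' @param af_common_rate,af_common fraction of variants given a common
#'   allele frequency, and that frequency (exercises the 0.01 filter).
#' @param cohort_size,n_hom,n_comphet,n_hemi cohort composition; remaining
#'   patients are decoys (lone heterozygotes, common-frequency variants,
#'   cis pairs).
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_transcripts = 12L,
                       exon_count_range = c(4L, 7L),
                       exon_length_range = c(40L, 200L),
                       intron_length_range = c(60L, 300L),
                       utr_length_range = c(12L, 60L),
                       protein_length_range = c(120L, 400L),
                       n_variants = 2000L, spike_fraction = 0.3,
                       rho = 0.83, spike_mean = 1.8, decoy_mean = -1.5,
                       consensus_placement = 0.7,
                       af_common_rate = 0.05, af_common = 0.05,
                       cohort_size = 34L, n_hom = 7L, n_comphet = 9L,
                       n_hemi = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$rho >= -1, cfg$rho <= 1,
            cfg$n_hom + cfg$n_comphet + cfg$n_hemi <= cfg$cohort_size,
            all(unlist(cfg[grep("_range$", names(cfg))]) > 0))
  structure(cfg, class = "SimulationConfig")
}

## build one transcript (+ its contig sequence) from explicit geometry:
## mRNA pieces are exon sequences in transcript orientation
assemble_transcript <- function(id, gene, contig, strand, exon_seq_list,
                                intron_seqs, utr5_len, pad = 25L) {
  k <- length(exon_seq_list)
  stopifnot(length(intron_seqs) == k - 1L)
  pre <- character(0)
  bounds <- matrix(0L, nrow = k, ncol = 2L)
  pos <- 0L
  for (i in seq_len(k)) {
    pre <- c(pre, exon_seq_list[[i]])
    bounds[i, ] <- c(pos + 1L, pos + nchar(exon_seq_list[[i]]))
    pos <- pos + nchar(exon_seq_list[[i]])
    if (i < k) {
      pre <- c(pre, intron_seqs[[i]])
      pos <- pos + nchar(intron_seqs[[i]])
    }
  }
  premrna <- paste(pre, collapse = "")
  L <- nchar(premrna)
  pad5 <- random_dna(pad); pad3 <- random_dna(pad)
  mrna_len <- sum(nchar(unlist(exon_seq_list)))
  cds_t1 <- utr5_len + 1L                       # mRNA coord of CDS start
  cds_t2 <- mrna_len - attr(exon_seq_list, "utr3_len")
  ## mRNA coord -> pre-mRNA coord
  m2p <- function(m) {
    cum <- 0L
    for (i in seq_len(k)) {
      w <- bounds[i, 2L] - bounds[i, 1L] + 1L
      if (m <= cum + w) return(bounds[i, 1L] + (m - cum - 1L))
      cum <- cum + w
    }
    stop("mRNA coord out of range")
  }
  if (strand == "+") {
    contig_seq <- paste0(pad5, premrna, pad3)
    g <- function(p) pad + p
    exons <- data.frame(start = g(bounds[, 1L]), end = g(bounds[, 2L]))
    cds_start <- g(m2p(cds_t1)); cds_end <- g(m2p(cds_t2))
  } else {
    contig_seq <- paste0(pad5, revcomp(premrna), pad3)
    g <- function(p) pad + L - p + 1L
    exons <- data.frame(start = g(bounds[, 2L]), end = g(bounds[, 1L]))
    cds_start <- g(m2p(cds_t1)); cds_end <- g(m2p(cds_t2))
  }
  list(contig_seq = contig_seq,
       model = transcript_model(id, gene, contig, strand, exons,
                                cds_start, cds_end))
}

## split total mRNA length M into k exon pieces, each >= min_len
split_lengths <- function(M, k, min_len) {
  if (M < k * min_len) stop("sim: mRNA too short for requested exon count",
                            call. = FALSE)
  extra <- M - k * min_len
  if (extra == 0L) return(rep(min_len, k))
  cuts <- sort(sample.int(extra + k - 1L, k - 1L))
  d <- diff(c(0L, cuts, extra + k)) - 1L
  min_len + d
}

#' Generate a toy transcriptome with a genome reference
#'
#' Every transcript has a valid open reading frame (start codon, no
#' internal stop, terminal stop), multi-exon structure with GT..AG introns,
#' 5'/3' UTRs, a random strand, and its own contig; the last transcript is
#' placed on contig `"chrX"` so hemizygous genotypes can be simulated.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a [genome_ref()]) and `transcripts`
#'   (list of built [transcript_model()]s).
#' @export
sim_transcriptome <- function(cfg = sim_config()) {
  with_rng(cfg$seed, {
    contig_seqs <- list()
    transcripts <- list()
    for (ti in seq_len(cfg$n_transcripts)) {
      k <- pick1(cfg$exon_count_range[1]:cfg$exon_count_range[2])
      n_res <- pick1(cfg$protein_length_range[1]:cfg$protein_length_range[2])
      u5 <- pick1(cfg$utr_length_range[1]:cfg$utr_length_range[2])
      u3 <- pick1(cfg$utr_length_range[1]:cfg$utr_length_range[2])
      mrna <- paste0(random_dna(u5), random_cds(n_res), random_dna(u3))
      lens <- split_lengths(nchar(mrna), k, cfg$exon_length_range[1])
      stops <- cumsum(lens)
      pieces <- substring(mrna, c(1L, stops[-k] + 1L), stops)
      pieces <- as.list(pieces)
      attr(pieces, "utr3_len") <- u3
      introns <- replicate(k - 1L, random_intron(
        pick1(cfg$intron_length_range[1]:cfg$intron_length_range[2])),
        simplify = FALSE)
      contig <- if (ti == cfg$n_transcripts) "chrX" else paste0("chr", ti)
      strand <- sample(c("+", "-"), 1L)
      asm <- assemble_transcript(sprintf("TX%03d", ti), sprintf("GENE%03d", ti),
                                 contig, strand, pieces, introns, u5)
      contig_seqs[[contig]] <- asm$contig_seq
      transcripts[[asm$model$transcript_id]] <- asm$model
    }
    genome <- genome_ref(unlist(contig_seqs))
    transcripts <- lapply(transcripts, function(m) build_transcript(genome, m))
    list(genome = genome, transcripts = transcripts)
  })
}

## ---- independent truth oracle (string surgery on the exon list) ---------

## alternate mRNA built by list surgery: drop/trim exon entries, insert
## retained intron pieces; deliberately a different route from apply_event's
## coordinate arithmetic on the concatenated mRNA
truth_alt_mrna <- function(genome, t, events) {
  if (inherits(events, "SpliceEvent")) events <- list(events)
  ex <- exon_seqs(genome, t)
  retained <- vector("list", length(ex))   # retained[[i]] follows exon i
  for (e in events) {
    i <- e$element_index
    if (e$event_type == "exon_skipping") {
      ex[i] <- ""
    } else if (e$event_type == "partial_exon_deletion") {
      a <- e$sub_interval[1]; b <- e$sub_interval[2]
      ex[i] <- paste0(substr(ex[i], 1L, a - 1L),
                      substr(ex[i], b + 1L, nchar(ex[i])))
    } else {
      iseq <- intron_seq(genome, t, i)
      sub <- if (is.null(e$sub_interval)) c(1L, nchar(iseq)) else e$sub_interval
      retained[[i]] <- substr(iseq, sub[1], sub[2])
    }
  }
  out <- character(0)
  for (i in seq_along(ex)) {
    out <- c(out, ex[i])
    if (!is.null(retained[[i]])) out <- c(out, retained[[i]])
  }
  paste(out, collapse = "")
}

## position of the original CDS start in the oracle's alternate mRNA:
## count surviving mRNA bases 5' of the start codon
truth_cds_start <- function(genome, t, events) {
  if (inherits(events, "SpliceEvent")) events <- list(events)
  lens <- exon_lengths(t)
  before <- t$cds_offset - 1L            # original mRNA bases before CDS
  starts <- cumsum(c(0L, lens)) + 1L
  shift <- 0L
  lost <- FALSE
  for (e in events) {
    i <- e$element_index
    if (e$event_type == "exon_skipping") {
      a <- starts[i]; b <- starts[i] + lens[i] - 1L
    } else if (e$event_type == "partial_exon_deletion") {
      a <- starts[i] + e$sub_interval[1] - 1L
      b <- starts[i] + e$sub_interval[2] - 1L
    } else {
      iseq_len <- if (is.null(e$sub_interval)) intron_length(t, i)
                  else e$sub_interval[2] - e$sub_interval[1] + 1L
      if (starts[i + 1L] - 1L <= before) shift <- shift + iseq_len
      next
    }
    if (b <= before) shift <- shift - (b - a + 1L)
    else if (a <= before + 3L) lost <- TRUE
  }
  if (lost) NA_integer_ else before + 1L + shift
}

## naive residue-by-residue comparison; quadratic-safe simple loops
truth_consequence <- function(ref_protein, alt_cds,
                              frame_ref_len = 3L * (nchar(ref_protein) + 1L)) {
  tr <- translate_cds(alt_cds)
  ref <- strsplit(ref_protein, "")[[1]]
  alt <- strsplit(tr$protein, "")[[1]]
  lr <- length(ref); la <- length(alt)
  p <- 0L
  while (p < min(lr, la) && ref[p + 1L] == alt[p + 1L]) p <- p + 1L
  if (!tr$stop_found) {
    return(list(kind = "frameshift", fs_first_res = p + 1L,
                fraction = (lr - p - 1L) / lr, count = lr - p - 1L,
                no_stop_found = TRUE))
  }
  if (la == lr && p == lr) {
    return(list(kind = "none", count = 0L, fraction = 0))
  }
  if (p == la) {
    return(list(kind = "stop_gain", fs_first_res = p + 1L,
                count = lr - p - 1L, fraction = (lr - p - 1L) / lr))
  }
  if ((nchar(alt_cds) - frame_ref_len) %% 3L != 0L) {
    return(list(kind = "frameshift", fs_first_res = p + 1L,
                fs_stop_offset = la - p + 1L,
                count = lr - p - 1L, fraction = (lr - p - 1L) / lr,
                no_stop_found = FALSE))
  }
  s <- 0L
  while (s < min(lr, la) - p && ref[lr - s] == alt[la - s]) s <- s + 1L
  if (p + s == la) {
    list(kind = "inframe_deletion", start_res = p + 1L, end_res = lr - s,
         count = lr - la, fraction = (lr - la) / lr)
  } else if (p + s == lr) {
    list(kind = "inframe_insertion", start_res = p, end_res = p + 1L,
         inserted = paste(alt[(p + 1L):(la - s)], collapse = ""),
         count = la - lr, fraction = (la - lr) / lr)
  } else {
    list(kind = "inframe_delins", start_res = p + 1L, end_res = lr - s,
         inserted = paste(alt[(p + 1L):(la - s)], collapse = ""),
         count = (lr - s) - p, fraction = ((lr - s) - p) / lr)
  }
}

## full oracle: event(s) -> expected consequence for a transcript
truth_for_events <- function(genome, t, events) {
  start <- truth_cds_start(genome, t, events)
  alt_mrna <- truth_alt_mrna(genome, t, events)
  if (is.na(start) || start + 2L > nchar(alt_mrna)) {
    return(list(kind = "cds_lost"))
  }
  truth_consequence(t$protein, substr(alt_mrna, start, nchar(alt_mrna)),
                    frame_ref_len = nchar(t$mrna) - t$cds_offset + 1L)
}

## -------------------------------------------------------------------------

## pick a variant position near the junctions of the spiked element;
## in_consensus with probability cfg$consensus_placement
spike_variant_pos <- function(t, e, in_consensus) {
  k <- n_exons(t)
  i <- e$element_index
  intronic <- runif(1) < 0.5
  if (e$event_type == "intron_retention") {
    don_g <- if (t$strand == "+") t$exons$end[i] else t$exons$start[i]
    dirn <- if (t$strand == "+") 1L else -1L
    off <- if (in_consensus) pick1(3:8) else
      pick1(9:max(9L, min(20L, intron_length(t, i) - 3L)))
    if (intronic) return(don_g + dirn * off)
    return(don_g - dirn * pick1(0:2))    # exonic, near the donor
  }
  ## exon events: place near the exon's acceptor or donor junction
  donor_side <- runif(1) < 0.5 && i < k
  if (!donor_side && i == 1L) donor_side <- TRUE
  if (donor_side) {
    don_g <- if (t$strand == "+") t$exons$end[i] else t$exons$start[i]
    dirn <- if (t$strand == "+") 1L else -1L
    if (intronic) {
      off <- if (in_consensus) pick1(3:8) else
        pick1(9:max(9L, min(20L, intron_length(t, i) - 3L)))
      don_g + dirn * off
    } else {
      off <- if (in_consensus) pick1(1:3) else
        pick1(4:max(4L, min(15L, exon_lengths(t)[i] - 2L)))
      don_g - dirn * (off - 1L)
    }
  } else {
    acc_g <- if (t$strand == "+") t$exons$start[i] else t$exons$end[i]
    dirn <- if (t$strand == "+") 1L else -1L
    if (intronic) {
      off <- if (in_consensus) pick1(3:12) else
        pick1(13:max(13L, min(25L, intron_length(t, i - 1L) - 3L)))
      acc_g - dirn * off
    } else {
      off <- if (in_consensus) pick1(1:2) else
        pick1(3:max(3L, min(15L, exon_lengths(t)[i] - 2L)))
      acc_g + dirn * (off - 1L)
    }
  }
}

random_event <- function(t, type = NULL) {
  k <- n_exons(t)
  stopifnot(k >= 4L)
  if (is.null(type)) {
    type <- pick1(c("exon_skipping", "partial_exon_deletion",
                     "intron_retention"))
  }
  if (type == "exon_skipping") {
    splice_event(type, pick1(2:(k - 2L)))
  } else if (type == "partial_exon_deletion") {
    i <- pick1(2:(k - 2L))
    len <- exon_lengths(t)[i]
    w <- pick1(2:max(2L, min(60L, len - 2L)))
    if (runif(1) < 0.5) splice_event(type, i, c(1L, w))            # cryptic acceptor
    else splice_event(type, i, c(len - w + 1L, len))               # cryptic donor
  } else {
    i <- pick1(2:(k - 2L))
    ilen <- intron_length(t, i)
    u <- runif(1)
    if (u < 1 / 3) splice_event(type, i)                            # full retention
    else {
      w <- pick1(2:max(2L, min(90L, ilen - 2L)))
      if (u < 2 / 3) splice_event(type, i, c(1L, w))
      else splice_event(type, i, c(ilen - w + 1L, ilen))
    }
  }
}

#' Spike splice-altering variants with known protein truth
#'
#' For each spike a transcript and an aberrant-splicing event are drawn, a
#' variant is placed at a junction-proximal position consistent with the
#' event (inside the consensus window for `cfg$consensus_placement` of the
#' spikes), and the true edited protein consequence is computed with an
#' independent string-surgery oracle and stored as the truth record. Only
#' internal exons/introns that do not touch the start or stop codon are
#' spiked, so every truth record has a defined consequence.
#'
#' @param tx output of [sim_transcriptome()].
#' @param cfg a [sim_config()].
#' @param n_spikes number of spikes (default
#'   `round(cfg$n_variants * cfg$spike_fraction)`).
#' @return data.frame of spiked variants (one row per spike) with columns
#'   `variant_key`, `transcript_id`, `gene`, `contig`, `pos`, `ref`, `alt`,
#'   `region`, `event_type`, `element_index`, `sub_start`, `sub_end`,
#'   `truth_kind`, `truth_count`, `truth_fraction`, `truth_first_res`;
#'   the `SpliceEvent` list is attached as attribute `"events"`.
#' @export
sim_spike_events <- function(tx, cfg = sim_config(),
                             n_spikes = round(cfg$n_variants * cfg$spike_fraction)) {
  with_rng(cfg$seed + 1L, {
    rows <- list(); events <- list()
    eligible <- Filter(function(t) n_exons(t) >= 4L, tx$transcripts)
    stopifnot(length(eligible) > 0L)
    for (s in seq_len(n_spikes)) {
      repeat {
        t <- eligible[[sample.int(length(eligible), 1L)]]
        e <- random_event(t)
        tr <- truth_for_events(tx$genome, t, e)
        if (tr$kind != "cds_lost" && tr$kind != "none") break
      }
      in_cons <- runif(1) < cfg$consensus_placement
      pos <- spike_variant_pos(t, e, in_cons)
      seqc <- contig_seq(tx$genome, t$contig)
      ref <- substr(seqc, pos, pos)
      alt <- pick1(setdiff(c("A", "C", "G", "T"), ref))
      cp <- map_g_to_c(t, pos)
      rows[[s]] <- data.frame(
        variant_key = sprintf("%s:%d:%s:%s", t$contig, pos, ref, alt),
        transcript_id = t$transcript_id, gene = t$gene, contig = t$contig,
        pos = pos, ref = ref, alt = alt,
        region = if (cp$offset == 0L) "exonic" else "intronic",
        event_type = e$event_type, element_index = e$element_index,
        sub_start = if (is.null(e$sub_interval)) NA_integer_ else e$sub_interval[1],
        sub_end = if (is.null(e$sub_interval)) NA_integer_ else e$sub_interval[2],
        truth_kind = tr$kind,
        truth_count = if (is.null(tr$count)) NA_integer_ else tr$count,
        truth_fraction = if (is.null(tr$fraction)) NA_real_ else tr$fraction,
        truth_first_res = if (!is.null(tr$fs_first_res)) tr$fs_first_res
                          else if (!is.null(tr$start_res)) tr$start_res
                          else NA_integer_,
        stringsAsFactors = FALSE)
      events[[s]] <- e
    }
    out <- do.call(rbind, rows)
    attr(out, "events") <- events
    out
  })
}

#' Generate correlated splicing prediction scores
#'
#' Scores are drawn from a Gaussian copula: a latent bivariate normal with
#' correlation `rho` and a mean shift for spiked variants; the SpliceAI-like
#' score is the probit transform of one coordinate and the
#' supporting-method count is `round(18 * pnorm(z))` of the other, clipped
#' to 0..18. For a homogeneous draw the empirical Pearson correlation of
#' the transformed scores is within 0.05 of `rho` at n >= 2000.
#'
#' @param spiked logical vector; `TRUE` rows get the spiked mean shift.
#' @param cfg a [sim_config()].
#' @param seed_offset added to `cfg$seed` (so catalogs and cohorts can draw
#'   independent scores).
#' @return data.frame with `spliceai` and `spcards`.
#' @export
sim_scores <- function(spiked, cfg = sim_config(), seed_offset = 2L) {
  with_rng(cfg$seed + seed_offset, {
    n <- length(spiked)
    mu <- ifelse(spiked, cfg$spike_mean, cfg$decoy_mean)
    z1 <- rnorm(n)
    z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * rnorm(n)
    data.frame(
      spliceai = round(pnorm(mu + z1), 4),
      spcards = pmin(18L, pmax(0L, as.integer(round(18 * pnorm(mu + z2)))))
    )
  })
}

#' Generate a full annotated variant catalog
#'
#' Combines spiked splice-altering variants with decoy variants placed on
#' the same transcripts, attaches copula scores (spikes shifted high),
#' allele frequencies (a point mass at rare values plus a configurable
#' common-variant tail) and truth labels.
#'
#' @param tx output of [sim_transcriptome()].
#' @param cfg a [sim_config()].
#' @return list with `catalog` (data.frame; `is_spike` is the truth label)
#'   and `spikes` (the [sim_spike_events()] output with events attribute).
#' @export
sim_catalog <- function(tx, cfg = sim_config()) {
  spikes <- sim_spike_events(tx, cfg)
  n_decoy <- cfg$n_variants - nrow(spikes)
  decoys <- with_rng(cfg$seed + 3L, {
    txl <- tx$transcripts
    rows <- vector("list", n_decoy)
    for (i in seq_len(n_decoy)) {
      t <- txl[[sample.int(length(txl), 1L)]]
      pos <- pick1(min(t$exons$start):max(t$exons$end))
      seqc <- contig_seq(tx$genome, t$contig)
      ref <- substr(seqc, pos, pos)
      alt <- pick1(setdiff(c("A", "C", "G", "T"), ref))
      cp <- map_g_to_c(t, pos)
      rows[[i]] <- data.frame(
        variant_key = sprintf("%s:%d:%s:%s", t$contig, pos, ref, alt),
        transcript_id = t$transcript_id, gene = t$gene, contig = t$contig,
        pos = pos, ref = ref, alt = alt,
        region = if (cp$offset == 0L) "exonic" else "intronic",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  cat_df <- rbind(
    cbind(spikes[, names(decoys)], is_spike = TRUE),
    cbind(decoys, is_spike = FALSE)
  )
  sc <- sim_scores(cat_df$is_spike, cfg)
  cat_df$spliceai <- sc$spliceai
  cat_df$spcards <- sc$spcards
  cat_df$af_pop1 <- with_rng(cfg$seed + 4L, {
    ifelse(runif(nrow(cat_df)) < cfg$af_common_rate & !cat_df$is_spike,
           cfg$af_common, 0)
  })
  rownames(cat_df) <- NULL
  list(catalog = cat_df, spikes = spikes)
}

## one screenable NCSV call on transcript t for patient construction
cohort_ncsv_call <- function(tx, t, zygosity, af = 0) {
  repeat {
    e <- random_event(t)
    tr <- truth_for_events(tx$genome, t, e)
    if (!tr$kind %in% c("cds_lost", "none")) break
  }
  pos <- spike_variant_pos(t, e, in_consensus = TRUE)
  seqc <- contig_seq(tx$genome, t$contig)
  ref <- substr(seqc, pos, pos)
  alt <- pick1(setdiff(c("A", "C", "G", "T"), ref))
  cp <- map_g_to_c(t, pos)
  cls <- if (cp$offset != 0L) "intronic" else
    pick1(c("missense", "synonymous"))
  data.frame(contig = t$contig, gene = t$gene,
             variant_key = sprintf("%s:%d:%s:%s", t$contig, pos, ref, alt),
             consequence_class = cls, zygosity = zygosity,
             spliceai = round(runif(1, 0.6, 0.99), 4),
             spcards = pick1(10:18),
             af_pop1 = af, sift = NA_character_, pp2 = NA_character_,
             mt = NA_character_, cadd = NA_real_,
             haplotype = NA_character_, stringsAsFactors = FALSE)
}

cohort_partner_call <- function(tx, t) {
  pos <- pick1(min(t$exons$start):max(t$exons$end))
  seqc <- contig_seq(tx$genome, t$contig)
  ref <- substr(seqc, pos, pos)
  alt <- pick1(setdiff(c("A", "C", "G", "T"), ref))
  cls <- pick1(c("stop_gain", "frameshift", "canonical_splicing", "missense"))
  if (cls == "missense") {
    data.frame(contig = t$contig, gene = t$gene,
               variant_key = sprintf("%s:%d:%s:%s", t$contig, pos, ref, alt),
               consequence_class = cls, zygosity = "het",
               spliceai = round(runif(1, 0, 0.2), 4), spcards = pick1(0:5),
               af_pop1 = 0, sift = "D", pp2 = "D", mt = "D", cadd = 28,
               haplotype = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = t$contig, gene = t$gene,
               variant_key = sprintf("%s:%d:%s:%s", t$contig, pos, ref, alt),
               consequence_class = cls, zygosity = "het",
               spliceai = round(runif(1, 0, 0.2), 4), spcards = pick1(0:5),
               af_pop1 = 0, sift = NA_character_, pp2 = NA_character_,
               mt = NA_character_, cadd = NA_real_,
               haplotype = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Generate a screening cohort with planted inheritance configurations
#'
#' Plants `n_hom` homozygous, `n_comphet` compound-heterozygous (trans) and
#' `n_hemi` hemizygous (X, male) NCSV carriers; the remaining patients are
#' decoys cycling through lone heterozygous NCSVs, common-allele-frequency
#' homozygotes, and cis heterozygous pairs. All patients are male (the
#' screened cohort design). Deterministic given `cfg$seed`.
#'
#' @param tx output of [sim_transcriptome()].
#' @param cfg a [sim_config()].
#' @return list with `calls` (data.frame as consumed by
#'   [inheritance_screen()]) and `truth` (data.frame `patient_id`,
#'   `planted_pattern` with `"none"` for decoys).
#' @export
sim_cohort <- function(tx, cfg = sim_config()) {
  with_rng(cfg$seed + 5L, {
    txl <- tx$transcripts
    auto <- Filter(function(t) t$contig != "chrX" && n_exons(t) >= 4L, txl)
    xtx <- Filter(function(t) t$contig == "chrX" && n_exons(t) >= 4L, txl)
    stopifnot(length(auto) >= 2L, length(xtx) >= 1L)
    patterns <- c(rep("homozygous", cfg$n_hom),
                  rep("compound_het", cfg$n_comphet),
                  rep("hemizygous", cfg$n_hemi))
    n_decoy <- cfg$cohort_size - length(patterns)
    decoy_kinds <- rep(c("lone_het", "common_af", "cis_pair"),
                       length.out = max(0L, n_decoy))
    plan <- c(patterns, rep("none", n_decoy))[sample.int(cfg$cohort_size)]
    decoy_i <- 0L
    calls <- list(); truth <- list()
    for (p in seq_len(cfg$cohort_size)) {
      pid <- sprintf("P%03d", p)
      pat <- plan[p]
      rows <- switch(pat,
        homozygous = cohort_ncsv_call(tx, auto[[sample.int(length(auto), 1L)]], "hom"),
        hemizygous = cohort_ncsv_call(tx, xtx[[sample.int(length(xtx), 1L)]], "hemi"),
        compound_het = {
          t <- auto[[sample.int(length(auto), 1L)]]
          a <- cohort_ncsv_call(tx, t, "het")
          b <- if (runif(1) < 0.5) cohort_ncsv_call(tx, t, "het")
               else cohort_partner_call(tx, t)
          while (b$variant_key == a$variant_key) b <- cohort_partner_call(tx, t)
          a$haplotype <- "M"; b$haplotype <- "P"
          rbind(a, b)
        },
        none = {
          decoy_i <- decoy_i + 1L
          kind <- decoy_kinds[decoy_i]
          t <- auto[[sample.int(length(auto), 1L)]]
          if (kind == "lone_het") {
            cohort_ncsv_call(tx, t, "het")
          } else if (kind == "common_af") {
            cohort_ncsv_call(tx, t, "hom", af = cfg$af_common)
          } else {
            a <- cohort_ncsv_call(tx, t, "het")
            b <- cohort_ncsv_call(tx, t, "het")
            a$haplotype <- "M"; b$haplotype <- "M"   # cis pair
            rbind(a, b)
          }
        })
      rows <- cbind(patient_id = pid, sex = "male", rows,
                    stringsAsFactors = FALSE)
      calls[[p]] <- rows
      truth[[p]] <- data.frame(patient_id = pid, planted_pattern = pat,
                               stringsAsFactors = FALSE)
    }
    list(calls = do.call(rbind, calls), truth = do.call(rbind, truth))
  })
}

## --- prescribed-geometry transcripts for golden/desk-scale checks --------

#' Construct a transcript and splice event with prescribed protein geometry
#'
#' Builds a random toy transcript whose CDS encodes `protein_length`
#' residues and whose exon/intron structure realises one named event
#' geometry, then verifies with the string-surgery truth oracle that the
#' event's consequence has exactly the requested first-altered-residue /
#' deleted-range, redrawing the random sequence if a coincidental residue
#' match shifts the alignment. Supported geometries:
#'
#' * `"inframe_del_skip"`: codon-aligned exon covering residues
#'   `res_start..res_end`; skipping it deletes that range in frame.
#' * `"frameshift_skip"`: exon starting at codon `res_start` with a length
#'   not divisible by 3; skipping it shifts the frame from `res_start`.
#' * `"frameshift_retention"`: retention of `ret_len` intron bases (not a
#'   multiple of 3) at a junction inside codon `res_start`.
#' * `"delins_partial"`: partial exon deletion of
#'   `3*(res_end-res_start+1)-3` nt replacing residues
#'   `res_start..res_end` with a single new residue.
#' * `"insertion_retention"`: in-frame retention of `ret_len` (multiple of
#'   3) intron bases at the codon boundary after `res_start`, inserting
#'   `ret_len/3` residues.
#'
#' @param geometry one of the names above.
#' @param protein_length reference protein length (residues).
#' @param res_start,res_end residue coordinates of the geometry.
#' @param ret_len retained intron length (retention geometries).
#' @param seed RNG seed.
#' @return list with `genome`, `transcript` (built), `event`
#'   (a [splice_event()]), `truth` (oracle consequence).
#' @export
sim_transcript_event <- function(geometry, protein_length, res_start,
                                 res_end = res_start, ret_len = NULL,
                                 seed = 1L) {
  geometry <- match.arg(geometry, c("inframe_del_skip", "frameshift_skip",
                                    "frameshift_retention", "delins_partial",
                                    "insertion_retention"))
  L <- as.integer(protein_length)
  a <- as.integer(res_start); b <- as.integer(res_end)
  stopifnot(a >= 2L, b >= a, b <= L - 1L)
  for (attempt in seq_len(200L)) {
    built <- with_rng(seed * 1000L + attempt, {
      cds <- random_cds(L)                       # 3L+3 nt incl. stop
      utr3 <- paste0("TAAGTAAGTAAG", random_dna(18L))  # stops in all frames
      if (geometry == "inframe_del_skip") {
        pieces <- list(substr(cds, 1L, 3L * (a - 1L)),
                       substr(cds, 3L * (a - 1L) + 1L, 3L * b),
                       paste0(substr(cds, 3L * b + 1L, nchar(cds)), utr3))
        ev <- splice_event("exon_skipping", 2L)
      } else if (geometry == "frameshift_skip") {
        cut2 <- 3L * (a - 1L) + 100L             # 100 nt: frame shift of 1
        pieces <- list(substr(cds, 1L, 3L * (a - 1L)),
                       substr(cds, 3L * (a - 1L) + 1L, cut2),
                       paste0(substr(cds, cut2 + 1L, nchar(cds)), utr3))
        ev <- splice_event("exon_skipping", 2L)
      } else if (geometry == "frameshift_retention") {
        cut <- 3L * (a - 1L) + 1L                # junction inside codon a
        pieces <- list(substr(cds, 1L, cut),
                       paste0(substr(cds, cut + 1L, nchar(cds)), utr3))
        ev <- splice_event("intron_retention", 1L, c(1L, ret_len))
      } else if (geometry == "delins_partial") {
        span <- 3L * (b - a + 1L)                # nt of residues a..b
        del_len <- span - 3L
        d1 <- 3L * (a - 1L) + 2L                 # keep 1st base of codon a
        pieces <- list(substr(cds, 1L, 3L * (a - 2L)),
                       substr(cds, 3L * (a - 2L) + 1L, 3L * (b + 1L)),
                       paste0(substr(cds, 3L * (b + 1L) + 1L, nchar(cds)), utr3))
        local_start <- d1 - 3L * (a - 2L)
        ev <- splice_event("partial_exon_deletion", 2L,
                          c(local_start, local_start + del_len - 1L))
      } else {                                   # insertion_retention
        stopifnot(ret_len %% 3L == 0L)
        cut <- 3L * a                            # codon boundary after res a
        pieces <- list(substr(cds, 1L, cut),
                       paste0(substr(cds, cut + 1L, nchar(cds)), utr3))
        ev <- splice_event("intron_retention", 1L, c(1L, ret_len))
      }
      attr(pieces, "utr3_len") <- nchar(utr3)
      need_ret <- geometry %in% c("frameshift_retention", "insertion_retention")
      introns <- replicate(length(pieces) - 1L,
                           random_intron(if (need_ret) max(ret_len + 8L, 80L)
                                         else 80L),
                           simplify = FALSE)
      asm <- assemble_transcript("TXG", "GENEG", "chrG", "+",
                                 pieces, introns, utr5_len = 0L)
      list(genome = genome_ref(setNames(asm$contig_seq, "chrG")),
           model = asm$model, event = ev)
    })
    t <- build_transcript(built$genome, built$model)
    tr <- truth_for_events(built$genome, t, built$event)
    ok <- switch(geometry,
      inframe_del_skip = tr$kind == "inframe_deletion" &&
        tr$count == b - a + 1L,
      frameshift_skip = tr$kind == "frameshift" && !isTRUE(tr$no_stop_found) &&
        tr$fs_first_res == a,
      frameshift_retention = tr$kind == "frameshift" &&
        !isTRUE(tr$no_stop_found) && tr$fs_first_res == a,
      delins_partial = tr$kind == "inframe_delins" && tr$start_res == a &&
        tr$end_res == b && nchar(tr$inserted) == 1L,
      insertion_retention = tr$kind == "inframe_insertion" &&
        nchar(tr$inserted) == ret_len %/% 3L)
    if (ok) {
      return(list(genome = built$genome, transcript = t,
                  event = built$event, truth = tr))
    }
  }
  stop("sim_transcript_event: could not realise geometry in 200 attempts",
       call. = FALSE)
}
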