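#' Classify a variant by transcript consequence
#'
#' Single-nucleotide variants inside the CDS are classified by codon effect
#' (synonymous / missense / stop_gain / stop_loss / start_loss); exonic
#' indels by length difference modulo 3 (frameshift / nonframeshift);
#' intronic positions are `canonical_splicing` when within +/-2 of a
#' junction and `intronic` otherwise; UTR positions are `utr`.
#'
#' @param genome a [genome_ref()].
#' @param t a built [transcript_model()].
#' @param pos genomic position (1-based) of the first reference base.
#' @param ref,alt reference/alternate alleles on the plus strand of the
#'   contig (VCF convention).
#' @return consequence class string.
#' @export
classify_variant <- function(genome, t, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("classify_variant: ref == alt", call. = FALSE)
  cp <- map_g_to_c(t, pos)
  if (cp$region %in% c("utr5", "utr3")) return("utr")
  if (cp$offset != 0L) {
    return(if (abs(cp$offset) <= 2L) "canonical_splicing" else "intronic")
  }
  if (nchar(ref) != nchar(alt)) {
    d <- abs(nchar(ref) - nchar(alt))
    return(if (d %% 3L == 0L) "nonframeshift" else "frameshift")
  }
  if (nchar(ref) != 1L) {
    ## multi-nucleotide substitution: classify by re-translation below using
    ## the first base position; only SNVs are expected in this pipeline
    return("missense")
  }
  ## transcript-strand alleles
  if (t$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  base <- cp$base
  obs <- substr(t$cds, base, base)
  if (obs != ref) {
    stop(sprintf("classify_variant: reference allele mismatch at c.%d (%s vs %s)",
                 base, obs, ref), call. = FALSE)
  }
  cds_alt <- t$cds
  substr(cds_alt, base, base) <- alt
  codon_i <- (base - 1L) %/% 3L + 1L
  from <- substr(t$cds, 3L * codon_i - 2L, 3L * codon_i)
  to <- substr(cds_alt, 3L * codon_i - 2L, 3L * codon_i)
  aa_from <- translate_codon(from)
  aa_to <- translate_codon(to)
  if (aa_from == aa_to) return("synonymous")
  if (codon_i == 1L) return("start_loss")
  if (aa_to == "*") return("stop_gain")
  if (aa_from == "*") return("stop_loss")
  "missense"
}

translate_codon <- function(codon) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(codon), no.init.codon = TRUE)))
}

#' Junction context of a variant position
#'
#' Distance to the nearest splice junction, signed along the transcript
#' direction relative to that junction: intronic bases after a donor are
#' positive and before an acceptor negative; the exonic base immediately
#' before a donor is -1 and the exonic base k bases after an acceptor is +k.
#' The consensus windows are donor -3..+8 and acceptor -12..+2.
#'
#' @param t a built [transcript_model()].
#' @param gpos genomic position.
#' @param donor_window,acceptor_window consensus windows `c(lo, hi)`.
#' @return list with `side` (`"donor"`/`"acceptor"`), `distance`, `region`
#'   (`"exonic"`/`"intronic"`), `in_consensus`; or `NULL` for a single-exon
#'   transcript (no junctions).
#' @export
junction_context <- function(t, gpos, donor_window = c(-3L, 8L),
                             acceptor_window = c(-12L, 2L)) {
  if (n_exons(t) < 2L) return(NULL)
  tpos <- g_to_t(t, gpos)
  if (!is.na(tpos)) {
    lens <- exon_lengths(t)
    ends <- cumsum(lens)
    i <- which(tpos <= ends)[1L]
    exon_start_t <- c(1L, ends + 1L)[i]
    d_acc <- tpos - exon_start_t + 1L          # +k after the acceptor
    d_don <- -(ends[i] - tpos + 1L)            # -k before the donor
    has_acc <- i > 1L
    has_don <- i < n_exons(t)
    if (has_acc && (!has_don || d_acc < abs(d_don))) {
      side <- "acceptor"; d <- d_acc
    } else if (has_don && (!has_acc || abs(d_don) < d_acc)) {
      side <- "donor"; d <- d_don
    } else {
      side <- "donor"; d <- d_don              # tie -> donor
    }
    region <- "exonic"
  } else {
    found <- FALSE
    for (i in seq_len(n_exons(t) - 1L)) {
      lo <- min(t$exons$end[i], t$exons$start[i + 1L])
      hi <- max(t$exons$end[i], t$exons$start[i + 1L])
      if (gpos > lo && gpos < hi) { found <- TRUE; break }
    }
    if (!found) stop("junction_context: position outside transcript span", call. = FALSE)
    don_g <- if (t$strand == "+") t$exons$end[i] else t$exons$start[i]
    acc_g <- if (t$strand == "+") t$exons$start[i + 1L] else t$exons$end[i + 1L]
    d_don <- abs(gpos - don_g)
    d_acc <- abs(acc_g - gpos)
    if (d_don <= d_acc) { side <- "donor"; d <- d_don }
    else { side <- "acceptor"; d <- -d_acc }
    region <- "intronic"
  }
  list(side = side, distance = as.integer(d), region = region,
       in_consensus = in_consensus_window(side, d, donor_window, acceptor_window))
}

#' Is a signed junction distance inside the splicing consensus region?
#'
#' @param side `"donor"` or `"acceptor"`.
#' @param distance signed distance (see [junction_context()]).
#' @param donor_window,acceptor_window windows `c(lo, hi)`, defaults
#'   -3..+8 (donor) and -12..+2 (acceptor).
#' @return logical.
#' @export
in_consensus_window <- function(side, distance, donor_window = c(-3L, 8L),
                                acceptor_window = c(-12L, 2L)) {
  w <- if (side == "donor") donor_window else acceptor_window
  distance >= w[1] & distance <= w[2]
}

## infer the junction side from a reported signed distance and region:
## intronic +d lies after a donor, intronic -d before an acceptor; exonic -d
## precedes a donor, exonic +d follows an acceptor
junction_side_from_distance <- function(distance, region) {
  ifelse(region == "intronic",
         ifelse(distance > 0, "donor", "acceptor"),
         ifelse(distance < 0, "donor", "acceptor"))
}

#' Dual-threshold splicing prioritization
#'
#' A variant is prioritized as a potential splicing variant when its
#' supporting-method count reaches `spcards_min` (default 9 of 18) OR its
#' SpliceAI score reaches `spliceai_min` (default 0.5); both thresholds are
#' inclusive and a missing score on one arm never blocks the other.
#'
#' @param spliceai numeric vector in `[0,1]`, `NA` allowed.
#' @param spcards integer vector in `[0,18]`, `NA` allowed.
#' @param spcards_min,spliceai_min inclusive thresholds.
#' @return data.frame with logical columns `prioritized`, `arm_spcards`,
#'   `arm_spliceai`.
#' @export
#' @examples
#' prioritize(spliceai = c(0.9482, 0.6563, NA, 0.49),
#'            spcards  = c(14, 2, 15, 8))
prioritize <- function(spliceai, spcards, spcards_min = 9L, spliceai_min = 0.5) {
  stopifnot(length(spliceai) == length(spcards))
  if (any(spliceai < 0 | spliceai > 1, na.rm = TRUE)) {
    stop("prioritize: spliceai outside [0,1]", call. = FALSE)
  }
  if (any(spcards < 0 | spcards > 18, na.rm = TRUE)) {
    stop("prioritize: spcards outside [0,18]", call. = FALSE)
  }
  arm_sp <- !is.na(spcards) & spcards >= spcards_min
  arm_ai <- !is.na(spliceai) & spliceai >= spliceai_min
  data.frame(prioritized = arm_sp | arm_ai,
             arm_spcards = arm_sp, arm_spliceai = arm_ai)
}

#' Select prioritized variants for functional validation
#'
#' Canonical splicing and stop-gain variants are loss-of-function variants
#' handled by the standard interpretation pipeline and are excluded; the
#' remaining potential NCSV classes (intronic, missense, synonymous) are
#' selected. Previously validated variants are removed unless explicitly
#' re-queued.
#'
#' @param catalog data.frame with at least `consequence_class` and
#'   `prioritized`; optional `prior_validation` (`"none"`, `"predicted"`,
#'   `"validated"`) and logical `requeue`.
#' @return the selected subset of `catalog`, with an `excluded_reason`
#'   column (`canonical`, `lof`, `already_validated`, `not_prioritized`,
#'   `other_class`, `none`) attached to the full input as attribute
#'   `"decisions"`.
#' @export
select_for_validation <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("consequence_class", "prioritized") %in% names(catalog)))
  pv <- if ("prior_validation" %in% names(catalog)) catalog$prior_validation
        else rep("none", nrow(catalog))
  rq <- if ("requeue" %in% names(catalog)) catalog$requeue
        else rep(FALSE, nrow(catalog))
  reason <- rep("none", nrow(catalog))
  reason[!catalog$prioritized] <- "not_prioritized"
  reason[catalog$prioritized &
           catalog$consequence_class == "canonical_splicing"] <- "canonical"
  reason[catalog$prioritized & catalog$consequence_class == "stop_gain"] <- "lof"
  reason[catalog$prioritized & reason == "none" &
           !catalog$consequence_class %in% c("intronic", "missense", "synonymous")] <-
    "other_class"
  reason[reason == "none" & pv == "validated" & !rq] <- "already_validated"
  out <- catalog[reason == "none", , drop = FALSE]
  attr(out, "decisions") <- reason
  out
}
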