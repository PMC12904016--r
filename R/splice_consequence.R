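#' Describe an aberrant splicing event
#'
#' @param event_type one of `"exon_skipping"`, `"partial_exon_deletion"`,
#'   `"intron_retention"`.
#' @param element_index exon ordinal (for skipping / partial deletion) or
#'   intron ordinal (for retention), counted in transcript orientation;
#'   intron `i` lies between exons `i` and `i+1`.
#' @param sub_interval optional `c(start, end)` local to the element
#'   (1-based, element orientation = transcript orientation). Required for
#'   `partial_exon_deletion`; for `intron_retention` it must be anchored to
#'   one end of the intron (a cryptic donor retains `1..k`, a cryptic
#'   acceptor retains `len-k+1..len`); absent means the whole intron.
#' @return object of class `SpliceEvent`.
#' @export
#' @examples
#' splice_event("exon_skipping", 14)
#' splice_event("intron_retention", 2, c(1, 2))
splice_event <- function(event_type, element_index, sub_interval = NULL) {
  event_type <- match.arg(event_type,
    c("exon_skipping", "partial_exon_deletion", "intron_retention"))
  if (event_type == "partial_exon_deletion" && is.null(sub_interval)) {
    stop("partial_exon_deletion requires sub_interval", call. = FALSE)
  }
  if (!is.null(sub_interval)) {
    sub_interval <- as.integer(sub_interval)
    stopifnot(length(sub_interval) == 2L, sub_interval[1] >= 1L,
              sub_interval[2] >= sub_interval[1])
  }
  structure(list(event_type = event_type,
                 element_index = as.integer(element_index),
                 sub_interval = sub_interval),
            class = "SpliceEvent")
}

#' @export
print.SpliceEvent <- function(x, ...) {
  sub <- if (is.null(x$sub_interval)) "" else
    sprintf(" [%d-%d]", x$sub_interval[1], x$sub_interval[2])
  cat(sprintf("<SpliceEvent> %s of element %d%s\n",
              x$event_type, x$element_index, sub))
  invisible(x)
}

## mRNA-coordinate edit for one event: list(pos, del_len, ins_seq);
## pos = first mRNA base affected (for insertions, insert AFTER pos)
event_edit <- function(genome, t, e) {
  lens <- exon_lengths(t)
  starts <- cumsum(c(0L, lens)) + 1L
  i <- e$element_index
  if (e$event_type == "exon_skipping") {
    if (i < 1L || i > n_exons(t)) stop("no exon ", i, call. = FALSE)
    list(pos = starts[i], del_len = lens[i], ins = "")
  } else if (e$event_type == "partial_exon_deletion") {
    if (i < 1L || i > n_exons(t)) stop("no exon ", i, call. = FALSE)
    if (e$sub_interval[2] > lens[i]) {
      stop("sub_interval outside exon ", i, call. = FALSE)
    }
    list(pos = starts[i] + e$sub_interval[1] - 1L,
         del_len = e$sub_interval[2] - e$sub_interval[1] + 1L, ins = "")
  } else {
    iseq <- intron_seq(genome, t, i)
    sub <- if (is.null(e$sub_interval)) c(1L, nchar(iseq)) else e$sub_interval
    if (sub[2] > nchar(iseq)) stop("sub_interval outside intron ", i, call. = FALSE)
    if (sub[1] != 1L && sub[2] != nchar(iseq)) {
      stop("retention sub_interval must be anchored to one intron end", call. = FALSE)
    }
    ## retained sequence sits at the exon i / exon i+1 junction
    list(pos = starts[i + 1L] - 1L, del_len = 0L,
         ins = substr(iseq, sub[1], sub[2]))
  }
}

#' Apply aberrant splicing events to a transcript
#'
#' Edits the mature mRNA according to one or more [splice_event()]s
#' (exon skipping removes the exon, partial exon deletion removes the
#' sub-interval, intron retention inserts the retained intronic sequence at
#' the junction) and re-derives the CDS from the original start codon to the
#' 3' end of the edited mRNA.
#'
#' @param genome a [genome_ref()].
#' @param t a built [transcript_model()].
#' @param events a single [splice_event()] or a list of them (a compound
#'   outcome); events are interpreted on original transcript coordinates.
#' @return list with `mrna` (edited), `cds` (from the original start codon;
#'   `NA` with `cds_lost = TRUE` if an edit removes the start codon), and
#'   `cds_lost`.
#' @export
apply_event <- function(genome, t, events) {
  if (inherits(events, "SpliceEvent")) events <- list(events)
  edits <- lapply(events, function(e) event_edit(genome, t, e))
  ## apply right-to-left so earlier coordinates stay valid
  ord <- order(vapply(edits, `[[`, numeric(1), "pos"), decreasing = TRUE)
  mrna <- t$mrna
  cds_off <- t$cds_offset
  for (ed in edits[ord]) {
    if (ed$del_len > 0L) {
      a <- ed$pos; b <- ed$pos + ed$del_len - 1L
      mrna <- paste0(substr(mrna, 1L, a - 1L),
                     substr(mrna, b + 1L, nchar(mrna)))
      if (b < cds_off) {
        cds_off <- cds_off - ed$del_len
      } else if (a <= cds_off + 2L) {   # start codon touched
        return(list(mrna = mrna, cds = NA_character_, cds_lost = TRUE))
      }
    } else if (nzchar(ed$ins)) {
      mrna <- paste0(substr(mrna, 1L, ed$pos), ed$ins,
                     substr(mrna, ed$pos + 1L, nchar(mrna)))
      if (ed$pos < cds_off) cds_off <- cds_off + nchar(ed$ins)
    }
  }
  if (cds_off + 2L > nchar(mrna)) {
    return(list(mrna = mrna, cds = NA_character_, cds_lost = TRUE))
  }
  list(mrna = mrna, cds = substr(mrna, cds_off, nchar(mrna)), cds_lost = FALSE)
}

aa1 <- function(protein, i) substr(protein, i, i)

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b, max_s) {
  if (max_s <= 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])
  bv <- rev(strsplit(b, "")[[1]])
  n <- min(length(av), length(bv), max_s)
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Protein-level consequence of an edited CDS
#'
#' Translates the alternate CDS (to its first stop) and compares it with the
#' reference protein by trimming the maximal common prefix, then the maximal
#' common suffix (which places deletions 3'-most, matching HGVS practice).
#' The change is classified as an in-frame deletion, delins or insertion, a
#' stop gain, or a frameshift; frameshifts are named
#' `p.<ref><pos><new>fs*N` where `N` counts residues from the first changed
#' residue (= 1) to the new stop. An alternate translation lacking any stop
#' is flagged `no_stop_found`.
#'
#' @param ref_protein reference protein (residues, no stop character).
#' @param alt_cds alternate CDS from the original start codon to the 3' end
#'   of the edited mRNA.
#' @param frame_ref_len length the unedited sequence from the start codon
#'   to the same 3' end would have; the frame check compares
#'   `nchar(alt_cds)` with it modulo 3. Defaults to the bare reference CDS
#'   length (`3 * (protein_length + 1)`), appropriate when `alt_cds` ends at
#'   the transcript's stop codon; pass `nchar(mrna) - cds_offset + 1` when
#'   the edited mRNA carries a 3' UTR (see [event_consequence()]).
#' @return object of class `ProteinConsequence` with fields `kind`
#'   (`none`, `inframe_deletion`, `inframe_delins`, `inframe_insertion`,
#'   `frameshift`, `stop_gain`), `start_res`, `end_res`, `inserted`,
#'   `fs_first_res`, `fs_stop_offset`, `no_stop_found`, `hgvs_p`.
#' @export
protein_consequence <- function(ref_protein, alt_cds,
                                frame_ref_len = 3L * (nchar(ref_protein) + 1L)) {
  if (is.na(alt_cds) || !nzchar(alt_cds)) {
    stop("protein_consequence: empty alternate CDS", call. = FALSE)
  }
  tr <- translate_cds(alt_cds)
  alt <- tr$protein
  ref <- ref_protein
  lr <- nchar(ref); la <- nchar(alt)
  frame_shifted <- ((nchar(alt_cds) - frame_ref_len) %% 3L) != 0L

  res <- list(kind = "none", start_res = NA_integer_, end_res = NA_integer_,
              start_aa = NA_character_, end_aa = NA_character_,
              inserted = "", fs_first_res = NA_integer_,
              fs_stop_offset = NA_integer_, fs_ref_aa = NA_character_,
              fs_new_aa = NA_character_, no_stop_found = FALSE,
              hgvs_p = "p.=")
  class(res) <- "ProteinConsequence"

  if (!frame_shifted && tr$stop_found && alt == ref) return(res)

  p <- common_prefix_len(ref, alt)

  if (!tr$stop_found) {
    res$kind <- "frameshift"
    res$no_stop_found <- TRUE
    res$fs_first_res <- p + 1L
    res$fs_ref_aa <- aa1(ref, p + 1L)
    res$fs_new_aa <- if (p < la) aa1(alt, p + 1L) else "?"
    res$hgvs_p <- format_hgvs_p(res)
    return(res)
  }

  if (p == la) {
    ## alternate protein is a (strict) prefix of the reference: translation
    ## terminates at residue p+1 of the reference
    if (p >= lr) {
      ## extension beyond ref never occurs here because alt == ref handled;
      ## p == lr with la > lr impossible since p <= la
      return(res)
    }
    res$kind <- "stop_gain"
    res$start_res <- res$fs_first_res <- p + 1L
    res$end_res <- p + 1L
    res$start_aa <- res$end_aa <- aa1(ref, p + 1L)
    res$hgvs_p <- format_hgvs_p(res)
    return(res)
  }

  if (frame_shifted) {
    res$kind <- "frameshift"
    res$fs_first_res <- p + 1L
    res$fs_stop_offset <- la - p + 1L
    res$fs_ref_aa <- aa1(ref, p + 1L)
    res$fs_new_aa <- aa1(alt, p + 1L)
    res$hgvs_p <- format_hgvs_p(res)
    return(res)
  }

  s <- common_suffix_len(ref, alt, min(lr, la) - p)
  if (p + s == la) {                     # pure loss
    res$kind <- "inframe_deletion"
    res$start_res <- p + 1L
    res$end_res <- lr - s
  } else if (p + s == lr) {              # pure gain
    res$kind <- "inframe_insertion"
    res$start_res <- p
    res$end_res <- p + 1L
    res$inserted <- substr(alt, p + 1L, la - s)
  } else {                               # replacement
    res$kind <- "inframe_delins"
    res$start_res <- p + 1L
    res$end_res <- lr - s
    res$inserted <- substr(alt, p + 1L, la - s)
  }
  res$start_aa <- aa1(ref, res$start_res)
  res$end_aa <- aa1(ref, res$end_res)
  res$hgvs_p <- format_hgvs_p(res)
  res
}

#' Format a protein consequence as an HGVS-p string
#'
#' Regenerates the HGVS-p description from the structured fields of a
#' `ProteinConsequence` (deletions `p.V430_K475del`, delins
#' `p.N43_A66delinsT`, insertions `p.A211_A212insLA`, stop gains
#' `p.A394*`, frameshifts `p.G194Rfs*7` / `p.K12Efs*?`).
#'
#' @param cons a `ProteinConsequence` (from [protein_consequence()] or
#'   [parse_hgvs_p()]).
#' @return character scalar.
#' @export
format_hgvs_p <- function(cons) {
  switch(cons$kind,
    none = "p.=",
    stop_gain = sprintf("p.%s%d*", cons$start_aa, cons$start_res),
    frameshift = sprintf("p.%s%d%sfs*%s", cons$fs_ref_aa, cons$fs_first_res,
                         cons$fs_new_aa,
                         if (cons$no_stop_found) "?"
                         else as.character(cons$fs_stop_offset)),
    inframe_deletion = if (cons$start_res == cons$end_res) {
      sprintf("p.%s%ddel", cons$start_aa, cons$start_res)
    } else {
      sprintf("p.%s%d_%s%ddel", cons$start_aa, cons$start_res,
              cons$end_aa, cons$end_res)
    },
    inframe_insertion = sprintf("p.%s%d_%s%dins%s", cons$start_aa,
                                cons$start_res, cons$end_aa, cons$end_res,
                                cons$inserted),
    inframe_delins = if (cons$start_res == cons$end_res) {
      sprintf("p.%s%ddelins%s", cons$start_aa, cons$start_res, cons$inserted)
    } else {
      sprintf("p.%s%d_%s%ddelins%s", cons$start_aa, cons$start_res,
              cons$end_aa, cons$end_res, cons$inserted)
    },
    stop("format_hgvs_p: unknown kind ", cons$kind, call. = FALSE))
}

#' Apply a splicing event and derive its protein consequence
#'
#' Convenience wrapper chaining [apply_event()] and
#' [protein_consequence()] with the correct frame reference (the edited
#' mRNA tail includes the 3' UTR).
#'
#' @inheritParams apply_event
#' @return a `ProteinConsequence`; kind `none` with attribute
#'   `cds_lost = TRUE` if the event removes the start codon.
#' @export
event_consequence <- function(genome, t, events) {
  ed <- apply_event(genome, t, events)
  if (ed$cds_lost) {
    res <- structure(list(kind = "none", start_res = NA_integer_,
                          end_res = NA_integer_, inserted = "",
                          fs_first_res = NA_integer_,
                          fs_stop_offset = NA_integer_,
                          no_stop_found = FALSE, hgvs_p = "p.?"),
                     class = "ProteinConsequence")
    attr(res, "cds_lost") <- TRUE
    warning("event removes the translation start; no consequence derived")
    return(res)
  }
  protein_consequence(t$protein, ed$cds,
                      frame_ref_len = nchar(t$mrna) - t$cds_offset + 1L)
}

#' @export
print.ProteinConsequence <- function(x, ...) {
  cat(sprintf("<ProteinConsequence> %s %s\n", x$kind, x$hgvs_p))
  invisible(x)
}

#' Parse an HGVS-p consequence string
#'
#' Inverse of the naming used by [protein_consequence()]: deletions
#' (`p.V430_K475del`, `p.A2del`), delins (`p.N43_A66delinsT`), insertions
#' (`p.A211_A212insLA`), stop gains (`p.A394*`) and frameshifts
#' (`p.G194Rfs*7`, `p.K12Efs*?`).
#'
#' @param x character scalar.
#' @return a `ProteinConsequence` (without `hgvs_p` regeneration applied;
#'   the regenerated string from [protein_consequence()] fields equals a
#'   normalized `x`).
#' @export
parse_hgvs_p <- function(x) {
  s <- gsub("‐|‒|–|—|−", "-", x)
  s <- gsub("[[:space:]]", "", s)
  res <- list(kind = NA_character_, start_res = NA_integer_,
              end_res = NA_integer_, start_aa = NA_character_,
              end_aa = NA_character_, inserted = "",
              fs_first_res = NA_integer_, fs_stop_offset = NA_integer_,
              fs_ref_aa = NA_character_, fs_new_aa = NA_character_,
              no_stop_found = FALSE, hgvs_p = s)
  class(res) <- "ProteinConsequence"
  aa <- "[A-Za-z]"
  m <- regmatches(s, regexec(sprintf(
    "^p\\.(%s)(\\d+)(?:_(%s)(\\d+))?del(?:ins(%s+))?$", aa, aa, aa), s))[[1]]
  if (length(m)) {
    res$start_res <- as.integer(m[3])
    res$end_res <- if (nzchar(m[5])) as.integer(m[5]) else res$start_res
    res$start_aa <- toupper(m[2])
    res$end_aa <- if (nzchar(m[4])) toupper(m[4]) else res$start_aa
    if (nzchar(m[6])) {
      res$kind <- "inframe_delins"; res$inserted <- toupper(m[6])
    } else {
      res$kind <- "inframe_deletion"
    }
    if (res$end_res < res$start_res) {
      stop("parse_hgvs_p: reversed residue range in ", x, call. = FALSE)
    }
    return(res)
  }
  m <- regmatches(s, regexec(sprintf(
    "^p\\.(%s)(\\d+)_(%s)(\\d+)ins(%s+)$", aa, aa, aa), s))[[1]]
  if (length(m)) {
    res$kind <- "inframe_insertion"
    res$start_res <- as.integer(m[3])
    res$end_res <- as.integer(m[5])
    res$start_aa <- toupper(m[2])
    res$end_aa <- toupper(m[4])
    res$inserted <- toupper(m[6])
    if (res$end_res != res$start_res + 1L) {
      stop("parse_hgvs_p: insertion flanks not adjacent in ", x, call. = FALSE)
    }
    return(res)
  }
  m <- regmatches(s, regexec(sprintf(
    "^p\\.(%s)(\\d+)(%s)fs\\*(\\d+|\\?)$", aa, aa), s))[[1]]
  if (length(m)) {
    res$kind <- "frameshift"
    res$fs_first_res <- as.integer(m[3])
    res$fs_ref_aa <- toupper(m[2])
    res$fs_new_aa <- toupper(m[4])
    if (m[5] == "?") res$no_stop_found <- TRUE
    else res$fs_stop_offset <- as.integer(m[5])
    return(res)
  }
  m <- regmatches(s, regexec(sprintf("^p\\.(%s)(\\d+)\\*$", aa), s))[[1]]
  if (length(m)) {
    res$kind <- "stop_gain"
    res$start_res <- res$end_res <- res$fs_first_res <- as.integer(m[3])
    res$start_aa <- res$end_aa <- toupper(m[2])
    return(res)
  }
  if (s == "p.=") { res$kind <- "none"; return(res) }
  stop("parse_hgvs_p: cannot parse ", x, call. = FALSE)
}

#' Disrupted residue count and fraction of a protein consequence
#'
#' Counting conventions: in-frame deletions and delins count the removed
#' reference range (`end - start + 1`); in-frame insertions count the
#' inserted residues; frameshifts and stop gains count everything from the
#' first altered residue to the C terminus, exclusive of the first altered
#' residue itself (`protein_length - fs_first_res`).
#'
#' @param cons a `ProteinConsequence`.
#' @param protein_length reference protein length (residues).
#' @return list with `count` and `fraction` (`count / protein_length`).
#' @export
#' @examples
#' disrupted_fraction(parse_hgvs_p("p.V430_K475del"), 940)   # 46/940
#' disrupted_fraction(parse_hgvs_p("p.A69Sfs*12"), 134)      # 65/134
disrupted_fraction <- function(cons, protein_length) {
  stopifnot(protein_length >= 1L)
  count <- switch(cons$kind,
    none = 0L,
    inframe_deletion = ,
    inframe_delins = {
      if (cons$end_res > protein_length) {
        stop("disrupted_fraction: residue range outside protein", call. = FALSE)
      }
      cons$end_res - cons$start_res + 1L
    },
    inframe_insertion = nchar(cons$inserted),
    frameshift = ,
    stop_gain = {
      first <- cons$fs_first_res
      if (is.na(first) || first > protein_length) {
        stop("disrupted_fraction: first altered residue outside protein", call. = FALSE)
      }
      protein_length - first
    },
    stop("disrupted_fraction: consequence kind is none/unknown", call. = FALSE)
  )
  list(count = as.integer(count), fraction = count / protein_length)
}

#' PVS1 strength call for a splicing consequence
#'
#' `PVS1_Strong` is assigned when the consequence is loss-of-function type
#' (frameshift or stop gain) and the disrupted fraction strictly exceeds
#' 10% of the protein product; otherwise `not_met` with a rationale.
#'
#' @param cons a `ProteinConsequence`.
#' @param protein_length reference protein length.
#' @param threshold disrupted-fraction threshold (default 0.10, strict).
#' @return list with `strength` (`"PVS1_Strong"`/`"not_met"`), `fraction`,
#'   `rationale`.
#' @export
pvs1_call <- function(cons, protein_length, threshold = 0.10) {
  if (cons$kind == "none") {
    return(list(strength = "not_met", fraction = 0,
                rationale = "no protein-level consequence"))
  }
  fr <- disrupted_fraction(cons, protein_length)$fraction
  lof <- cons$kind %in% c("frameshift", "stop_gain")
  if (lof && fr > threshold) {
    list(strength = "PVS1_Strong", fraction = fr,
         rationale = sprintf("%s disrupting %.2f%% (> %.0f%%) of the protein",
                             cons$kind, 100 * fr, 100 * threshold))
  } else if (!lof) {
    list(strength = "not_met", fraction = fr,
         rationale = sprintf("in-frame consequence (%s), not LoF-type", cons$kind))
  } else {
    list(strength = "not_met", fraction = fr,
         rationale = sprintf("%s disrupting only %.2f%% (<= %.0f%%) of the protein",
                             cons$kind, 100 * fr, 100 * threshold))
  }
}

ncsv_label_grid <- data.frame(
  region = rep(c("exonic", "intronic"), 3),
  outcome = rep(c("exon_skipping", "partial_exon_deletion", "intron_retention"),
                each = 2),
  label = c("A", "B", "C", "D", "E", "F"),
  stringsAsFactors = FALSE
)

#' Classify a validated NCSV into the six-class taxonomy
#'
#' Classes combine the variant's region with the splicing outcome:
#' A exonic/exon skipping, B intronic/exon skipping, C exonic/partial exon
#' deletion, D intronic/partial exon deletion, E exonic/intron retention,
#' F intronic/intron retention. A compound outcome (one variant, several
#' events) yields one row per outcome.
#'
#' @param region `"exonic"` or `"intronic"` (variant location).
#' @param event_types character vector of outcome types.
#' @return data.frame with columns `region`, `outcome`, `label`.
#' @export
#' @examples
#' ncsv_classify("intronic", "exon_skipping")           # class B
#' ncsv_classify("exonic",
#'   c("partial_exon_deletion", "intron_retention"))    # classes C and E
ncsv_classify <- function(region, event_types) {
  region <- match.arg(region, c("exonic", "intronic"))
  out <- merge(data.frame(region = region, outcome = event_types,
                          stringsAsFactors = FALSE),
               ncsv_label_grid, by = c("region", "outcome"), sort = FALSE)
  if (nrow(out) != length(event_types)) {
    stop("ncsv_classify: unknown outcome type", call. = FALSE)
  }
  out[order(out$label), , drop = FALSE]
}
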