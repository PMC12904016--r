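#' Bundled curated catalog of validated non-canonical splicing variants
#'
#' A plain-text transcription of the published compilation of functionally
#' validated NCSVs in hereditary male infertility (28 variants curated from
#' primary reports plus 13 identified by cohort re-analysis). Each row
#' carries the variant (`position`, `gene`, `hgvs_c`), its class (`type`:
#' `Mis`/`Syn`/`Intron`), the signed distance to the nearest canonical
#' splice junction, the two splicing prediction scores, the observed
#' splicing outcome, the predicted protein alteration with the printed
#' disrupted-residue count, protein length and percentage, and two
#' consistency flags: `count_ok` / `pct_ok` are `TRUE` when the printed
#' count / percentage agree with the engine's counting conventions applied
#' to the alteration string (a handful of printed values carry arithmetic
#' or rounding slips, flagged `FALSE` with a `note`).
#'
#' @return data.frame, one row per validated NCSV.
#' @export
ncsv_catalog <- function() {
  path <- system.file("extdata", "ncsv_catalog.tsv", package = "ncsvtools",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", "-", ""))
  df$count_ok <- as.logical(df$count_ok)
  df$pct_ok <- as.logical(df$pct_ok)
  df
}

#' Bundled cohort genotype table of biallelic/X-linked candidates
#'
#' Transcription of the screened biallelic/X-linked variant calls
#' (17 patients; homozygous, compound-heterozygous and hemizygous
#' genotypes with allele frequencies and missense predictor calls).
#'
#' @return data.frame, one row per variant call.
#' @export
ncsv_cohort_genotypes <- function() {
  path <- system.file("extdata", "cohort_genotypes.tsv", package = "ncsvtools",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
}

#' Reconstructed analysis-stage counts
#'
#' The class tallies of the curated catalog (stated non-redundant total
#' 2404; the per-class counts sum to 2403 and both numbers are reported by
#' [tally_classes()]), the prioritization/validation funnel counts and the
#' cohort counts, as inputs for [headline_rates()].
#'
#' @return named list of counts.
#' @export
ncsv_stage_counts <- function() {
  path <- system.file("extdata", "stage_counts.tsv", package = "ncsvtools",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.list(df$count), df$stage)
}

#' Parse a splicing outcome description
#'
#' Converts outcome strings like `"Exon 3 skipping"`,
#' `"Intron 2 6bp retention"`, `"Exon 31 133bp deletion"`,
#' `"Intron 74 retention and exon 75 65bp deletion"` or
#' `"Intron 2 19bp;26bp;33bp retention"` into one row per elementary
#' outcome.
#'
#' @param x character vector of outcome descriptions.
#' @return data.frame with columns `input_index`, `event_type`
#'   (`exon_skipping`/`partial_exon_deletion`/`intron_retention`),
#'   `element_index`, `length_bp` (`NA` for whole-element outcomes).
#' @export
parse_outcome <- function(x) {
  out <- list()
  for (i in seq_along(x)) {
    for (part in strsplit(x[i], "\\s+and\\s+", perl = TRUE)[[1]]) {
      m <- regmatches(part, regexec(
        "^\\s*(Exon|exon|Intron|intron)\\s+(\\d+)\\s+(.*)$", part))[[1]]
      if (length(m) == 0L) stop("cannot parse outcome: ", part, call. = FALSE)
      element <- tolower(m[2]); idx <- as.integer(m[3]); rest <- trimws(m[4])
      if (grepl("^skipping$", rest)) {
        out[[length(out) + 1L]] <- data.frame(
          input_index = i, event_type = "exon_skipping", element_index = idx,
          length_bp = NA_integer_)
      } else if (grepl("retention", rest)) {
        lens <- regmatches(rest, gregexpr("\\d+(?=\\s?bp)", rest, perl = TRUE))[[1]]
        if (length(lens) == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            input_index = i, event_type = "intron_retention",
            element_index = idx, length_bp = NA_integer_)
        } else {
          for (L in as.integer(lens)) {
            out[[length(out) + 1L]] <- data.frame(
              input_index = i, event_type = "intron_retention",
              element_index = idx, length_bp = L)
          }
        }
      } else if (grepl("deletion", rest)) {
        L <- regmatches(rest, regexpr("\\d+(?=\\s?bp)", rest, perl = TRUE))
        out[[length(out) + 1L]] <- data.frame(
          input_index = i, event_type = "partial_exon_deletion",
          element_index = idx,
          length_bp = if (length(L)) as.integer(L) else NA_integer_)
      } else {
        stop("cannot parse outcome: ", part, call. = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
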