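#' Allele-frequency filter
#'
#' Common variants are dropped: a variant is removed iff any configured
#' population frequency strictly exceeds the threshold (default 0.01).
#' Missing frequencies never drop a variant.
#'
#' @param calls data.frame of variant calls.
#' @param af_cols names of allele-frequency columns (default: all columns
#'   beginning with `"af"`).
#' @param af_max threshold (strict `>` drops).
#' @param semantics `"any"` (default; any exceedance drops) or `"max"`
#'   (the maximum across populations is compared; identical outcome, kept as
#'   a configuration switch for per-source reporting).
#' @return logical vector, `TRUE` = keep.
#' @export
#' @examples
#' af_filter(data.frame(af_1kgp = c(0.010, NA), af_gnomad = c(NA, 0.043)))
af_filter <- function(calls, af_cols = grep("^af", names(calls), value = TRUE),
                      af_max = 0.01, semantics = c("any", "max")) {
  semantics <- match.arg(semantics)
  if (length(af_cols) == 0L) return(rep(TRUE, nrow(calls)))
  af <- as.matrix(calls[, af_cols, drop = FALSE])
  storage.mode(af) <- "double"
  if (semantics == "max") {
    mx <- suppressWarnings(apply(af, 1L, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- NA_real_
    !(mx > af_max) | is.na(mx)
  } else {
    drop <- rowSums(af > af_max, na.rm = TRUE) > 0L
    !drop
  }
}

damaging_call <- function(tool, value) {
  if (is.na(value) || value %in% c("", "NA", ".")) return(NA)
  switch(tool,
    sift = value == "D",
    pp2 = value %in% c("D", "P"),
    mt = value %in% c("A", "D"),
    stop("unknown tool: ", tool, call. = FALSE))
}

#' Deleteriousness call for missense variants
#'
#' A missense variant is deleterious when at least 3 of the 4 prediction
#' tools call it damaging: SIFT `D`; PolyPhen-2 `D` or `P`; MutationTaster
#' `A` or `D`; CADD score strictly above `cadd_min` (default 20). When all
#' four predictions are missing the variant is retained as
#' deleterious-unknown rather than silently dropped.
#'
#' @param sift,pp2,mt character vectors of tool calls (`NA` allowed).
#' @param cadd numeric CADD scores (`NA` allowed).
#' @param min_calls number of damaging calls required (default 3).
#' @param cadd_min CADD damaging threshold (strict `>`).
#' @return data.frame with `n_damaging`, `n_available`, `deleterious`
#'   (logical; `TRUE` also when all four are missing), `unknown` (logical,
#'   all predictions missing).
#' @export
missense_deleterious <- function(sift, pp2, mt, cadd, min_calls = 3L,
                                 cadd_min = 20) {
  n <- length(sift)
  stopifnot(length(pp2) == n, length(mt) == n, length(cadd) == n)
  out <- data.frame(n_damaging = integer(n), n_available = integer(n),
                    deleterious = logical(n), unknown = logical(n))
  for (i in seq_len(n)) {
    calls <- c(damaging_call("sift", as.character(sift[i])),
               damaging_call("pp2", as.character(pp2[i])),
               damaging_call("mt", as.character(mt[i])),
               if (is.na(cadd[i])) NA else cadd[i] > cadd_min)
    out$n_available[i] <- sum(!is.na(calls))
    out$n_damaging[i] <- sum(calls, na.rm = TRUE)
    out$unknown[i] <- out$n_available[i] == 0L
    out$deleterious[i] <- out$unknown[i] || out$n_damaging[i] >= min_calls
  }
  out
}

## trans-partner classes for the compound-heterozygous arm
partner_classes <- c("canonical_splicing", "stop_gain", "stop_loss", "frameshift")

#' Screen a cohort for biallelic/X-linked NCSV candidates
#'
#' For each patient, potential NCSVs (intronic/missense/synonymous variants
#' prioritized by either splicing-score arm) passing the strict allele
#' frequency filter are screened: a homozygous NCSV yields a homozygous
#' candidate; a hemizygous NCSV on the X chromosome in a male yields a
#' hemizygous candidate; a heterozygous NCSV yields a compound-heterozygous
#' candidate when another heterozygous variant in the same gene belongs to
#' the trans-partner class set (canonical splicing, stop gain, stop loss,
#' frameshift, deleterious missense, or another potential NCSV). Partners
#' are frequency-filtered at a lenient threshold (`partner_af_max`).
#' Phase: variants with distinct known haplotype labels are `validated_trans`,
#' identical labels are rejected as cis, otherwise `unknown`.
#'
#' @param calls data.frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `contig`, `gene`, `variant_key`,
#'   `consequence_class`, `zygosity` (`"hom"`/`"het"`/`"hemi"`),
#'   `spliceai`, `spcards`, AF columns (`af*`), predictor columns `sift`,
#'   `pp2`, `mt`, `cadd`, and optionally `haplotype`.
#' @param config a [pipeline_config()].
#' @return data.frame of candidates: `patient_id`, `pattern`
#'   (`homozygous`/`compound_het`/`hemizygous`), `gene`, `variant_key`,
#'   `partner_key`, `phase_status`.
#' @export
inheritance_screen <- function(calls, config = pipeline_config()) {
  req <- c("patient_id", "sex", "contig", "gene", "variant_key",
           "consequence_class", "zygosity", "spliceai", "spcards")
  missing <- setdiff(req, names(calls))
  if (length(missing)) {
    stop("inheritance_screen: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"haplotype" %in% names(calls)) calls$haplotype <- NA_character_
  for (col in c("sift", "pp2", "mt")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_character_
  }
  if (!"cadd" %in% names(calls)) calls$cadd <- NA_real_

  if (any(calls$zygosity == "hemi" &
          (calls$sex != "male" | !calls$contig %in% c("X", "chrX")))) {
    stop("inheritance_screen: hemizygous call off the X or in a female",
         call. = FALSE)
  }

  pri <- prioritize(calls$spliceai, calls$spcards,
                    spcards_min = config$spcards_min,
                    spliceai_min = config$spliceai_min)
  is_ncsv <- pri$prioritized &
    calls$consequence_class %in% c("intronic", "missense", "synonymous")
  keep_strict <- af_filter(calls, af_max = config$af_max)
  keep_lenient <- af_filter(calls, af_max = config$partner_af_max)
  del <- missense_deleterious(calls$sift, calls$pp2, calls$mt, calls$cadd,
                              cadd_min = config$cadd_damaging)
  is_partner <- calls$consequence_class %in% partner_classes |
    (calls$consequence_class == "missense" & del$deleterious) |
    is_ncsv

  out <- list()
  for (pid in sort(unique(calls$patient_id))) {
    rows <- which(calls$patient_id == pid)
    ncsv_rows <- rows[is_ncsv[rows] & keep_strict[rows]]
    for (i in ncsv_rows) {
      zy <- calls$zygosity[i]
      if (zy == "hom") {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, pattern = "homozygous", gene = calls$gene[i],
          variant_key = calls$variant_key[i], partner_key = NA_character_,
          phase_status = "validated_trans", stringsAsFactors = FALSE)
      } else if (zy == "hemi") {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, pattern = "hemizygous", gene = calls$gene[i],
          variant_key = calls$variant_key[i], partner_key = NA_character_,
          phase_status = "validated_trans", stringsAsFactors = FALSE)
      } else {
        partners <- rows[rows != i &
                           calls$gene[rows] == calls$gene[i] &
                           calls$zygosity[rows] == "het" &
                           is_partner[rows] & keep_lenient[rows]]
        for (j in partners) {
          ## emit each unordered pair once: either j is not itself a
          ## screenable NCSV, or i carries the lexicographically smaller
          ## variant key (input-order independent)
          if (is_ncsv[j] && keep_strict[j] &&
              calls$variant_key[j] < calls$variant_key[i]) next
          h1 <- calls$haplotype[i]; h2 <- calls$haplotype[j]
          phase <- if (!is.na(h1) && !is.na(h2)) {
            if (h1 == h2) "cis_rejected" else "validated_trans"
          } else "unknown"
          if (phase == "cis_rejected") next
          out[[length(out) + 1L]] <- data.frame(
            patient_id = pid, pattern = "compound_het", gene = calls$gene[i],
            variant_key = calls$variant_key[i],
            partner_key = calls$variant_key[j],
            phase_status = phase, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(patient_id = character(), pattern = character(),
                      gene = character(), variant_key = character(),
                      partner_key = character(), phase_status = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$patient_id, res$gene, res$variant_key), , drop = FALSE]
}

#' Restrict candidates to a gene panel
#'
#' @param candidates data.frame from [inheritance_screen()].
#' @param panel character vector of gene symbols; an empty panel warns and
#'   passes every candidate through.
#' @return the kept candidates; dropped genes are attached as attribute
#'   `"dropped_genes"`.
#' @export
gene_panel_filter <- function(candidates, panel) {
  if (length(panel) == 0L) {
    warning("gene_panel_filter: empty panel, passing all candidates through")
    attr(candidates, "dropped_genes") <- character()
    return(candidates)
  }
  keep <- candidates$gene %in% panel
  out <- candidates[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- sort(unique(candidates$gene[!keep]))
  out
}
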