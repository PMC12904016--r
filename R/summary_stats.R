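#' Round half-up
#'
#' Decimal rounding where exact halves round away from zero (the style used
#' for printed percentages such as 4.89 or 86.75), unlike base [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a numerator over a denominator
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param digits decimal places (default 2, half-up).
#' @return list with `numerator`, `denominator`, `percent`.
#' @export
#' @examples
#' rate(49, 169)$percent   # 28.99
rate <- function(numerator, denominator, digits = 2L) {
  if (denominator <= 0) stop("rate: denominator must be > 0", call. = FALSE)
  list(numerator = numerator, denominator = denominator,
       percent = round_half_up(100 * numerator / denominator, digits))
}

#' Tally consequence classes over a catalog
#'
#' @param classes character vector of consequence classes (one per variant).
#' @param expected_total optional externally stated catalog size; any
#'   mismatch with the tally sum is reported, not forced.
#' @return list with `tallies` (named integer vector), `total`,
#'   `expected_total`, `discrepancy`.
#' @export
tally_classes <- function(classes, expected_total = NULL) {
  tab <- table(classes)
  tallies <- setNames(as.integer(tab), names(tab))
  total <- sum(tallies)
  list(tallies = tallies, total = total,
       expected_total = expected_total,
       discrepancy = if (is.null(expected_total)) 0L else expected_total - total)
}

#' Share of positives inside splicing consensus regions
#'
#' @param side character vector (`"donor"`/`"acceptor"`) per variant.
#' @param distance signed junction distances per variant.
#' @param donor_window,acceptor_window consensus windows.
#' @return list with `n_in`, `n_total`, `percent` (2 dp half-up).
#' @export
consensus_share <- function(side, distance, donor_window = c(-3L, 8L),
                            acceptor_window = c(-12L, 2L)) {
  stopifnot(length(side) == length(distance))
  if (length(side) == 0L) stop("consensus_share: empty input", call. = FALSE)
  flags <- mapply(in_consensus_window, side, distance,
                  MoreArgs = list(donor_window = donor_window,
                                  acceptor_window = acceptor_window))
  r <- rate(sum(flags), length(flags))
  list(n_in = r$numerator, n_total = r$denominator, percent = r$percent,
       in_consensus = unname(flags))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration (sum over tables with the
#' observed margins whose probability does not exceed the observed table's,
#' with the conventional 1e-7 relative tolerance for floating-point ties).
#' The odds ratio is the conditional maximum-likelihood estimate and the
#' 95% CI the exact conditional interval. Degenerate margins give `p = 1`
#' and an undefined odds ratio.
#'
#' @param tab 2x2 matrix of non-negative counts (rows e.g. exonic/intronic,
#'   columns positive/negative).
#' @param conf_level confidence level (default 0.95).
#' @param or compute the odds ratio and CI (set `FALSE` for a p-value-only
#'   call, e.g. in large enumeration sweeps).
#' @return list with `p`, `or`, `ci` (length 2), `or_defined`.
#' @export
#' @examples
#' fisher_exact(matrix(c(1, 1, 1, 1), 2))   # p = 1, OR = 1
fisher_exact <- function(tab, conf_level = 0.95, or = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), sum(tab) > 0)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0L || n == 0L || k == 0L || sum(tab[, 2]) == 0L) {
    return(list(p = 1, or = NA_real_, ci = c(NA_real_, NA_real_),
                or_defined = FALSE))
  }
  support <- max(0L, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  p <- sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  p <- min(1, p)
  if (!or) {
    return(list(p = p, or = NA_real_, ci = c(NA_real_, NA_real_),
                or_defined = NA))
  }
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  list(p = p, or = unname(ft$estimate), ci = unname(ft$conf.int),
       or_defined = is.finite(ft$estimate))
}

#' Pearson correlation between two prediction scores
#'
#' Rows with a missing score in either column are excluded pairwise; at
#' least 3 complete pairs are required and a constant column is flagged
#' undefined.
#'
#' @param x,y numeric score vectors of equal length.
#' @return list with `r`, `p`, `n`, `defined`.
#' @export
score_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("score_correlation: need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Headline catalog/cohort rates
#'
#' Computes the standard summary fractions of an NCSV analysis from stage
#' counts: share of splicing variants that are non-canonical, expansion of
#' the known NCSV set, validation-positive rate, prioritization positive
#' rate, and cohort prevalence. Every rate carries its numerator and
#' denominator.
#'
#' @param counts named list/vector with elements `ncsv_positive_total`,
#'   `splicing_total`, `ncsv_new`, `ncsv_previous`, `validated_positive`,
#'   `validated_assayed`, `prioritized_positive`, `prioritized_assayed`,
#'   `cohort_carriers`, `cohort_size`.
#' @return data.frame with columns `measure`, `numerator`, `denominator`,
#'   `percent`.
#' @export
headline_rates <- function(counts) {
  counts <- as.list(counts)
  need <- c("ncsv_positive_total", "splicing_total", "ncsv_new",
            "ncsv_previous", "validated_positive", "validated_assayed",
            "prioritized_positive", "prioritized_assayed",
            "cohort_carriers", "cohort_size")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("headline_rates: missing counts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list(
    c("ncsv_share_of_splicing", counts$ncsv_positive_total, counts$splicing_total),
    c("expansion_percent", counts$ncsv_new, counts$ncsv_previous),
    c("validation_rate", counts$validated_positive, counts$validated_assayed),
    c("prioritization_positive_rate", counts$prioritized_positive,
      counts$prioritized_assayed),
    c("cohort_prevalence", counts$cohort_carriers, counts$cohort_size)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    rr <- rate(as.numeric(r[2]), as.numeric(r[3]))
    data.frame(measure = r[1], numerator = rr$numerator,
               denominator = rr$denominator, percent = rr$percent,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
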