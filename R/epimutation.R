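# Epimutation statistics: classification against bulk, rates, the exact
# two-sided test of methylating events against the non-conversion
# background, and the region summary table.

.EPI_CLASSES <- c("DEMETHYLATING", "METHYLATING", "CONCORDANT",
                  "NOT_EVALUABLE")

#' Classify a methylation call against the bulk baseline
#'
#' A bulk-methylated CpG observed `UNMETHYLATED` or `HEMI` is a
#' `DEMETHYLATING` epimutation; a bulk-unmethylated CpG observed
#' `METHYLATED` or `HEMI` is `METHYLATING`. An `AMBIGUOUS` call, or a
#' `MIXED` bulk CpG, is `NOT_EVALUABLE`; everything else is `CONCORDANT`.
#' A `HEMI` call counts as a single event: unless two peaks are clearly
#' distinguished, only one allele is assumed represented, so each
#' discordant cell-CpG contributes exactly one event regardless of
#' alleles.
#'
#' @param call_state Character vector of call states (`METHYLATED`,
#'   `UNMETHYLATED`, `HEMI`, `AMBIGUOUS`).
#' @param bulk_status Character vector of bulk statuses (`METHYLATED`,
#'   `UNMETHYLATED`, `MIXED`), recycled against `call_state`.
#' @return Character vector of classes.
#' @export
classify_cpg <- function(call_state, bulk_status) {
  stopifnot(all(call_state %in% .CALL_STATES),
            all(bulk_status %in% .BULK_STATUSES))
  n <- max(length(call_state), length(bulk_status))
  call_state <- rep_len(call_state, n)
  bulk_status <- rep_len(bulk_status, n)
  out <- rep("CONCORDANT", n)
  out[bulk_status == "METHYLATED" &
        call_state %in% c("UNMETHYLATED", "HEMI")] <- "DEMETHYLATING"
  out[bulk_status == "UNMETHYLATED" &
        call_state %in% c("METHYLATED", "HEMI")] <- "METHYLATING"
  out[call_state == "AMBIGUOUS" | bulk_status == "MIXED"] <- "NOT_EVALUABLE"
  out
}

#' Epimutation rate
#'
#' The number of altered CpG methylation sites over the total number of
#' CpGs analysed, as a percentage.
#'
#' @param n_events Event count.
#' @param n_total Total evaluable CpGs (> 0).
#' @return The unrounded percentage. Use [format_percent()] for the
#'   one-decimal display form.
#' @examples
#' epimutation_rate(16, 601)                  # 2.6622...
#' format_percent(epimutation_rate(16, 601))  # "2.7"
#' @export
epimutation_rate <- function(n_events, n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || is.na(n_total) ||
      n_total <= 0)
    stop(errorCondition("epimutation rate undefined: n_total must be > 0",
                        class = "slbs_undefined_rate"))
  stopifnot(is.numeric(n_events), length(n_events) == 1L, n_events >= 0,
            n_events <= n_total)
  100 * n_events / n_total
}

#' Format a percentage, rounding half away from zero
#'
#' One decimal by default. Rounding half away from zero (2.65 -> "2.7") is
#' used rather than banker's rounding so that display values are stable
#' and predictable; unrounded values are always reported alongside.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 1L) {
  f <- 10^digits
  sprintf(paste0("%.", digits, "f"), sign(x) * floor(abs(x) * f + 0.5) / f)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-sided
#' definition: the p-value is the sum of the probabilities of all tables
#' with the observed margins whose point probability does not exceed that
#' of the observed table (a relative tolerance of 1e-7 guards ties against
#' floating-point noise). This is the most common convention (mid-p and
#' one-sided variants differ).
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`; all
#'   non-negative, grand total at least 1.
#' @param rel_tol Relative tie tolerance on point probabilities.
#' @return The p-value, in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  counts <- c(a, b, c, d)
  if (!is.numeric(counts) || length(counts) != 4L || anyNA(counts) ||
      any(counts < 0) || any(counts != floor(counts)))
    stop("a, b, c, d must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("grand total must be at least 1", call. = FALSE)
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  lp_obs <- lp[xs == a]
  p <- sum(exp(lp[lp <= lp_obs + log1p(rel_tol)]))
  min(1, p)
}

#' Test methylating events against the non-conversion background
#'
#' A methylating "event" (an unconverted cytosine at a bulk-unmethylated
#' CpG) is indistinguishable, read by read, from a bisulfite conversion
#' failure. This test asks whether methylating events occur significantly
#' more often than non-CpG cytosines escape conversion, via
#' [fisher_exact_two_sided()] on the table
#' `rbind(c(n_methylating, total_cpgs - n_methylating),
#'        c(non_cpg_nonconverted, non_cpg_converted))`.
#'
#' @param n_methylating Methylating event count, or an `slbs_summary`
#'   object (see [summarize_epimutations()]), in which case the remaining
#'   arguments are taken from its totals row.
#' @param total_cpgs Total evaluable CpGs.
#' @param non_cpg_converted,non_cpg_total Pooled non-CpG conversion counts.
#' @return List with `table` (the 2x2 matrix) and `p_value`.
#' @export
significance_vs_nonconversion <- function(n_methylating, total_cpgs = NULL,
                                          non_cpg_converted = NULL,
                                          non_cpg_total = NULL) {
  if (inherits(n_methylating, "slbs_summary")) {
    tt <- n_methylating$totals
    if (is.null(tt))
      stop("summary has no totals row", call. = FALSE)
    total_cpgs <- tt$total_cpgs
    non_cpg_converted <- tt$non_cpg_converted
    non_cpg_total <- tt$non_cpg_total
    n_methylating <- tt$n_methylating
  }
  tab <- matrix(c(n_methylating, total_cpgs - n_methylating,
                  non_cpg_total - non_cpg_converted, non_cpg_converted),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("cpg_sites", "non_cpg_background"),
                                c("event", "no_event")))
  list(table = tab,
       p_value = fisher_exact_two_sided(tab[1L, 1L], tab[1L, 2L],
                                        tab[2L, 1L], tab[2L, 2L]))
}

#' Summarise epimutation calls per region
#'
#' Applies the conversion-QC filter, classifies every retained call
#' against the bulk profile, and aggregates per gene region: cells
#' analysed, evaluable CpGs, demethylating and methylating event counts,
#' and pooled non-CpG conversion counts. A totals row carries both
#' epimutation rates (unrounded and display-rounded; the denominator for
#' both is the total evaluable CpGs across all regions) and the pooled
#' conversion rate. Regions are ordered by name.
#'
#' @param calls Call data frame (see [call_methylation()]).
#' @param qc QC data frame (see [call_methylation()]).
#' @param bulk Bulk profile data frame covering every locus called.
#' @param min_conversion QC threshold passed to [qc_filter()].
#' @return An object of class `slbs_summary`: list with `regions` (one row
#'   per region), `totals` (one row, `NULL` for empty input) and
#'   `n_rejected_qc`.
#' @export
summarize_epimutations <- function(calls, qc, bulk, min_conversion = 0.95) {
  empty <- (is.null(calls) || nrow(calls) == 0L) &&
    (is.null(qc) || nrow(qc) == 0L)
  if (empty) {
    regions <- data.frame(gene_region = character(0),
                          n_cpgs_per_region = integer(0),
                          n_cells_analyzed = integer(0),
                          total_cpgs = integer(0),
                          n_demethylating = integer(0),
                          n_methylating = integer(0),
                          non_cpg_converted = integer(0),
                          non_cpg_total = integer(0))
    return(structure(list(regions = regions, totals = NULL,
                          n_rejected_qc = 0L), class = "slbs_summary"))
  }
  key <- function(d) paste(d$cell_id, d$locus, sep = "\r")
  if (!all(key(calls) %in% key(qc)))
    stop(errorCondition(
      "orphan calls: every cell-locus in `calls` must appear in `qc`",
      class = "slbs_consistency_error"))
  qc <- qc_filter(qc, min_conversion)
  qr <- qc[qc$retained, , drop = FALSE]
  calls_r <- calls[key(calls) %in% key(qr), , drop = FALSE]
  bkey <- paste(bulk$locus, bulk$cpg_index)
  ckey <- paste(calls_r$locus, calls_r$cpg_index)
  if (!all(ckey %in% bkey))
    stop(errorCondition(
      "bulk profile does not cover every called CpG",
      class = "slbs_incomplete_profile"))
  calls_r$bulk_status <- bulk$status[match(ckey, bkey)]
  calls_r$class <- classify_cpg(calls_r$state, calls_r$bulk_status)

  region_names <- sort(unique(c(bulk$locus, qc$locus)))
  rows <- lapply(region_names, function(g) {
    qg <- qr[qr$locus == g, , drop = FALSE]
    cg <- calls_r[calls_r$locus == g, , drop = FALSE]
    data.frame(
      gene_region = g,
      n_cpgs_per_region = sum(bulk$locus == g),
      n_cells_analyzed = length(unique(qg$cell_id)),
      total_cpgs = sum(cg$class != "NOT_EVALUABLE"),
      n_demethylating = sum(cg$class == "DEMETHYLATING"),
      n_methylating = sum(cg$class == "METHYLATING"),
      non_cpg_converted = sum(qg$n_converted),
      non_cpg_total = sum(qg$n_total))
  })
  regions <- do.call(rbind, rows)
  tot_cpgs <- sum(regions$total_cpgs)
  dem <- sum(regions$n_demethylating)
  met <- sum(regions$n_methylating)
  conv <- sum(regions$non_cpg_converted)
  convtot <- sum(regions$non_cpg_total)
  totals <- data.frame(
    gene_region = "TOTAL",
    n_cpgs_per_region = sum(regions$n_cpgs_per_region),
    n_cells_analyzed = sum(regions$n_cells_analyzed),
    total_cpgs = tot_cpgs,
    n_demethylating = dem,
    n_methylating = met,
    non_cpg_converted = conv,
    non_cpg_total = convtot,
    demethylating_rate_pct =
      if (tot_cpgs > 0) epimutation_rate(dem, tot_cpgs) else NA_real_,
    methylating_rate_pct =
      if (tot_cpgs > 0) epimutation_rate(met, tot_cpgs) else NA_real_,
    conversion_rate_pct =
      if (convtot > 0) 100 * conv / convtot else NA_real_)
  totals$demethylating_rate_label <-
    if (is.na(totals$demethylating_rate_pct)) NA_character_
    else format_percent(totals$demethylating_rate_pct)
  totals$methylating_rate_label <-
    if (is.na(totals$methylating_rate_pct)) NA_character_
    else format_percent(totals$methylating_rate_pct)
  structure(list(regions = regions, totals = totals,
                 n_rejected_qc = sum(!qc$retained)),
            class = "slbs_summary")
}

#' @export
print.slbs_summary <- function(x, ...) {
  cat("<slbs_summary>\n")
  print(x$regions, row.names = FALSE)
  if (!is.null(x$totals)) {
    t <- x$totals
    cat(sprintf(
      "totals: %d cells, %d CpGs | demethylating %d (%s%%), methylating %d (%s%%) | conversion %d/%d (%.2f%%)\n",
      t$n_cells_analyzed, t$total_cpgs, t$n_demethylating,
      t$demethylating_rate_label, t$n_methylating,
      t$methylating_rate_label, t$non_cpg_converted, t$non_cpg_total,
      t$conversion_rate_pct))
  }
  if (x$n_rejected_qc > 0L)
    cat(sprintf("(%d cell-locus pairs rejected by conversion QC)\n",
                x$n_rejected_qc))
  invisible(x)
}
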