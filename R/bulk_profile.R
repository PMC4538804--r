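# Bulk methylation profiles: the tissue-level baseline each single cell is
# compared against.

.BULK_STATUSES <- c("METHYLATED", "UNMETHYLATED", "MIXED")

#' Construct a bulk methylation profile for one locus
#'
#' The bulk profile records, for every CpG of an amplicon, whether the
#' tissue (or mother cell population) is methylated, unmethylated, or mixed
#' at that site. `MIXED` CpGs (partial methylation in bulk, e.g. midway
#' through a 5-Aza time course) are valid input but are excluded from
#' epimutation calling downstream: epimutations are only defined against a
#' clearly hyper- or hypomethylated baseline.
#'
#' @param locus Amplicon name the profile belongs to.
#' @param status Character vector, one of `METHYLATED`, `UNMETHYLATED`,
#'   `MIXED` per CpG, in CpG order.
#' @param methylated_fraction Optional numeric vector in `[0, 1]`.
#'   Required (strictly between 0 and 1) for `MIXED` CpGs; for
#'   `METHYLATED`/`UNMETHYLATED` it is implied (1/0) and filled in.
#' @return A data frame with columns `locus`, `cpg_index` (0-based),
#'   `status`, `methylated_fraction`.
#' @examples
#' bulk_profile("Nfe2l2", rep("UNMETHYLATED", 4))
#' @export
bulk_profile <- function(locus, status, methylated_fraction = NULL) {
  stopifnot(is.character(locus), length(locus) == 1L, nzchar(locus),
            is.character(status), length(status) >= 1L)
  if (!all(status %in% .BULK_STATUSES))
    stop("status values must be one of: ",
         paste(.BULK_STATUSES, collapse = ", "), call. = FALSE)
  n <- length(status)
  mf <- if (is.null(methylated_fraction)) rep(NA_real_, n)
        else as.numeric(methylated_fraction)
  stopifnot(length(mf) == n)
  mf[status == "METHYLATED" & is.na(mf)] <- 1
  mf[status == "UNMETHYLATED" & is.na(mf)] <- 0
  if (any(status == "METHYLATED" & mf != 1) ||
      any(status == "UNMETHYLATED" & mf != 0))
    stop("METHYLATED/UNMETHYLATED imply methylated_fraction 1/0",
         call. = FALSE)
  mixed <- status == "MIXED"
  if (any(mixed & (is.na(mf) | mf <= 0 | mf >= 1)))
    stop("MIXED CpGs require methylated_fraction strictly between 0 and 1",
         call. = FALSE)
  data.frame(locus = locus, cpg_index = seq_len(n) - 1L, status = status,
             methylated_fraction = mf)
}

#' Uniform bulk profile helper
#'
#' @param locus Amplicon name.
#' @param n_cpgs Number of CpGs in the amplicon.
#' @param status Single status applied to every CpG.
#' @return A bulk profile data frame (see [bulk_profile()]).
#' @export
uniform_bulk_profile <- function(locus, n_cpgs, status) {
  bulk_profile(locus, rep(status, n_cpgs))
}

# Subset a (possibly multi-locus) bulk profile table to one amplicon and
# verify that it covers every CpG exactly once, in order.
.bulk_for_locus <- function(bulk, amplicon) {
  b <- bulk[bulk$locus == amplicon$name, , drop = FALSE]
  b <- b[order(b$cpg_index), , drop = FALSE]
  k <- length(amplicon$cpg_positions)
  if (nrow(b) != k || !identical(as.integer(b$cpg_index), seq_len(k) - 1L))
    stop(errorCondition(
      sprintf("bulk profile for locus '%s' does not cover its %d CpGs",
              amplicon$name, k),
      class = "slbs_incomplete_profile"))
  rownames(b) <- NULL
  b
}

#' Read / write a bulk profile TSV
#'
#' The on-disk format is a tab-separated table with columns `locus`,
#' `cpg_index` (0-based), `status`, `methylated_fraction`; lines starting
#' with `#` are provenance comments.
#'
#' @param path File path.
#' @return `read_bulk_profile()` returns the bulk profile data frame.
#' @export
read_bulk_profile <- function(path) {
  b <- .read_tsv(path)
  need <- c("locus", "cpg_index", "status", "methylated_fraction")
  if (!all(need %in% names(b)))
    stop("bulk profile TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  b$cpg_index <- as.integer(b$cpg_index)
  b$methylated_fraction <- as.numeric(b$methylated_fraction)
  b[need]
}

#' @rdname read_bulk_profile
#' @param bulk Bulk profile data frame.
#' @param provenance Optional character vector of `#`-comment header lines.
#' @export
write_bulk_profile <- function(bulk, path, provenance = NULL) {
  .write_tsv(bulk, path, provenance)
  invisible(path)
}
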