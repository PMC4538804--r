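# Methylation calling: anchor each consensus read to its conversion-
# specific reference, call per-CpG states, and compute non-CpG conversion
# QC.

.CALL_STATES <- c("METHYLATED", "UNMETHYLATED", "HEMI", "AMBIGUOUS")

.base_to_state <- function(base) {
  ifelse(is.na(base), "AMBIGUOUS",
  ifelse(base == "C", "METHYLATED",
  ifelse(base == "T", "UNMETHYLATED",
  ifelse(base == "Y", "HEMI", "AMBIGUOUS"))))
}

#' Anchor a read to its amplicon reference
#'
#' Globally aligns the read against the fully converted reference (all
#' cytosines replaced by T) with match +1, mismatch -1, gap -2. Reference
#' cytosine positions (CpG and non-CpG alike) are wildcards that match
#' `C`, `T` or `Y` -- their read-out carries the methylation signal and
#' must not count against the anchor. The read is accepted if identity
#' over the aligned non-wildcard columns is at least `min_identity`;
#' otherwise a `slbs_locus_mismatch` error is raised.
#'
#' Alignment ties are broken deterministically: a mismatch is preferred
#' over a gap, and a gap in the reference over a gap in the read, so that
#' identical inputs always give byte-identical outputs. A read identical
#' in length to the reference and matching at every column takes a fast
#' path that skips the dynamic program.
#'
#' @param read IUPAC read string (non-empty).
#' @param amplicon An [amplicon()] object.
#' @param min_identity Minimum identity over non-wildcard aligned columns
#'   (default 0.90).
#' @return An object of class `slbs_anchor`: list with `ref_to_read` and
#'   `read_to_ref` (1-based index maps, `NA` where gapped; both monotone),
#'   `identity` and `n_mismatch`.
#' @export
anchor_read <- function(read, amplicon, min_identity = 0.90) {
  stopifnot(inherits(amplicon, "slbs_amplicon"))
  if (!is.character(read) || length(read) != 1L || is.na(read) ||
      !nzchar(read))
    stop("read must be a non-empty string", call. = FALSE)
  read <- toupper(read)
  ref <- amplicon$sequence
  m <- nchar(ref)
  cchars <- .chars(bisulfite_convert(ref))
  wild <- rep(FALSE, m)
  wild[c(amplicon$cpg_positions, amplicon$non_cpg_c_positions) + 1L] <- TRUE
  rchars <- .chars(read)
  n <- length(rchars)

  # fast path: equal length, every non-wildcard column an exact match and
  # every wildcard column C/T/Y/N. The positional alignment is then the
  # unique dynamic-program optimum (any gap pair costs more than any
  # wildcard mismatch), so the DP is skipped; N columns still count as
  # mismatches.
  if (n == m) {
    okw <- wild & rchars %in% c("C", "T", "Y", "N")
    if (all(okw | (!wild & rchars == cchars)))
      return(structure(list(ref_to_read = seq_len(m),
                            read_to_ref = seq_len(m),
                            identity = 1,
                            n_mismatch = sum(wild & rchars == "N")),
                       class = "slbs_anchor"))
  }

  gap <- -2
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- gap * (0:m)
  S[, 1L] <- gap * (0:n)
  ctly <- c("C", "T", "Y")
  for (i in seq_len(n)) {
    sc <- ifelse(wild, rchars[i] %in% ctly, rchars[i] == cchars) * 2 - 1
    prev <- S[i, ]
    row <- S[i + 1L, ]
    for (j in seq_len(m)) {
      row[j + 1L] <- max(prev[j] + sc[j], prev[j + 1L] + gap,
                         row[j] + gap)
    }
    S[i + 1L, ] <- row
  }

  # traceback; preference: diagonal (mismatch over gap), then gap in the
  # reference (consume read), then gap in the read
  ref_to_read <- rep(NA_integer_, m)
  read_to_ref <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sc <- if (wild[j]) (rchars[i] %in% ctly) * 2 - 1
            else (rchars[i] == cchars[j]) * 2 - 1
      if (S[i + 1L, j + 1L] == S[i, j] + sc) {
        ref_to_read[j] <- i
        read_to_ref[i] <- j
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }

  aligned <- which(!is.na(ref_to_read))
  nonwild <- aligned[!wild[aligned]]
  matches <- sum(rchars[ref_to_read[nonwild]] == cchars[nonwild])
  identity <- if (length(nonwild)) matches / length(nonwild) else 1
  wildok <- sum(rchars[ref_to_read[aligned[wild[aligned]]]] %in% ctly)
  n_mismatch <- (length(nonwild) - matches) +
    (sum(wild[aligned]) - wildok)
  if (identity < min_identity)
    stop(errorCondition(
      sprintf("read does not anchor to locus '%s' (identity %.3f < %.3f)",
              amplicon$name, identity, min_identity),
      class = "slbs_locus_mismatch"))
  structure(list(ref_to_read = ref_to_read, read_to_ref = read_to_ref,
                 identity = identity, n_mismatch = as.integer(n_mismatch)),
            class = "slbs_anchor")
}

#' Call per-CpG methylation states for one read
#'
#' One call per CpG of the amplicon: `C` reads as `METHYLATED`, `T` as
#' `UNMETHYLATED`, `Y` (overlapping C+T peak) as `HEMI`; any other base,
#' or a CpG not covered by the alignment, is `AMBIGUOUS`.
#'
#' @param read IUPAC read string.
#' @param anchor The accepted [anchor_read()] result for this read.
#' @param amplicon An [amplicon()] object.
#' @param cell_id Cell identifier to stamp on the calls.
#' @return Data frame with columns `cell_id`, `locus`, `cpg_index`
#'   (0-based ordinal), `position` (0-based amplicon offset),
#'   `observed_base`, `state`.
#' @export
call_cpg_states <- function(read, anchor, amplicon,
                            cell_id = NA_character_) {
  stopifnot(inherits(anchor, "slbs_anchor"),
            inherits(amplicon, "slbs_amplicon"))
  rchars <- .chars(toupper(read))
  pos <- amplicon$cpg_positions
  ridx <- anchor$ref_to_read[pos + 1L]
  base <- ifelse(is.na(ridx), NA_character_, rchars[ifelse(is.na(ridx), 1L,
                                                           ridx)])
  data.frame(cell_id = cell_id, locus = amplicon$name,
             cpg_index = seq_along(pos) - 1L, position = pos,
             observed_base = ifelse(is.na(base), "-", base),
             state = .base_to_state(base))
}

#' Compute per-read non-CpG conversion QC
#'
#' Over the non-CpG cytosine positions covered by the alignment: a `T`
#' counts as converted; `C` or `Y` as non-converted (`Y` conservatively,
#' since at least one allele escaped conversion); any other base or a gap
#' is excluded from the denominator. The resulting rate is the assay's
#' internal bisulfite-efficiency control.
#'
#' @inheritParams call_cpg_states
#' @return One-row data frame with columns `cell_id`, `locus`,
#'   `n_converted`, `n_total`, `rate` (`NA` when no non-CpG cytosine is
#'   evaluable -- the QC-undefined case).
#' @export
compute_conversion_qc <- function(read, anchor, amplicon,
                                  cell_id = NA_character_) {
  stopifnot(inherits(anchor, "slbs_anchor"),
            inherits(amplicon, "slbs_amplicon"))
  rchars <- .chars(toupper(read))
  np <- amplicon$non_cpg_c_positions
  ridx <- anchor$ref_to_read[np + 1L]
  base <- rchars[ridx[!is.na(ridx)]]
  n_converted <- sum(base == "T")
  n_total <- n_converted + sum(base %in% c("C", "Y"))
  data.frame(cell_id = cell_id, locus = amplicon$name,
             n_converted = n_converted, n_total = n_total,
             rate = if (n_total > 0L) n_converted / n_total else NA_real_)
}

#' Filter cell-locus pairs on conversion QC
#'
#' Retains pairs whose conversion rate is at least `min_rate`, plus
#' QC-undefined pairs (no evaluable non-CpG cytosine: retained but
#' unscored). The default 0.95 cleanly separates an optimized bisulfite
#' regime (conversion ~0.99) from an under-converted one (~0.80).
#'
#' @param qc QC data frame from [compute_conversion_qc()] /
#'   [call_methylation()].
#' @param min_rate Minimum acceptable conversion rate in `[0, 1]`.
#' @return The QC data frame with a logical `retained` column added.
#' @export
qc_filter <- function(qc, min_rate = 0.95) {
  .check_prob(min_rate, "min_rate")
  qc$retained <- is.na(qc$rate) | qc$rate >= min_rate
  qc
}

#' Call methylation for a set of reads
#'
#' Anchors every read to its amplicon (by the `locus:` field of the read
#' header), calls CpG states and computes conversion QC. Reads that fail
#' to anchor, or whose locus is unknown, are collected in `rejected`
#' rather than aborting the run.
#'
#' @param reads Named character vector of IUPAC reads (headers
#'   `cell:<id>|locus:<name>|...`; a bare header is taken as the cell id,
#'   with the locus defaulting to the single amplicon if only one is
#'   given).
#' @param amplicons List of [amplicon()] objects (or a single one).
#' @param min_identity Passed to [anchor_read()].
#' @return List with `calls` (see [call_cpg_states()]), `qc` (see
#'   [compute_conversion_qc()]) and `rejected` (data frame `cell_id`,
#'   `locus`, `reason`).
#' @export
call_methylation <- function(reads, amplicons, min_identity = 0.90) {
  amplicons <- .as_amplicon_list(amplicons)
  calls <- list(); qcs <- list(); rej <- list()
  for (h in names(reads)) {
    meta <- .parse_read_header(h)
    locus <- meta$locus
    if (is.na(locus) && length(amplicons) == 1L)
      locus <- names(amplicons)[1L]
    if (is.na(locus) || !locus %in% names(amplicons)) {
      rej[[length(rej) + 1L]] <- data.frame(
        cell_id = meta$cell_id, locus = ifelse(is.na(locus), "?", locus),
        reason = "unknown-locus")
      next
    }
    amp <- amplicons[[locus]]
    anc <- tryCatch(anchor_read(reads[[h]], amp, min_identity),
                    slbs_locus_mismatch = function(e) e)
    if (inherits(anc, "condition")) {
      rej[[length(rej) + 1L]] <- data.frame(
        cell_id = meta$cell_id, locus = locus,
        reason = conditionMessage(anc))
      next
    }
    calls[[length(calls) + 1L]] <- call_cpg_states(reads[[h]], anc, amp,
                                                   meta$cell_id)
    qcs[[length(qcs) + 1L]] <- compute_conversion_qc(reads[[h]], anc, amp,
                                                     meta$cell_id)
  }
  empty_calls <- data.frame(cell_id = character(0), locus = character(0),
                            cpg_index = integer(0), position = integer(0),
                            observed_base = character(0),
                            state = character(0))
  empty_qc <- data.frame(cell_id = character(0), locus = character(0),
                         n_converted = integer(0), n_total = integer(0),
                         rate = numeric(0))
  list(
    calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
    qc = if (length(qcs)) do.call(rbind, qcs) else empty_qc,
    rejected = if (length(rej)) do.call(rbind, rej)
               else data.frame(cell_id = character(0), locus = character(0),
                               reason = character(0)))
}
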