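# Stochastic simulator: diploid single cells sampled from a bulk profile,
# with per-allele epimutations, bisulfite chemistry errors, MDA allelic
# dropout, amplicon dropout, and an optional 5-Aza demethylation time
# course. Every planted event is logged in a truth ledger.

.EVENT_KINDS <- c("DEMETHYLATING_EPIMUTATION", "METHYLATING_EPIMUTATION",
                  "CONVERSION_FAILURE", "OVERCONVERSION", "ALLELIC_DROPOUT",
                  "AMPLICON_DROPOUT", "NON_CPG_METHYLATION")

.empty_ledger <- function() {
  data.frame(cell_id = character(0), locus = character(0),
             allele_index = integer(0), position = integer(0),
             event_kind = character(0))
}

.ledger_row <- function(cell_id, locus, allele_index, position, event_kind) {
  data.frame(cell_id = cell_id, locus = locus,
             allele_index = as.integer(allele_index),
             position = as.integer(position), event_kind = event_kind)
}

.bind_ledger <- function(pieces) {
  pieces <- pieces[vapply(pieces, function(p) !is.null(p) && nrow(p) > 0, TRUE)]
  if (!length(pieces)) return(.empty_ledger())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  x
}

#' Simulation configuration
#'
#' All stochastic model parameters of the single-cell bisulfite read
#' simulator. Defaults reflect the magnitudes reported for the optimized
#' single-cell protocol: ~0.5\% of unmethylated cytosines escape
#' conversion, a small over-conversion of 5-methylcytosine, single-allele
#' (MDA-biased) amplification in ~10\% of cell-locus pairs, and a PCR
#' product in ~40\% of single cells (use `amplicon_success_prob = 0.99` for
#' the 100-cell control regime).
#'
#' @param n_cells Number of cells to simulate.
#' @param ploidy Alleles per cell (default 2; use 1 for parameter-recovery
#'   studies where each observed unit is a single allele).
#' @param rate_demethylating Per-allele probability that a bulk-methylated
#'   CpG loses methylation.
#' @param rate_methylating Per-allele probability that a bulk-unmethylated
#'   CpG gains methylation.
#' @param conversion_failure_rate Probability an unmethylated cytosine is
#'   NOT converted (reads C; a false methylation signal).
#' @param overconversion_rate Probability a methylated cytosine IS
#'   converted (reads T; a false demethylation signal).
#' @param allelic_dropout_prob Probability a cell-locus pair amplifies from
#'   one allele only.
#' @param amplicon_success_prob Probability a cell-locus pair yields any
#'   PCR product at all.
#' @param non_cpg_methylation_rate Probability a non-CpG cytosine is
#'   methylated (CHH methylation; reads C, indistinguishable from a
#'   conversion failure in this assay).
#' @param seed Integer RNG seed; the whole simulation is reproducible
#'   from it.
#' @return An object of class `slbs_config` (a validated list).
#' @export
simulation_config <- function(n_cells,
                              ploidy = 2L,
                              rate_demethylating = 0,
                              rate_methylating = 0,
                              conversion_failure_rate = 0.005,
                              overconversion_rate = 0.002,
                              allelic_dropout_prob = 0.10,
                              amplicon_success_prob = 0.40,
                              non_cpg_methylation_rate = 0,
                              seed = 1L) {
  n_cells <- as.integer(n_cells)
  ploidy <- as.integer(ploidy)
  stopifnot(length(n_cells) == 1L, n_cells >= 1L,
            length(ploidy) == 1L, ploidy >= 1L)
  .check_prob(rate_demethylating, "rate_demethylating")
  .check_prob(rate_methylating, "rate_methylating")
  .check_prob(conversion_failure_rate, "conversion_failure_rate")
  .check_prob(overconversion_rate, "overconversion_rate")
  .check_prob(allelic_dropout_prob, "allelic_dropout_prob")
  .check_prob(amplicon_success_prob, "amplicon_success_prob")
  .check_prob(non_cpg_methylation_rate, "non_cpg_methylation_rate")
  structure(list(
    n_cells = n_cells, ploidy = ploidy,
    rate_demethylating = rate_demethylating,
    rate_methylating = rate_methylating,
    conversion_failure_rate = conversion_failure_rate,
    overconversion_rate = overconversion_rate,
    allelic_dropout_prob = allelic_dropout_prob,
    amplicon_success_prob = amplicon_success_prob,
    non_cpg_methylation_rate = non_cpg_methylation_rate,
    seed = as.integer(seed)
  ), class = "slbs_config")
}

.default_cell_ids <- function(n) {
  sprintf(paste0("c%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' Draw per-cell, per-allele CpG methylation states
#'
#' Each allele starts from the bulk status of its CpG and is flipped
#' independently: methylated-to-unmethylated with `rate_demethylating`,
#' unmethylated-to-methylated with `rate_methylating`. `MIXED` bulk CpGs
#' are drawn methylated with their `methylated_fraction` and receive no
#' epimutation flip. Every flip is logged in the truth ledger.
#'
#' Uses the current global RNG stream; seed it (or call through
#' [simulate_experiment()], which seeds from `config$seed`).
#'
#' @param bulk Bulk profile data frame for one locus (see [bulk_profile()]).
#' @param config An [simulation_config()] object.
#' @param amplicon Optional [amplicon()]; if supplied, ledger positions are
#'   amplicon offsets of the CpGs (otherwise the CpG ordinal is recorded).
#' @param cell_ids Optional character vector of cell ids.
#' @return List with `states` (logical array cell x allele x CpG; `TRUE` =
#'   methylated), `cell_ids`, and `ledger` (truth ledger data frame).
#' @export
simulate_cell_allele_states <- function(bulk, config, amplicon = NULL,
                                        cell_ids = NULL) {
  stopifnot(inherits(config, "slbs_config"))
  locus <- as.character(bulk$locus[1L])
  if (!is.null(amplicon)) {
    bulk <- .bulk_for_locus(bulk, amplicon)
    pos <- amplicon$cpg_positions
  } else {
    bulk <- bulk[order(bulk$cpg_index), , drop = FALSE]
    pos <- as.integer(bulk$cpg_index)
  }
  n <- config$n_cells
  pl <- config$ploidy
  k <- nrow(bulk)
  if (is.null(cell_ids)) cell_ids <- .default_cell_ids(n)
  states <- array(FALSE, dim = c(n, pl, k))
  ledger <- list()
  for (j in seq_len(k)) {
    st <- bulk$status[j]
    if (st == "MIXED") {
      states[, , j] <- matrix(runif(n * pl) < bulk$methylated_fraction[j],
                              n, pl)
      next
    }
    base <- st == "METHYLATED"
    rate <- if (base) config$rate_demethylating else config$rate_methylating
    flip <- matrix(runif(n * pl) < rate, n, pl)
    states[, , j] <- xor(base, flip)
    if (any(flip)) {
      idx <- which(flip, arr.ind = TRUE)
      ledger[[length(ledger) + 1L]] <- .ledger_row(
        cell_ids[idx[, 1L]], locus, idx[, 2L], pos[j],
        if (base) "DEMETHYLATING_EPIMUTATION" else "METHYLATING_EPIMUTATION")
    }
  }
  list(states = states, cell_ids = cell_ids, ledger = .bind_ledger(ledger))
}

#' Apply stochastic bisulfite chemistry to one allele
#'
#' Converts the allele sequence according to its methylation state, with
#' chemistry errors: an unmethylated cytosine stays C with
#' `conversion_failure_rate` (logged `CONVERSION_FAILURE`), a methylated
#' cytosine converts to T with `overconversion_rate` (logged
#' `OVERCONVERSION`). Non-cytosine bases are untouched. With both error
#' rates at zero this equals the deterministic [bisulfite_convert()].
#'
#' Uses the current global RNG stream.
#'
#' @param amplicon An [amplicon()] object (the allele carries the reference
#'   sequence; methylation state determines conversion).
#' @param cpg_methylated Logical vector, one entry per CpG of the amplicon.
#' @param non_cpg_methylated Logical vector per non-CpG cytosine (CHH
#'   methylation, read as C); default all `FALSE`.
#' @param config An [simulation_config()] object.
#' @return List with `sequence` (converted DNA string) and `events` (data
#'   frame with columns `position`, `event_kind`).
#' @export
apply_bisulfite_chemistry <- function(amplicon, cpg_methylated,
                                      non_cpg_methylated = NULL, config) {
  stopifnot(inherits(amplicon, "slbs_amplicon"),
            inherits(config, "slbs_config"))
  cp <- amplicon$cpg_positions
  np <- amplicon$non_cpg_c_positions
  if (is.null(non_cpg_methylated)) non_cpg_methylated <- rep(FALSE, length(np))
  stopifnot(length(cpg_methylated) == length(cp),
            length(non_cpg_methylated) == length(np))
  chars <- .chars(amplicon$sequence)
  positions <- c(cp, np)
  meth <- c(as.logical(cpg_methylated), as.logical(non_cpg_methylated))
  events <- data.frame(position = integer(0), event_kind = character(0))
  if (length(positions)) {
    u <- runif(length(positions))
    fail <- !meth & u < config$conversion_failure_rate   # stays C
    over <- meth & u < config$overconversion_rate        # converts to T
    base <- ifelse(meth, "C", "T")
    base[fail] <- "C"
    base[over] <- "T"
    chars[positions + 1L] <- base
    if (any(fail) || any(over))
      events <- data.frame(
        position = c(positions[fail], positions[over]),
        event_kind = c(rep("CONVERSION_FAILURE", sum(fail)),
                       rep("OVERCONVERSION", sum(over))))
  }
  list(sequence = paste(chars, collapse = ""), events = events)
}

#' Render a Sanger-style consensus of allele sequences
#'
#' Position-wise: if all alleles agree the base is emitted; if exactly the
#' set \{C, T\} is observed the IUPAC code `Y` is emitted (an overlapping
#' C+T double peak, e.g. hemi-methylation); any other disagreement yields
#' `N` (uninterpretable). A single sequence (allelic dropout) is returned
#' verbatim.
#'
#' @param allele_sequences Character vector of equal-length DNA strings.
#' @return A single IUPAC consensus string.
#' @examples
#' render_sanger_consensus(c("ACGT", "ATGT"))  # "AYGT"
#' @export
render_sanger_consensus <- function(allele_sequences) {
  stopifnot(is.character(allele_sequences), length(allele_sequences) >= 1L)
  if (length(unique(nchar(allele_sequences))) != 1L)
    stop("allele sequences must all have the same length", call. = FALSE)
  if (length(allele_sequences) == 1L) return(allele_sequences)
  mat <- do.call(rbind, strsplit(allele_sequences, "", fixed = TRUE))
  out <- vapply(seq_len(ncol(mat)), function(j) {
    u <- unique(mat[, j])
    if (length(u) == 1L) u
    else if (length(u) == 2L && all(c("C", "T") %in% u)) "Y"
    else "N"
  }, "")
  paste(out, collapse = "")
}

# Amplification + chemistry + consensus for one locus, given a state array.
# Consumes the global RNG stream; draw order is cell-major and documented:
# per cell, (1) amplicon success, (2) allelic dropout + allele choice,
# (3) per retained-or-not allele: non-CpG methylation mask, chemistry.
.simulate_locus_reads <- function(amplicon, states, config, cell_ids,
                                  tp = 0) {
  n <- dim(states)[1L]
  pl <- dim(states)[2L]
  np <- amplicon$non_cpg_c_positions
  reads <- character(0)
  ledger <- list()
  add <- function(row) ledger[[length(ledger) + 1L]] <<- row
  for (i in seq_len(n)) {
    if (runif(1L) >= config$amplicon_success_prob) {
      add(.ledger_row(cell_ids[i], amplicon$name, NA_integer_, NA_integer_,
                      "AMPLICON_DROPOUT"))
      next
    }
    alleles <- seq_len(pl)
    if (pl > 1L && runif(1L) < config$allelic_dropout_prob) {
      keep <- sample.int(pl, 1L)
      add(.ledger_row(cell_ids[i], amplicon$name, keep, NA_integer_,
                      "ALLELIC_DROPOUT"))
      alleles <- keep
    }
    seqs <- character(length(alleles))
    for (ai in seq_along(alleles)) {
      a <- alleles[ai]
      mask <- if (length(np) && config$non_cpg_methylation_rate > 0)
        runif(length(np)) < config$non_cpg_methylation_rate
      else rep(FALSE, length(np))
      if (any(mask))
        add(.ledger_row(cell_ids[i], amplicon$name, a, np[mask],
                        "NON_CPG_METHYLATION"))
      chem <- apply_bisulfite_chemistry(amplicon, states[i, a, ], mask,
                                        config)
      if (nrow(chem$events))
        add(.ledger_row(cell_ids[i], amplicon$name, a, chem$events$position,
                        chem$events$event_kind))
      seqs[ai] <- chem$sequence
    }
    header <- sprintf("cell:%s|locus:%s|tp:%g", cell_ids[i], amplicon$name,
                      tp)
    reads[header] <- render_sanger_consensus(seqs)
  }
  list(reads = reads, ledger = .bind_ledger(ledger))
}

#' Simulate a full single-cell bisulfite sequencing experiment
#'
#' For every cell and locus: with probability
#' `1 - amplicon_success_prob` no read is produced (`AMPLICON_DROPOUT`);
#' otherwise, with probability `allelic_dropout_prob` a single uniformly
#' chosen allele is amplified (`ALLELIC_DROPOUT`), else all alleles.
#' Epimutations are planted per allele (see
#' [simulate_cell_allele_states()]), bisulfite chemistry errors applied
#' (see [apply_bisulfite_chemistry()]), and the read is the Sanger-style
#' consensus of the amplified alleles. Fully reproducible from
#' `config$seed`.
#'
#' @param amplicons A list of [amplicon()] objects (or a single one).
#' @param bulk_profiles Bulk profile data frame covering every amplicon.
#' @param config An [simulation_config()] object.
#' @return List with `reads` (named character vector; headers
#'   `cell:<id>|locus:<name>|tp:0`) and `ledger` (truth ledger data frame
#'   with columns `cell_id`, `locus`, `allele_index`, `position`,
#'   `event_kind`).
#' @examples
#' amp <- amplicon("toy", "TTACGTTACTTACGTT")
#' bulk <- uniform_bulk_profile("toy", 2, "METHYLATED")
#' cfg <- simulation_config(n_cells = 4, amplicon_success_prob = 1,
#'                          conversion_failure_rate = 0,
#'                          overconversion_rate = 0, seed = 7)
#' simulate_experiment(amp, bulk, cfg)$reads
#' @export
simulate_experiment <- function(amplicons, bulk_profiles, config) {
  stopifnot(inherits(config, "slbs_config"))
  amplicons <- .as_amplicon_list(amplicons)
  set.seed(config$seed)
  cell_ids <- .default_cell_ids(config$n_cells)
  reads <- character(0)
  ledger <- list()
  for (amp in amplicons) {
    bl <- .bulk_for_locus(bulk_profiles, amp)
    st <- simulate_cell_allele_states(bl, config, amplicon = amp,
                                      cell_ids = cell_ids)
    out <- .simulate_locus_reads(amp, st$states, config, cell_ids)
    reads <- c(reads, out$reads)
    ledger <- c(ledger, list(st$ledger, out$ledger))
  }
  list(reads = reads, ledger = .bind_ledger(ledger))
}

#' Simulate a 5-Aza passive demethylation time course
#'
#' 5-aza-2'-deoxycytidine traps DNMT1 and blocks maintenance methylation in
#' newly synthesised DNA, so a fully methylated locus demethylates
#' passively with cell division. Per allele and CpG, methylation is
#' retained with probability `(1 - per_division_block_prob)^g`, where
#' `g = floor(hours / generation_time_hours)` is the number of completed
#' divisions. Hemi-demethylation (a mixed C+T peak, `Y`) arises naturally
#' when one allele retains methylation and the other loses it. At `t = 0`
#' the bulk profile is reproduced. Methylation losses are logged as
#' `DEMETHYLATING_EPIMUTATION` events.
#'
#' @param amplicon An [amplicon()] object.
#' @param bulk Bulk profile for the locus; must be fully `METHYLATED`.
#' @param config An [simulation_config()] object.
#' @param timepoints Numeric vector of treatment durations in hours.
#' @param per_division_block_prob Probability, per division and allele-CpG,
#'   that maintenance methylation is blocked.
#' @param generation_time_hours Cell generation time in hours (> 0).
#' @return Named list (one element per timepoint, `t<hours>`) of lists with
#'   `hours`, `generations`, `retain_prob`, `reads` and `ledger`.
#' @export
simulate_aza_timecourse <- function(amplicon, bulk, config, timepoints,
                                    per_division_block_prob,
                                    generation_time_hours = 24) {
  stopifnot(inherits(amplicon, "slbs_amplicon"),
            inherits(config, "slbs_config"),
            is.numeric(timepoints), all(timepoints >= 0))
  .check_prob(per_division_block_prob, "per_division_block_prob")
  if (!is.numeric(generation_time_hours) || generation_time_hours <= 0)
    stop("generation_time_hours must be > 0", call. = FALSE)
  bl <- .bulk_for_locus(bulk, amplicon)
  if (!all(bl$status == "METHYLATED"))
    stop("the time-course model starts from a fully methylated locus",
         call. = FALSE)
  set.seed(config$seed)
  cell_ids <- .default_cell_ids(config$n_cells)
  n <- config$n_cells
  pl <- config$ploidy
  k <- nrow(bl)
  pos <- amplicon$cpg_positions
  out <- list()
  for (h in timepoints) {
    g <- floor(h / generation_time_hours)
    retain <- (1 - per_division_block_prob)^g
    states <- array(runif(n * pl * k) < retain, dim = c(n, pl, k))
    ledger <- list()
    lost <- which(!states, arr.ind = TRUE)
    if (nrow(lost))
      ledger[[1L]] <- .ledger_row(cell_ids[lost[, 1L]], amplicon$name,
                                  lost[, 2L], pos[lost[, 3L]],
                                  "DEMETHYLATING_EPIMUTATION")
    rendered <- .simulate_locus_reads(amplicon, states, config, cell_ids,
                                      tp = h)
    out[[paste0("t", h)]] <- list(
      hours = h, generations = g, retain_prob = retain,
      reads = rendered$reads,
      ledger = .bind_ledger(c(ledger, list(rendered$ledger))))
  }
  out
}
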