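# Deterministic single-hepatocyte benchmark fixture: eight promoter /
# intragenic regions with known per-region cell counts, planted epimutation
# events and planted conversion failures, constructed so the analysis
# pipeline recovers the published totals (206 cells, 601 CpGs, 16
# demethylating and 10 methylating events, 3279/3296 non-CpG conversions).

.hepatocyte_regions <- function() {
  data.frame(
    name = c("Oct4_region1", "Oct4_region2", "L1_Chr18", "Gabra1",
             "Cyp71a", "Nfe2l2", "Rabgap1l", "Dpf1"),
    n_cpgs = c(2L, 4L, 2L, 3L, 2L, 4L, 4L, 3L),
    n_cells = c(17L, 12L, 33L, 66L, 24L, 34L, 11L, 9L),
    bulk_status = c("METHYLATED", "METHYLATED", "METHYLATED",
                    "UNMETHYLATED", "UNMETHYLATED", "UNMETHYLATED",
                    "METHYLATED", "METHYLATED"),
    n_demethylating = c(6L, 3L, 3L, 0L, 0L, 0L, 3L, 1L),
    n_methylating = c(0L, 0L, 0L, 0L, 4L, 6L, 0L, 0L),
    n_nonconversions = c(3L, 0L, 0L, 2L, 7L, 1L, 3L, 1L),
    # amplicon non-CpG cytosine count; at least 20 wherever a conversion
    # failure is planted, so one failure leaves the cell's QC rate >= 0.95
    n_non_cpg_c = c(20L, 18L, 1L, 20L, 31L, 20L, 63L, 20L),
    # per-region evaluable non-CpG denominator; the eight values sum to
    # exactly 3296 (the published pooled denominator)
    non_cpg_evaluable = c(289L, 216L, 33L, 726L, 744L, 442L, 693L, 153L))
}

# Deterministic per-cell evaluable non-CpG counts for one region: cells
# carrying a planted failure get max(20, ceiling(D / n)) evaluable
# positions; the remainder is spread evenly over the other cells. Excess
# amplicon positions are masked with N (excluded from QC denominators).
.per_cell_evaluable <- function(D, n, f, K) {
  e <- integer(n)
  if (f > 0L) {
    e_fail <- min(K, max(20L, as.integer(ceiling(D / n))))
    e[seq_len(f)] <- e_fail
  }
  nf <- n - f
  if (nf > 0L) {
    R <- D - sum(e)
    base <- R %/% nf
    rem <- R %% nf
    e[f + seq_len(nf)] <- base + as.integer(seq_len(nf) <= rem)
  }
  stopifnot(sum(e) == D, all(e >= 0L), all(e <= K))
  e
}

# Alternate CpG units ("AACGTT") and non-CpG-cytosine units ("AACTTT");
# unit boundaries (T|A) can never create an accidental CpG.
.build_region_sequence <- function(n_cpgs, n_non_cpg) {
  units <- character(0)
  ncpg <- n_cpgs; nnon <- n_non_cpg
  while (ncpg > 0L || nnon > 0L) {
    if (nnon > 0L) { units <- c(units, "AACTTT"); nnon <- nnon - 1L }
    if (ncpg > 0L) { units <- c(units, "AACGTT"); ncpg <- ncpg - 1L }
  }
  paste(units, collapse = "")
}

#' Generate the deterministic single-hepatocyte benchmark fixture
#'
#' Constructs eight synthetic amplicons with the published per-region CpG
#' counts (2, 4, 2, 3, 2, 4, 4, 3) and cell counts (17, 12, 33, 66, 24,
#' 34, 11, 9), plants exactly the published demethylating (16) and
#' methylating (10) epimutation events and exactly 17 bisulfite
#' non-conversions, and writes reads, amplicon references, bulk profile
#' and the expected summary to `out_dir`. Running [call_methylation()] and
#' [summarize_epimutations()] on the fixture reproduces the published
#' totals row exactly. The construction is fully deterministic (no RNG):
#' event `j` of a region is planted in cell `j` at CpG ordinal
#' `j %% n_cpgs`, and non-conversion `j` is assigned round-robin across
#' cells starting at cell 0, at non-CpG cytosine ordinal
#' `j %% n_non_cpg_c`.
#'
#' The published per-region conversion denominators are internally
#' inconsistent with the published pooled total (they sum to 3313, not
#' 3296), so the fixture reproduces the pooled total -- the quantity the
#' epimutation significance test uses -- exactly, and the per-region
#' fractions approximately. Per-region evaluable denominators (summing to
#' 3296) are realised by masking excess non-CpG cytosine positions with
#' `N`, which the conversion QC excludes; every cell carrying a planted
#' failure has at least 20 evaluable non-CpG cytosines, keeping its QC
#' rate at or above the default 0.95 retention threshold.
#'
#' @param out_dir Output directory (created if needed).
#' @param plant_events Plant the epimutation events (default `TRUE`).
#' @param plant_nonconversions Plant the 17 conversion failures (default
#'   `TRUE`). With both flags `FALSE` the fixture is fully concordant with
#'   bulk and converts perfectly.
#' @return Invisibly, a list with `paths` (amplicons FASTA, regions BED,
#'   bulk TSV, reads FASTA, expected-summary TSV), the in-memory
#'   `amplicons`, `bulk`, `reads`, and the `expected` per-region table.
#' @export
generate_hepatocyte_fixture <- function(out_dir,
                                        plant_events = TRUE,
                                        plant_nonconversions = TRUE) {
  spec <- .hepatocyte_regions()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  amplicons <- list()
  bulk <- list()
  reads <- character(0)
  expected <- list()
  for (r in seq_len(nrow(spec))) {
    rg <- spec[r, ]
    seqn <- .build_region_sequence(rg$n_cpgs, rg$n_non_cpg_c)
    amp <- amplicon(rg$name, seqn, chrom = "chr1",
                    start = 1000L + (r - 1L) * 10000L)
    stopifnot(length(amp$cpg_positions) == rg$n_cpgs,
              length(amp$non_cpg_c_positions) == rg$n_non_cpg_c)
    amplicons[[rg$name]] <- amp
    bulk[[rg$name]] <- uniform_bulk_profile(rg$name, rg$n_cpgs,
                                            rg$bulk_status)
    methylated <- rg$bulk_status == "METHYLATED"
    base <- .chars(bisulfite_convert(
      seqn, if (methylated) amp$cpg_positions else integer(0)))
    n_events <- if (methylated) rg$n_demethylating else rg$n_methylating
    evaluable <- .per_cell_evaluable(rg$non_cpg_evaluable, rg$n_cells,
                                     rg$n_nonconversions, rg$n_non_cpg_c)
    for (i in seq_len(rg$n_cells) - 1L) {
      chars <- base
      n_mask <- rg$n_non_cpg_c - evaluable[i + 1L]
      if (n_mask > 0L) {
        masked <- amp$non_cpg_c_positions[
          rg$n_non_cpg_c - seq_len(n_mask) + 1L]
        chars[masked + 1L] <- "N"
      }
      if (plant_events && n_events > 0L) {
        for (j in seq_len(n_events) - 1L) {
          if (j %% rg$n_cells == i) {
            p <- amp$cpg_positions[(j %% rg$n_cpgs) + 1L]
            chars[p + 1L] <- if (methylated) "T" else "C"
          }
        }
      }
      if (plant_nonconversions && rg$n_nonconversions > 0L) {
        for (j in seq_len(rg$n_nonconversions) - 1L) {
          if (j %% rg$n_cells == i) {
            p <- amp$non_cpg_c_positions[(j %% rg$n_non_cpg_c) + 1L]
            chars[p + 1L] <- "C"
          }
        }
      }
      header <- sprintf("cell:%s_c%03d|locus:%s|tp:0", rg$name, i + 1L,
                        rg$name)
      reads[header] <- paste(chars, collapse = "")
    }
    nct <- rg$non_cpg_evaluable
    expected[[rg$name]] <- data.frame(
      gene_region = rg$name,
      n_cpgs_per_region = rg$n_cpgs,
      n_cells_analyzed = rg$n_cells,
      total_cpgs = rg$n_cpgs * rg$n_cells,
      n_demethylating = if (plant_events) rg$n_demethylating else 0L,
      n_methylating = if (plant_events) rg$n_methylating else 0L,
      non_cpg_converted = nct -
        if (plant_nonconversions) rg$n_nonconversions else 0L,
      non_cpg_total = nct)
  }
  bulk <- do.call(rbind, bulk)
  rownames(bulk) <- NULL
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$gene_region), , drop = FALSE]
  rownames(expected) <- NULL

  paths <- c(amplicons = file.path(out_dir, "amplicons.fasta"),
             regions = file.path(out_dir, "regions.bed"),
             bulk = file.path(out_dir, "bulk.tsv"),
             reads = file.path(out_dir, "reads.fasta"),
             expected = file.path(out_dir, "expected_summary.tsv"))
  write_amplicons(amplicons, paths[["amplicons"]], paths[["regions"]])
  write_bulk_profile(bulk, paths[["bulk"]],
                     provenance = .provenance_lines(seed = NA))
  write_reads_fasta(reads, paths[["reads"]])
  .write_tsv(expected, paths[["expected"]],
             provenance = .provenance_lines(seed = NA))
  invisible(list(paths = paths, amplicons = amplicons, bulk = bulk,
                 reads = reads, expected = expected))
}
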