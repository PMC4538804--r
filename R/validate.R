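# Input validation: aggregate all violations before failing.

.violation <- function(file, record, rule, message) {
  data.frame(file = file, record = record, rule = rule, message = message)
}

#' Validate a set of pipeline input files
#'
#' Checks the amplicon FASTA alphabet, name and length agreement between
#' FASTA and BED, and bulk-profile CpG coverage and status validity. All
#' violations are collected into a single report rather than failing at
#' the first.
#'
#' @param amplicons_fasta Path to the amplicon FASTA.
#' @param regions_bed Path to the BED file of region coordinates.
#' @param bulk_tsv Path to the bulk profile TSV.
#' @return A data frame with columns `file`, `record`, `rule`, `message`;
#'   zero rows when all inputs are consistent.
#' @export
validate_inputs <- function(amplicons_fasta, regions_bed, bulk_tsv) {
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  seqs <- tryCatch(Biostrings::readDNAStringSet(amplicons_fasta),
                   error = function(e) e)
  if (inherits(seqs, "error")) {
    add(.violation(amplicons_fasta, "-", "fasta-parse",
                   conditionMessage(seqs)))
    seqs <- NULL
  }
  gr <- tryCatch(rtracklayer::import(regions_bed), error = function(e) e)
  if (inherits(gr, "error")) {
    add(.violation(regions_bed, "-", "bed-parse", conditionMessage(gr)))
    gr <- NULL
  }
  bulk <- tryCatch(read_bulk_profile(bulk_tsv), error = function(e) e)
  if (inherits(bulk, "error")) {
    add(.violation(bulk_tsv, "-", "bulk-parse", conditionMessage(bulk)))
    bulk <- NULL
  }

  fasta_names <- character(0)
  seq_str <- character(0)
  if (!is.null(seqs)) {
    fasta_names <- sub("\\s.*$", "", names(seqs))
    seq_str <- setNames(as.character(seqs), fasta_names)
    for (nm in fasta_names) {
      if (grepl("[^ACGT]", seq_str[[nm]]))
        add(.violation(amplicons_fasta, nm, "fasta-alphabet",
                       "sequence contains characters outside A/C/G/T"))
    }
  }
  if (!is.null(seqs) && !is.null(gr)) {
    bed_names <- if (!is.null(gr$name)) as.character(gr$name)
                 else character(0)
    for (nm in setdiff(fasta_names, bed_names))
      add(.violation(regions_bed, nm, "name-agreement",
                     "FASTA record has no BED interval"))
    for (nm in setdiff(bed_names, fasta_names))
      add(.violation(amplicons_fasta, nm, "name-agreement",
                     "BED interval has no FASTA record"))
    for (nm in intersect(fasta_names, bed_names)) {
      w <- GenomicRanges::width(gr)[match(nm, bed_names)]
      if (w != nchar(seq_str[[nm]]))
        add(.violation(regions_bed, nm, "length-agreement",
                       sprintf("BED width %d != sequence length %d", w,
                               nchar(seq_str[[nm]]))))
    }
  }
  if (!is.null(bulk)) {
    bad <- !bulk$status %in% .BULK_STATUSES
    for (i in which(bad))
      add(.violation(bulk_tsv, paste0(bulk$locus[i], ":", bulk$cpg_index[i]),
                     "bulk-status",
                     paste0("invalid status '", bulk$status[i], "'")))
    mixed <- bulk$status == "MIXED"
    badf <- mixed & (is.na(bulk$methylated_fraction) |
                       bulk$methylated_fraction <= 0 |
                       bulk$methylated_fraction >= 1)
    for (i in which(badf))
      add(.violation(bulk_tsv, paste0(bulk$locus[i], ":", bulk$cpg_index[i]),
                     "bulk-fraction",
                     "MIXED requires methylated_fraction in (0, 1)"))
    if (!is.null(seqs)) {
      for (nm in fasta_names) {
        if (grepl("[^ACGT]", seq_str[[nm]])) next
        k <- length(find_cpg_cytosines(seq_str[[nm]]))
        idx <- sort(bulk$cpg_index[bulk$locus == nm])
        missing <- setdiff(seq_len(k) - 1L, idx)
        for (mi in missing)
          add(.violation(bulk_tsv, paste0(nm, ":", mi), "bulk-coverage",
                         "CpG has no bulk profile entry"))
        extra <- setdiff(idx, seq_len(k) - 1L)
        for (mi in extra)
          add(.violation(bulk_tsv, paste0(nm, ":", mi), "bulk-coverage",
                         "bulk entry indexes a CpG absent from the amplicon"))
      }
    }
  }
  if (length(v)) do.call(rbind, v)
  else .violation(character(0), character(0), character(0), character(0))
}
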