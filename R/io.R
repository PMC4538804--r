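# File-format plumbing: FASTA via Biostrings, BED via rtracklayer, TSV via
# base utils. All BED/TSV coordinates are 0-based half-open.

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance) && length(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read amplicon references from FASTA + BED
#'
#' The FASTA record id (first whitespace-delimited token of the header) is
#' the amplicon name and must match a BED `name` field; the BED interval
#' supplies the genomic anchor (`chrom`, 0-based half-open `start`/`end`)
#' and its width must equal the sequence length.
#'
#' @param fasta_path FASTA of amplicon sequences (A/C/G/T).
#' @param bed_path BED file (chrom, start, end, name).
#' @return Named list of [amplicon()] objects, in FASTA order.
#' @export
read_amplicons <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nms <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(bed_path)
  bed_names <- if (!is.null(gr$name)) as.character(gr$name)
               else as.character(seq_along(gr))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    j <- match(nms[i], bed_names)
    if (is.na(j))
      stop("amplicon '", nms[i], "' has no BED interval", call. = FALSE)
    sq <- as.character(seqs[[i]])
    if (GenomicRanges::width(gr)[j] != nchar(sq))
      stop("BED width for '", nms[i], "' (", GenomicRanges::width(gr)[j],
           ") != sequence length (", nchar(sq), ")", call. = FALSE)
    out[[i]] <- amplicon(nms[i], sq,
                         chrom = as.character(GenomicRanges::seqnames(gr))[j],
                         start = GenomicRanges::start(gr)[j] - 1L)
  }
  setNames(out, nms)
}

#' Write amplicon references to FASTA + BED
#'
#' @param amplicons A list of [amplicon()] objects (or a single one).
#' @inheritParams read_amplicons
#' @return Invisibly, the two paths.
#' @export
write_amplicons <- function(amplicons, fasta_path, bed_path) {
  amplicons <- .as_amplicon_list(amplicons)
  seqs <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, "", "sequence"))
  names(seqs) <- vapply(amplicons, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(amplicons, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(amplicons, `[[`, 0L, "start") + 1L,
      end = vapply(amplicons, `[[`, 0L, "end")),
    name = vapply(amplicons, `[[`, "", "name"))
  rtracklayer::export(gr, bed_path, format = "bed")
  invisible(c(fasta = fasta_path, bed = bed_path))
}

.as_amplicon_list <- function(amplicons) {
  if (inherits(amplicons, "slbs_amplicon")) amplicons <- list(amplicons)
  stopifnot(all(vapply(amplicons, inherits, TRUE, "slbs_amplicon")))
  setNames(amplicons, vapply(amplicons, `[[`, "", "name"))
}

#' Read / write single-cell consensus reads (FASTA)
#'
#' Reads are IUPAC strings (`Y` marks an overlapping C+T double peak, i.e.
#' the two alleles disagree). Headers follow the convention
#' `cell:<id>|locus:<name>|tp:<hours>`.
#'
#' @param path FASTA file path.
#' @return `read_reads_fasta()`: a named character vector (names are the
#'   full headers).
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_reads_fasta
#' @param reads Named character vector of reads.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.parse_read_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1L]]
  kv <- regmatches(fields, regexec("^([^:]+):(.*)$", fields))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else "", "")
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else "", "")
  list(cell_id = if ("cell" %in% keys) vals[keys == "cell"][1L] else header,
       locus = if ("locus" %in% keys) vals[keys == "locus"][1L] else NA_character_,
       tp = if ("tp" %in% keys) as.numeric(vals[keys == "tp"][1L]) else 0)
}
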