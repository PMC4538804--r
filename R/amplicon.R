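# Amplicon references and deterministic in-silico bisulfite conversion.
# Coordinates: 0-based half-open throughout; amplicon-local offsets.

.check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop(errorCondition(
      paste0(what, " contains characters outside the A/C/G/T alphabet"),
      class = "slbs_invalid_alphabet"))
  invisible(sequence)
}

.chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

#' Locate CpG cytosines in a DNA sequence
#'
#' Returns the 0-based offsets of every cytosine immediately followed by a
#' guanine (the CpG dinucleotide, the principal substrate of mammalian DNA
#' methylation).
#'
#' @param sequence A single uppercase DNA string (A/C/G/T only).
#' @return Integer vector of 0-based offsets, ordered; empty if none.
#' @examples
#' find_cpg_cytosines("ACGTCGA")  # 1, 4
#' @seealso [find_non_cpg_cytosines()]
#' @export
find_cpg_cytosines <- function(sequence) {
  .check_dna(sequence)
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Locate non-CpG cytosines in a DNA sequence
#'
#' All cytosines not followed by a guanine. These are assumed unmethylated
#' in non-pluripotent cells and their C-to-T conversion is the internal
#' control for bisulfite efficiency. A terminal cytosine (no following
#' base) is classed non-CpG; this conservative choice enters the
#' conversion-rate denominator.
#'
#' @inheritParams find_cpg_cytosines
#' @return Integer vector of 0-based offsets, ordered; empty if none.
#' @export
find_non_cpg_cytosines <- function(sequence) {
  .check_dna(sequence)
  all_c <- which(.chars(sequence) == "C") - 1L
  setdiff(all_c, find_cpg_cytosines(sequence))
}

#' Construct an amplicon reference
#'
#' An amplicon is a fixed PCR-targeted fragment (typically a gene promoter
#' region) with its CpG and non-CpG cytosine position maps precomputed.
#'
#' @param name Amplicon (locus) name; used as the FASTA record id.
#' @param sequence Uppercase DNA string, A/C/G/T only.
#' @param chrom Chromosome name for BED reporting.
#' @param start 0-based genomic start; `end` is derived as
#'   `start + nchar(sequence)` (half-open).
#' @return An object of class `slbs_amplicon`: a list with fields `name`,
#'   `chrom`, `start`, `end`, `sequence`, `cpg_positions` and
#'   `non_cpg_c_positions` (both 0-based amplicon offsets).
#' @examples
#' amp <- amplicon("toy", "ACGTCAC")
#' amp$cpg_positions       # 1
#' amp$non_cpg_c_positions # 4, 6
#' @export
amplicon <- function(name, sequence, chrom = "chrU", start = 0L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .check_dna(sequence)
  start <- as.integer(start)
  structure(list(
    name = name,
    chrom = as.character(chrom),
    start = start,
    end = start + nchar(sequence),
    sequence = sequence,
    cpg_positions = find_cpg_cytosines(sequence),
    non_cpg_c_positions = find_non_cpg_cytosines(sequence)
  ), class = "slbs_amplicon")
}

#' @export
print.slbs_amplicon <- function(x, ...) {
  cat(sprintf("<slbs_amplicon> %s  %s:%d-%d (%d bp)\n", x$name, x$chrom,
              x$start, x$end, nchar(x$sequence)))
  cat(sprintf("  CpG cytosines:     %d\n", length(x$cpg_positions)))
  cat(sprintf("  non-CpG cytosines: %d\n", length(x$non_cpg_c_positions)))
  invisible(x)
}

#' Deterministic in-silico bisulfite conversion
#'
#' Converts every unmethylated cytosine to thymine (the PCR read-out of
#' uracil) and leaves methylated cytosines and all other bases unchanged.
#' Only the top (read) strand is modelled.
#'
#' @inheritParams find_cpg_cytosines
#' @param methylated_positions Integer vector of 0-based offsets of
#'   methylated (retained) cytosines. Every offset must hold a `C`.
#' @return The converted DNA string, same length as the input.
#' @examples
#' bisulfite_convert("ACGT")            # "ATGT"
#' bisulfite_convert("ACGT", 1L)        # "ACGT"
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer(0)) {
  .check_dna(sequence)
  chars <- .chars(sequence)
  mp <- as.integer(methylated_positions)
  if (length(mp) &&
      (anyNA(mp) || any(mp < 0L | mp >= length(chars)) ||
       any(chars[mp + 1L] != "C")))
    stop(errorCondition(
      "every methylated position must index a cytosine of `sequence`",
      class = "slbs_inconsistent_methylation"))
  convert <- chars == "C"
  convert[mp + 1L] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Check that a primer is conversion-specific
#'
#' A conversion-specific primer anneals only to bisulfite-converted
#' template: it must match the converted amplicon subsequence exactly and
#' differ from the unconverted subsequence in at least one position (its
#' footprint contains at least one convertible cytosine). Such primers
#' ensure that only fully converted molecules are amplified.
#'
#' @param primer Primer sequence (top strand, A/C/G/T).
#' @param amplicon An [amplicon()] object.
#' @param primer_start 0-based offset of the primer within the amplicon.
#' @param methylated_positions 0-based amplicon offsets of methylated
#'   cytosines assumed retained during conversion.
#' @return `TRUE` or `FALSE`.
#' @export
primer_is_conversion_specific <- function(primer, amplicon, primer_start,
                                          methylated_positions = integer(0)) {
  stopifnot(inherits(amplicon, "slbs_amplicon"))
  .check_dna(primer, "primer")
  primer_start <- as.integer(primer_start)
  w <- nchar(primer)
  if (is.na(primer_start) || primer_start < 0L ||
      primer_start + w > nchar(amplicon$sequence))
    stop(errorCondition("primer window falls outside the amplicon",
                        class = "slbs_range_error"))
  converted <- bisulfite_convert(amplicon$sequence, methylated_positions)
  sub_conv <- substr(converted, primer_start + 1L, primer_start + w)
  sub_raw <- substr(amplicon$sequence, primer_start + 1L, primer_start + w)
  identical(primer, sub_conv) && !identical(sub_conv, sub_raw)
}
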