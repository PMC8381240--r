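#' Load a genome from FASTA
#'
#' @param path Path to a (multi-record, free line wrap) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # keep only the sequence identifier, drop FASTA description tails
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome character vector must be named",
                                     call. = FALSE)
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet or a named character vector",
       call. = FALSE)
}

#' Extract the coding-strand sequence of a gene segment
#'
#' Returns the 1-based inclusive slice of the segment's chromosome; for minus
#' strand segments the reverse complement is returned, so position 1 of the
#' result is the segment's 5' end on the coding strand.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param segment A [gene_segment()] (or bare [genomic_interval()]).
#' @return Nucleotide sequence as a single string.
#' @export
extract_segment_sequence <- function(genome, segment) {
  interval <- if (inherits(segment, "gene_segment")) segment$interval
              else segment
  stopifnot(inherits(interval, "genomic_interval"))
  genome <- as_genome(genome)
  if (!interval$chrom %in% names(genome)) {
    stop("chromosome not in genome: ", interval$chrom, call. = FALSE)
  }
  chrom <- genome[[interval$chrom]]
  if (interval$end > length(chrom)) {
    stop("segment ", interval$chrom, ":", interval$start, "-", interval$end,
         " extends past chromosome end (", length(chrom), " bp)",
         call. = FALSE)
  }
  s <- Biostrings::subseq(chrom, interval$start, interval$end)
  if (interval$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Translate a nucleotide sequence in frame 0
#'
#' Standard genetic code, codon by codon; stops render as `*`, codons
#' containing ambiguity codes render as `X`, and a trailing partial codon is
#' ignored. No initiation-codon special-casing and no 6-frame search: the
#' annotated segment delimits the reading frame.
#'
#' @param nt Nucleotide string.
#' @return Amino-acid string (may be empty).
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  n_codons <- n %/% 3L
  if (n_codons == 0L) return("")
  trimmed <- substr(nt, 1L, n_codons * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(trimmed),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}
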