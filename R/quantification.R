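#' Read a SAM subset into alignment records
#'
#' Consumes the 11 mandatory SAM fields plus the optional `NH:i` tag (number
#' of reported alignment loci for the read; absent means unique, NH = 1).
#' Aligned reference blocks are derived from the cigar: M/=/X/D runs extend a
#' block, N splits blocks, I/S/H consume no reference. Records flagged
#' unmapped (0x4) carry `mapped = FALSE` and no blocks.
#'
#' @param sam SAM text (single string or lines) or a file path.
#' @return An object of class `alignment_records`: a list with `reads` (data
#'   frame: `read_id`, `chrom`, `pos`, `strand`, `nh`, `mapped`) and `blocks`
#'   (an [IRanges::IRangesList] parallel to the rows of `reads`).
#' @export
read_alignments <- function(sam) {
  lines <- read_text_lines(sam)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n_fields <- vapply(fields, length, integer(1))
  if (any(n_fields < 11L)) {
    bad <- body_idx[which(n_fields < 11L)[1]]
    stop("malformed SAM line ", bad, ": fewer than 11 fields", call. = FALSE)
  }
  flag <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4L)))
  cigar <- vapply(fields, `[`, character(1), 6L)
  if (anyNA(flag) || anyNA(pos)) {
    bad <- body_idx[which(is.na(flag) | is.na(pos))[1]]
    stop("malformed SAM line ", bad, ": non-numeric flag or pos",
         call. = FALSE)
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  bad_cigar <- mapped & !grepl("^([0-9]+[MIDNSH=X])+$", cigar)
  if (any(bad_cigar)) {
    stop("malformed SAM line ", body_idx[which(bad_cigar)[1]],
         ": unsupported cigar '", cigar[which(bad_cigar)[1]], "'",
         call. = FALSE)
  }
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else 1L
  }, integer(1))
  reads <- data.frame(
    read_id = vapply(fields, `[`, character(1), 1L),
    chrom = vapply(fields, `[`, character(1), 3L),
    pos = pos,
    strand = ifelse(bitwAnd(flag, 16L) == 0L, "+", "-"),
    nh = pmax(nh, 1L),
    mapped = mapped,
    stringsAsFactors = FALSE)
  blocks <- if (nrow(reads) == 0L) IRanges::IRangesList() else
    IRanges::IRangesList(rep(list(IRanges::IRanges()), nrow(reads)))
  if (any(mapped)) {
    blk <- GenomicAlignments::extractAlignmentRangesOnReference(
      cigar[mapped], pos = reads$pos[mapped])
    # drop zero-width ranges (insertion-only runs between introns)
    blocks[mapped] <- blk[IRanges::width(blk) > 0L]
  }
  structure(list(reads = reads, blocks = blocks),
            class = "alignment_records")
}

subset_records <- function(records, keep) {
  structure(list(reads = records$reads[keep, , drop = FALSE],
                 blocks = records$blocks[keep]),
            class = "alignment_records")
}

#' Exclude multimapping reads
#'
#' Mirrors the stringent mapping rule under which reads aligned to more than
#' `max_loci` regions of the genome are considered unmapped: every record of
#' any read whose NH exceeds `max_loci` is removed, as are records flagged
#' unmapped.
#'
#' @param records An `alignment_records` object.
#' @param max_loci Maximum reported alignment loci to retain (default 2).
#' @return A filtered `alignment_records` object.
#' @export
filter_multimappers <- function(records, max_loci = 2L) {
  stopifnot(inherits(records, "alignment_records"), max_loci >= 1L)
  reads <- records$reads
  over <- unique(reads$read_id[reads$nh > max_loci])
  keep <- reads$mapped & !(reads$read_id %in% over)
  subset_records(records, keep)
}

#' Count reads per locus footprint
#'
#' A read contributes when any aligned block overlaps a locus footprint by at
#' least 1 bp. Records sharing a `read_id` (paired mates, or the retained
#' alignments of an NH = 2 read) are pooled as one fragment. Under
#' `"best-overlap"` (default) a fragment overlapping several loci counts only
#' toward the locus with the greatest total overlap, ties broken by
#' lexicographically smallest locus name; under `"any-overlap"` it counts
#' toward each. Counting is unstranded unless `stranded = TRUE`, which
#' restricts to same-strand overlap.
#'
#' Records must already be multimapper-filtered (see
#' [filter_multimappers()]).
#'
#' @param records An `alignment_records` object.
#' @param loci List of [retro_locus()] objects.
#' @param assignment `"best-overlap"` or `"any-overlap"`.
#' @param stranded Restrict to same-strand overlap.
#' @return A list with `counts` (named integer vector over all loci) and
#'   `library_size` (number of retained fragments).
#' @export
count_by_locus <- function(records, loci,
                           assignment = c("best-overlap", "any-overlap"),
                           stranded = FALSE) {
  assignment <- match.arg(assignment)
  locus_names <- vapply(loci, `[[`, character(1), "name")
  counts <- stats::setNames(integer(length(loci)), locus_names)
  library_size <- length(unique(records$reads$read_id))
  if (nrow(records$reads) == 0L || length(loci) == 0L) {
    return(list(counts = counts, library_size = library_size))
  }
  n_blocks <- lengths(records$blocks)
  rec_idx <- rep.int(seq_len(nrow(records$reads)), n_blocks)
  flat <- unlist(records$blocks, use.names = FALSE)
  block_gr <- GenomicRanges::GRanges(
    seqnames = records$reads$chrom[rec_idx],
    ranges = flat,
    strand = if (stranded) records$reads$strand[rec_idx] else "*")
  fp <- loci_granges(loci)
  if (!stranded) GenomicRanges::strand(fp) <- "*"
  hits <- GenomicRanges::findOverlaps(block_gr, fp, ignore.strand = !stranded)
  if (length(hits) == 0L) {
    return(list(counts = counts, library_size = library_size))
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov_width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(block_gr)[q], IRanges::ranges(fp)[s]))
  read_of_hit <- records$reads$read_id[rec_idx[q]]
  key <- paste0(read_of_hit, "\r", s)
  total <- tapply(ov_width, key, sum)
  parts <- strsplit(names(total), "\r", fixed = TRUE)
  df <- data.frame(read_id = vapply(parts, `[`, character(1), 1L),
                   locus = locus_names[as.integer(vapply(parts, `[`,
                                                         character(1), 2L))],
                   overlap = as.integer(total),
                   stringsAsFactors = FALSE)
  if (assignment == "any-overlap") {
    tab <- table(df$locus[!duplicated(paste0(df$read_id, "\r", df$locus))])
    counts[names(tab)] <- as.integer(tab)
  } else {
    # per fragment: max total overlap, ties to lexicographically smallest name
    df <- df[order(df$read_id, -df$overlap, df$locus), , drop = FALSE]
    best <- df[!duplicated(df$read_id), , drop = FALSE]
    tab <- table(best$locus)
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, library_size = library_size)
}

#' Build a locus-by-sample count matrix from SAM inputs
#'
#' Applies [filter_multimappers()] then [count_by_locus()] to each sample.
#'
#' @param sam_list Named list (or character vector of paths) of SAM inputs;
#'   names become sample names.
#' @param loci List of [retro_locus()] objects.
#' @param max_loci Multimapper threshold (default 2).
#' @param assignment Passed to [count_by_locus()].
#' @param stranded Passed to [count_by_locus()].
#' @return An object of class `count_matrix`: list with `counts` (integer
#'   matrix, loci x samples) and `library_size` (named integer vector of
#'   retained fragments per sample).
#' @export
count_matrix <- function(sam_list, loci, max_loci = 2L,
                         assignment = "best-overlap", stranded = FALSE) {
  stopifnot(length(sam_list) >= 1L)
  if (is.null(names(sam_list)) || any(!nzchar(names(sam_list)))) {
    names(sam_list) <- paste0("sample", seq_along(sam_list))
  }
  cols <- lapply(sam_list, function(sam) {
    recs <- filter_multimappers(read_alignments(sam), max_loci = max_loci)
    count_by_locus(recs, loci, assignment = assignment, stranded = stranded)
  })
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(counts) <- names(sam_list)
  structure(list(counts = counts,
                 library_size = vapply(cols, `[[`, integer(1),
                                       "library_size")),
            class = "count_matrix")
}

#' Counts per million retained fragments
#'
#' A reporting aid: `count * 1e6 / library_size` per sample. Differential
#' expression runs on raw counts, not CPM.
#'
#' @param cm A `count_matrix` (or a list with `counts` and `library_size`).
#' @return Real-valued matrix of the same shape as `cm$counts`.
#' @export
cpm_normalize <- function(cm) {
  stopifnot(!is.null(cm$counts), !is.null(cm$library_size),
            all(cm$library_size > 0))
  sweep(cm$counts, 2L, cm$library_size, function(x, n) x * 1e6 / n)
}

#' Write a count matrix as TSV
#'
#' First column `locus`, one column per sample; a trailing comment-free
#' companion file is not produced, library sizes are recoverable from the SAM
#' inputs.
#'
#' @param cm A `count_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(locus = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export counts as MatrixMarket-compatible triplets
#'
#' @param cm A `count_matrix`.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
export_counts_mtx <- function(cm, path) {
  m <- cm$counts
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(paste(nrow(m), ncol(m), nrow(nz)), con)
  if (nrow(nz)) {
    writeLines(paste(nz[, 1], nz[, 2], m[nz]), con)
  }
  invisible(path)
}
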