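#' Competence-calling configuration
#'
#' Tunable parameters of the sequence-based competence model.
#'
#' "Truncated" is operationalised two ways, either of which suffices: an
#' in-frame stop earlier than the final `terminal_stop_window` codons, or a
#' nucleotide length below `min_length_fraction` of the canonical length for
#' that gene role. Canonical lengths default to MLV-scale ERV genes and
#' L1-scale ORFs. `allowed_offsets` gives the gag->pol reading-frame offsets
#' (mod 3) accepted as "in frame"; the default `0` is the readthrough-style
#' gammaretroviral arrangement, and `c(0, 2)` admits a -1 programmed
#' frameshift. With `strict_motif_order = TRUE` the ERV call additionally
#' requires the template-binding motif to precede QDLREVNK to precede YxDD
#' along the pol translation.
#'
#' @param min_length_fraction Minimum nt length as a fraction of canonical.
#' @param terminal_stop_window Codons at the 3' end where a stop is terminal.
#' @param allowed_offsets Integer vector of admissible (pol - gag) mod 3.
#' @param strict_motif_order Require the ordered motif arrangement.
#' @param canonical_length Named numeric vector of canonical nt lengths per
#'   role.
#' @return A list of class `competence_config`.
#' @export
competence_config <- function(min_length_fraction = 0.9,
                              terminal_stop_window = 5L,
                              allowed_offsets = 0L,
                              strict_motif_order = FALSE,
                              canonical_length = c(gag = 1600, pol = 3600,
                                                   env = 2000, ORF1 = 1000,
                                                   ORF2 = 3800)) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            terminal_stop_window >= 0,
            all(allowed_offsets %in% 0:2),
            all(c("gag", "pol", "env", "ORF1", "ORF2") %in%
                  names(canonical_length)))
  structure(list(min_length_fraction = min_length_fraction,
                 terminal_stop_window = as.integer(terminal_stop_window),
                 allowed_offsets = as.integer(allowed_offsets),
                 strict_motif_order = isTRUE(strict_motif_order),
                 canonical_length = canonical_length),
            class = "competence_config")
}

#' Assess the integrity of one ORF
#'
#' Translates the strand-oriented segment sequence in frame 0 and reports the
#' first premature stop (0-based codon index) and the length fraction
#' relative to the configured canonical length of the role.
#'
#' @param segment_seq Coding-strand nucleotide sequence (nonempty).
#' @param role Gene role (`gag`, `pol`, `env`, `ORF1`, `ORF2`).
#' @param config A [competence_config()].
#' @return List with `role`, `nt_length`, `aa_sequence`,
#'   `premature_stop_index` (`NA` if none), `length_fraction`, `truncated`.
#' @export
assess_orf <- function(segment_seq, role, config = competence_config()) {
  stopifnot(is.character(segment_seq), nzchar(segment_seq))
  role <- match.arg(role, c("gag", "pol", "env", "ORF1", "ORF2"))
  aa <- translate_nt(segment_seq)
  n_codons <- nchar(aa)
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*") - 1L  # 0-based
  internal <- stops[stops < n_codons - config$terminal_stop_window]
  premature <- if (length(internal)) internal[1] else NA_integer_
  nt_length <- nchar(segment_seq)
  length_fraction <- nt_length / config$canonical_length[[role]]
  truncated <- !is.na(premature) ||
    length_fraction < config$min_length_fraction
  list(role = role, nt_length = nt_length, aa_sequence = aa,
       premature_stop_index = premature, length_fraction = length_fraction,
       truncated = truncated)
}

#' gag/pol reading-frame relation
#'
#' Computes the offset (mod 3) between the strand-oriented CDS starts of the
#' gag and pol segments. On the plus strand the oriented start is the genomic
#' start; on the minus strand orientation runs by descending genomic
#' coordinate, so the oriented start is the genomic end.
#'
#' @param locus A [retro_locus()] carrying both gag and pol segments.
#' @param config A [competence_config()] (supplies `allowed_offsets`).
#' @return List with `gag_pol_offset` (0, 1 or 2) and `in_frame`.
#' @export
gag_pol_frame_relation <- function(locus, config = competence_config()) {
  gag <- get_segment(locus, "gag")
  pol <- get_segment(locus, "pol")
  if (is.null(gag) || is.null(pol)) {
    stop(errorCondition(
      paste0("MISSING_SEGMENT: locus '", locus$name, "' lacks gag and/or pol"),
      class = "retrolocus_missing_segment"))
  }
  strand <- gag$interval$strand
  offset <- if (strand == "+") {
    (pol$interval$start - gag$interval$start) %% 3L
  } else {
    (gag$interval$end - pol$interval$end) %% 3L
  }
  list(gag_pol_offset = as.integer(offset),
       in_frame = as.integer(offset) %in% config$allowed_offsets)
}

#' Reverse-transcriptase active-site motifs
#'
#' The four conserved RVT_1-domain motif patterns used by the competence
#' model: `YxDD` and `DLKDAF` (Mg2+ coordination / polymerisation site),
#' `[WY]xxxLPQG` and `QDLREVNK` (template binding). `x` matches any one of
#' the 20 standard residues, never `X` or `*`.
#'
#' @return Data frame with columns `motif_id`, `pattern` (regex), `length`.
#' @export
rt_motifs <- function() {
  aa <- "[ACDEFGHIKLMNPQRSTVWY]"
  data.frame(
    motif_id = c("YxDD", "DLKDAF", "WY-LPQG", "QDLREVNK"),
    pattern = c(paste0("Y", aa, "DD"), "DLKDAF",
                paste0("[WY]", aa, aa, aa, "LPQG"), "QDLREVNK"),
    length = c(4L, 6L, 8L, 8L),
    stringsAsFactors = FALSE)
}

#' Scan a protein for RT active-site motifs
#'
#' Reports every (possibly overlapping) occurrence of the four motifs of
#' [rt_motifs()].
#'
#' @param aa Amino-acid string.
#' @return Data frame with columns `motif_id` and `position` (0-based start),
#'   ordered by position then motif.
#' @export
scan_rt_motifs <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L)
  motifs <- rt_motifs()
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    # lookahead so that overlapping occurrences are all reported
    m <- gregexpr(paste0("(?=", motifs$pattern[i], ")"), aa, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits[[length(hits) + 1L]] <- data.frame(
      motif_id = motifs$motif_id[i], position = as.integer(m) - 1L,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) {
    return(data.frame(motif_id = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$motif_id), , drop = FALSE]
}

#' Call reverse-transcription/retrotransposition competence for one locus
#'
#' ERV rule: competent iff gag and pol are both present and untruncated, gag
#' is in frame with pol, and all four RT motifs occur in the pol translation.
#' LINE-1 rule: competent iff ORF1 and ORF2 are both present and untruncated
#' and the YxDD motif occurs in the ORF2 translation. Every failed condition
#' appends one coded reason; conditions that depend on a missing segment are
#' not evaluated.
#'
#' @param locus A [retro_locus()].
#' @param genome Genome covering the locus ([Biostrings::DNAStringSet] or
#'   named character vector).
#' @param config A [competence_config()].
#' @return List of class `competence_call` with `locus`, `element_class`,
#'   `verdict` (`"competent"`/`"defective"`), `reasons` (character), and
#'   `motif_hits` (data frame).
#' @export
call_competence <- function(locus, genome, config = competence_config()) {
  stopifnot(inherits(locus, "retro_locus"))
  reasons <- character()
  motif_hits <- data.frame(motif_id = character(), position = integer(),
                           stringsAsFactors = FALSE)
  orf_of <- function(role) {
    seg <- get_segment(locus, role)
    if (is.null(seg)) return(NULL)
    assess_orf(extract_segment_sequence(genome, seg), role, config)
  }
  if (locus$element_class == "ERV") {
    gag <- orf_of("gag")
    pol <- orf_of("pol")
    if (is.null(gag)) reasons <- c(reasons, "MISSING_GAG")
    else if (gag$truncated) reasons <- c(reasons, "TRUNCATED_GAG")
    if (is.null(pol)) reasons <- c(reasons, "MISSING_POL")
    else if (pol$truncated) reasons <- c(reasons, "TRUNCATED_POL")
    if (!is.null(gag) && !is.null(pol)) {
      frame <- gag_pol_frame_relation(locus, config)
      if (!frame$in_frame) reasons <- c(reasons, "GAG_POL_FRAMESHIFT")
    }
    if (!is.null(pol)) {
      motif_hits <- scan_rt_motifs(pol$aa_sequence)
      for (id in rt_motifs()$motif_id) {
        if (!id %in% motif_hits$motif_id) {
          reasons <- c(reasons, paste0("MOTIF_ABSENT:", id))
        }
      }
      if (config$strict_motif_order &&
          all(rt_motifs()$motif_id %in% motif_hits$motif_id)) {
        first_at <- function(id) {
          min(motif_hits$position[motif_hits$motif_id == id])
        }
        if (!(first_at("WY-LPQG") < first_at("QDLREVNK") &&
              first_at("QDLREVNK") < first_at("YxDD"))) {
          reasons <- c(reasons, "MOTIF_ORDER")
        }
      }
    }
  } else {
    orf1 <- orf_of("ORF1")
    orf2 <- orf_of("ORF2")
    if (is.null(orf1)) reasons <- c(reasons, "MISSING_ORF1")
    else if (orf1$truncated) reasons <- c(reasons, "TRUNCATED_ORF1")
    if (is.null(orf2)) reasons <- c(reasons, "MISSING_ORF2")
    else if (orf2$truncated) reasons <- c(reasons, "TRUNCATED_ORF2")
    if (!is.null(orf2)) {
      motif_hits <- scan_rt_motifs(orf2$aa_sequence)
      if (!"YxDD" %in% motif_hits$motif_id) {
        reasons <- c(reasons, "MOTIF_ABSENT:YxDD")
      }
    }
  }
  structure(list(locus = locus$name, element_class = locus$element_class,
                 verdict = if (length(reasons)) "defective" else "competent",
                 reasons = reasons, motif_hits = motif_hits),
            class = "competence_call")
}

#' Call competence over a whole catalog
#'
#' @param loci List of [retro_locus()] objects.
#' @param genome Genome covering all loci.
#' @param config A [competence_config()].
#' @return Data frame with one row per locus: `locus`, `class`, `verdict`,
#'   `reasons` (';'-collapsed), `motif_hits` ("id@pos" ','-collapsed).
#' @export
call_competence_all <- function(loci, genome, config = competence_config()) {
  calls <- lapply(loci, call_competence, genome = genome, config = config)
  data.frame(
    locus = vapply(calls, `[[`, character(1), "locus"),
    class = vapply(calls, `[[`, character(1), "element_class"),
    verdict = vapply(calls, `[[`, character(1), "verdict"),
    reasons = vapply(calls, function(x) paste(x$reasons, collapse = ";"),
                     character(1)),
    motif_hits = vapply(calls, function(x) {
      paste0(x$motif_hits$motif_id, "@", x$motif_hits$position,
             collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
}
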