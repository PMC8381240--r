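#' @name synthetic-data
#' @title Seedable synthetic-data generators
#' @description Generators producing every input the pipeline consumes —
#'   genomes with planted retroelement loci of known integrity class,
#'   alignments with controlled multimapping, negative-binomial count
#'   matrices with planted effects, and assay tables — with the ground truth
#'   returned alongside. All generators are pure functions of their
#'   arguments and a mandatory seed (base R Mersenne-Twister via
#'   [withr::with_seed()]), so identical inputs give byte-identical outputs.
NULL

AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

sense_codons <- function(exclude_aa = character()) {
  code <- Biostrings::GENETIC_CODE
  keep <- code != "*" & !(code %in% exclude_aa)
  names(code)[keep]
}

random_codons <- function(n, exclude_aa = character()) {
  pool <- sense_codons(exclude_aa)
  sample(pool, n, replace = TRUE)
}

encode_aa <- function(aa_string) {
  unname(AA_CODON[strsplit(aa_string, "", fixed = TRUE)[[1]]])
}

# Build a stop-free pol/ORF2 codon vector with the RT motifs spliced in at
# fixed codon positions. Filler codons avoid Asp and Gln so no RT motif can
# arise outside the planted sites (every motif requires a D or a Q).
ERV_MOTIF_AT <- c("WY-LPQG" = 101L, "QDLREVNK" = 151L, "DLKDAF" = 201L,
                  "YxDD" = 251L)

pol_codons <- function(n_codons, motifs_at = ERV_MOTIF_AT,
                       ablate_yxdd = FALSE) {
  codons <- random_codons(n_codons, exclude_aa = c("D", "Q"))
  splice <- function(codons, at, aa) {
    enc <- encode_aa(aa)
    codons[at:(at + length(enc) - 1L)] <- enc
    codons
  }
  if ("WY-LPQG" %in% names(motifs_at)) {
    # W, three spacer residues, then the LPQG box
    codons <- splice(codons, motifs_at[["WY-LPQG"]], "WAAALPQG")
  }
  if ("QDLREVNK" %in% names(motifs_at)) {
    codons <- splice(codons, motifs_at[["QDLREVNK"]], "QDLREVNK")
  }
  if ("DLKDAF" %in% names(motifs_at)) {
    codons <- splice(codons, motifs_at[["DLKDAF"]], "DLKDAF")
  }
  if ("YxDD" %in% names(motifs_at)) {
    codons <- splice(codons, motifs_at[["YxDD"]],
                     if (ablate_yxdd) "AAAA" else "YMDD")
  }
  codons
}

ERV_CLASSES <- c("intact", "gag_frameshift", "pol_premature_stop",
                 "pol_fragment", "motif_ablated")
LINE1_CLASSES <- c("intact", "missing_orf1", "truncated_orf2",
                   "motif_ablated")

#' Specification of one planted retroelement locus
#'
#' @param name Locus name (unique within a simulation).
#' @param element_class `"ERV"` or `"LINE1"`.
#' @param integrity_class Lesion to apply. ERV classes: `intact`,
#'   `gag_frameshift`, `pol_premature_stop`, `pol_fragment`,
#'   `motif_ablated`. LINE-1 classes: `intact`, `missing_orf1`,
#'   `truncated_orf2`, `motif_ablated`.
#' @param strand Insertion strand.
#' @param chrom,offset Optional insertion site; laid out automatically by
#'   [build_genome()] when `NULL`.
#' @return List of class `planted_locus_spec`.
#' @export
planted_locus_spec <- function(name, element_class, integrity_class,
                               strand = "+", chrom = NULL, offset = NULL) {
  element_class <- match.arg(element_class, c("ERV", "LINE1"))
  allowed <- if (element_class == "ERV") ERV_CLASSES else LINE1_CLASSES
  if (!integrity_class %in% allowed) {
    stop("integrity class '", integrity_class, "' is incompatible with ",
         element_class, call. = FALSE)
  }
  structure(list(name = name, element_class = element_class,
                 integrity_class = integrity_class,
                 strand = normalize_strand(strand),
                 chrom = chrom, offset = offset),
            class = "planted_locus_spec")
}

#' Build the sequence of one planted locus
#'
#' Constructs an ERV as gag + pol (stop-free ORFs, all four RT motifs
#' embedded in pol, gag in frame with pol) + env, or a LINE-1 as ORF1 +
#' ORF2 (YxDD embedded), then applies the lesion named by the integrity
#' class: a 1-nt spacer before pol (`gag_frameshift`), a TAA at a mid-pol /
#' mid-ORF2 codon (`pol_premature_stop`, `truncated_orf2`), truncation of
#' pol below the length-fraction threshold (`pol_fragment`), omission of
#' ORF1 (`missing_orf1`), or replacement of the YxDD site
#' (`motif_ablated`). The returned verdict and reasons are forced by
#' construction.
#'
#' @param spec A [planted_locus_spec()].
#' @param seed Integer seed.
#' @param config [competence_config()] supplying canonical lengths.
#' @return List with `seq` (coding-orientation nucleotide string),
#'   `segments` (list of [gene_segment()] with construct-local plus-strand
#'   coordinates), `verdict`, and `reasons`.
#' @export
build_locus_sequence <- function(spec, seed, config = competence_config()) {
  stopifnot(inherits(spec, "planted_locus_spec"))
  withr::with_seed(seed, {
    if (spec$element_class == "ERV") build_erv_sequence(spec)
    else build_line1_sequence(spec)
  })
}

build_erv_sequence <- function(spec) {
  n_gag <- 534L; n_pol <- 1200L; n_env <- 667L  # 1602 / 3600 / 2001 nt
  gag <- random_codons(n_gag)
  pol <- pol_codons(n_pol,
                    ablate_yxdd = spec$integrity_class == "motif_ablated")
  env <- random_codons(n_env)
  reasons <- character()
  spacer <- ""
  if (spec$integrity_class == "gag_frameshift") {
    spacer <- sample(c("A", "C", "G", "T"), 1L)
    reasons <- "GAG_POL_FRAMESHIFT"
  } else if (spec$integrity_class == "pol_premature_stop") {
    pol[701L] <- "TAA"
    reasons <- "TRUNCATED_POL"
  } else if (spec$integrity_class == "pol_fragment") {
    pol <- pol[1:300]  # 900 nt, fraction 0.25 of canonical pol
    reasons <- "TRUNCATED_POL"
  } else if (spec$integrity_class == "motif_ablated") {
    reasons <- "MOTIF_ABSENT:YxDD"
  }
  gag_nt <- paste(gag, collapse = "")
  pol_nt <- paste(pol, collapse = "")
  env_nt <- paste(env, collapse = "")
  gag_end <- nchar(gag_nt)
  pol_start <- gag_end + nchar(spacer) + 1L
  pol_end <- pol_start + nchar(pol_nt) - 1L
  env_start <- pol_end + 1L
  env_end <- env_start + nchar(env_nt) - 1L
  seq <- paste0(gag_nt, spacer, pol_nt, env_nt)
  segments <- list(
    gene_segment("gag", genomic_interval("local", 1L, gag_end, "+")),
    gene_segment("pol", genomic_interval("local", pol_start, pol_end, "+")),
    gene_segment("env", genomic_interval("local", env_start, env_end, "+")))
  list(seq = seq, segments = segments,
       verdict = if (length(reasons)) "defective" else "competent",
       reasons = reasons)
}

build_line1_sequence <- function(spec) {
  n_orf1 <- 334L; n_orf2 <- 1267L  # 1002 / 3801 nt
  orf2 <- pol_codons(n_orf2, motifs_at = c("YxDD" = 501L),
                     ablate_yxdd = spec$integrity_class == "motif_ablated")
  reasons <- character()
  if (spec$integrity_class == "truncated_orf2") {
    orf2[701L] <- "TAA"
    reasons <- "TRUNCATED_ORF2"
  } else if (spec$integrity_class == "motif_ablated") {
    reasons <- "MOTIF_ABSENT:YxDD"
  }
  orf2_nt <- paste(orf2, collapse = "")
  if (spec$integrity_class == "missing_orf1") {
    seq <- orf2_nt
    segments <- list(gene_segment(
      "ORF2", genomic_interval("local", 1L, nchar(orf2_nt), "+")))
    reasons <- "MISSING_ORF1"
  } else {
    orf1_nt <- paste(random_codons(n_orf1), collapse = "")
    spacer <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                    collapse = "")
    orf2_start <- nchar(orf1_nt) + nchar(spacer) + 1L
    seq <- paste0(orf1_nt, spacer, orf2_nt)
    segments <- list(
      gene_segment("ORF1",
                   genomic_interval("local", 1L, nchar(orf1_nt), "+")),
      gene_segment("ORF2",
                   genomic_interval("local", orf2_start,
                                    orf2_start + nchar(orf2_nt) - 1L, "+")))
  }
  list(seq = seq, segments = segments,
       verdict = if (length(reasons)) "defective" else "competent",
       reasons = reasons)
}

#' Simulation specification
#'
#' Bundles the conditions of a synthetic experiment: the planted loci, the
#' expression weights and read counts for alignment simulation, and the
#' NB parameters for count simulation.
#'
#' @param seed Mandatory integer seed.
#' @param loci List of [planted_locus_spec()] objects.
#' @param chrom_lengths Named integer vector; computed to fit the planted
#'   loci when `NULL`.
#' @param expression Named per-locus expression weights (uniform if `NULL`).
#' @param n_reads Number of uniquely mapped reads to draw over loci.
#' @param read_length Read length in nt.
#' @param multimap_fraction Fraction of `n_reads` additionally emitted as
#'   NH = 2 duplicate records at the two `paralogs`.
#' @param paralogs Character vector of two locus names used as the
#'   multimapping paralog pair.
#' @param dispersion NB dispersion for count simulation.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, loci, chrom_lengths = NULL,
                            expression = NULL, n_reads = 2000L,
                            read_length = 50L, multimap_fraction = 0,
                            paralogs = NULL, dispersion = 0.1) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(loci) >= 0L,
            n_reads >= 0L, read_length >= 1L,
            multimap_fraction >= 0, multimap_fraction <= 1)
  ok <- vapply(loci, inherits, logical(1), "planted_locus_spec")
  if (!all(ok)) stop("loci must be planted_locus_spec objects", call. = FALSE)
  nm <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate planted locus names", call. = FALSE)
  if (multimap_fraction > 0 && length(paralogs) != 2L) {
    stop("multimapping requires a pair of paralog locus names",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), loci = loci,
                 chrom_lengths = chrom_lengths, expression = expression,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 multimap_fraction = multimap_fraction, paralogs = paralogs,
                 dispersion = dispersion),
            class = "simulation_spec")
}

#' Build a synthetic genome with planted loci
#'
#' Uniform-random ACGT background with each planted locus inserted at its
#' (possibly auto-laid-out) site; minus-strand loci are inserted as the
#' reverse complement of their construct. Catalog coordinates are 1-based
#' inclusive, as in [parse_locus_table()].
#'
#' @param sim A [simulation_spec()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `fasta_text`,
#'   `catalog` (list of [retro_locus()]), `catalog_tsv` (table1-dialect
#'   text), and `truth` (data frame `locus`, `verdict`, `reasons`).
#' @export
build_genome <- function(sim) {
  stopifnot(inherits(sim, "simulation_spec"))
  built <- lapply(seq_along(sim$loci), function(i) {
    build_locus_sequence(sim$loci[[i]], seed = sim$seed + i)
  })
  layout <- layout_loci(sim, vapply(built, function(b) nchar(b$seq),
                                    integer(1)))
  chrom_lengths <- layout$chrom_lengths
  withr::with_seed(sim$seed, {
    chrom_seqs <- lapply(chrom_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    })
  })
  catalog <- list()
  for (i in seq_along(sim$loci)) {
    spec <- sim$loci[[i]]
    b <- built[[i]]
    chrom <- layout$chrom[i]
    off <- layout$offset[i]
    L <- nchar(b$seq)
    insert <- if (spec$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(b$seq)))
    } else b$seq
    s <- chrom_seqs[[chrom]]
    chrom_seqs[[chrom]] <- paste0(substr(s, 1L, off - 1L), insert,
                                  substr(s, off + L, nchar(s)))
    segments <- lapply(b$segments, function(seg) {
      iv <- seg$interval
      if (spec$strand == "+") {
        gene_segment(seg$role, genomic_interval(chrom, off + iv$start - 1L,
                                                off + iv$end - 1L, "+"))
      } else {
        gene_segment(seg$role, genomic_interval(chrom, off + (L - iv$end),
                                                off + (L - iv$start), "-"))
      }
    })
    catalog[[i]] <- retro_locus(spec$name, spec$element_class, segments)
  }
  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  truth <- data.frame(
    locus = vapply(sim$loci, `[[`, character(1), "name"),
    verdict = vapply(built, `[[`, character(1), "verdict"),
    reasons = vapply(built, function(b) paste(b$reasons, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  list(genome = genome, fasta_text = fasta_text(genome), catalog = catalog,
       catalog_tsv = catalog_tsv(catalog), truth = truth)
}

layout_loci <- function(sim, lengths) {
  n <- length(sim$loci)
  chrom <- vapply(sim$loci, function(s) {
    if (is.null(s$chrom)) NA_character_ else s$chrom
  }, character(1))
  offset <- vapply(sim$loci, function(s) {
    if (is.null(s$offset)) NA_integer_ else as.integer(s$offset)
  }, integer(1))
  auto <- is.na(chrom)
  if (any(auto != is.na(offset))) {
    stop("specify both chrom and offset, or neither", call. = FALSE)
  }
  chrom_names <- if (!is.null(sim$chrom_lengths)) names(sim$chrom_lengths)
                 else unique(c(stats::na.omit(chrom),
                               paste0("chr", 1:4)))[seq_len(min(4L, max(1L, n)))]
  if (any(auto)) {
    # round-robin placement with 1 kb leading margin and 2 kb gaps;
    # fixed placements reserve their span first
    cursor <- stats::setNames(rep(1001L, length(chrom_names)), chrom_names)
    fixed <- which(!auto)
    for (i in fixed) {
      cursor[chrom[i]] <- max(cursor[chrom[i]],
                              offset[i] + lengths[i] + 2000L)
    }
    k <- 0L
    for (i in which(auto)) {
      cn <- chrom_names[(k %% length(chrom_names)) + 1L]
      chrom[i] <- cn
      offset[i] <- cursor[cn]
      cursor[cn] <- cursor[cn] + lengths[i] + 2000L
      k <- k + 1L
    }
  }
  chrom_lengths <- sim$chrom_lengths
  if (is.null(chrom_lengths)) {
    all_names <- unique(c(chrom_names, chrom[!is.na(chrom)]))
    chrom_lengths <- stats::setNames(rep(2000L, length(all_names)),
                                     all_names)
    for (i in seq_len(n)) {
      chrom_lengths[chrom[i]] <- max(chrom_lengths[chrom[i]],
                                     offset[i] + lengths[i] + 2000L)
    }
  }
  # overlap check
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    if (length(idx) < 2L) next
    o <- order(offset[idx])
    starts <- offset[idx][o]; ends <- starts + lengths[idx][o] - 1L
    if (any(starts[-1] <= ends[-length(ends)])) {
      stop("planted loci overlap on ", cn, call. = FALSE)
    }
  }
  for (i in seq_len(n)) {
    if (offset[i] + lengths[i] - 1L > chrom_lengths[chrom[i]]) {
      stop("planted locus '", sim$loci[[i]]$name,
           "' does not fit its chromosome", call. = FALSE)
    }
  }
  list(chrom = chrom, offset = offset, chrom_lengths = chrom_lengths)
}

fasta_text <- function(genome) {
  paste0(paste(vapply(seq_along(genome), function(i) {
    seq <- as.character(genome[[i]])
    wrapped <- paste(substring(seq, seq(1L, nchar(seq), 70L),
                               pmin(seq(70L, nchar(seq) + 69L, 70L),
                                    nchar(seq))),
                     collapse = "\n")
    paste0(">", names(genome)[i], "\n", wrapped)
  }, character(1)), collapse = "\n"), "\n")
}

catalog_tsv <- function(catalog) {
  roles <- c("gag", "pol", "env", "ORF1", "ORF2")
  header <- paste(c("name", "class", roles, "aliases"), collapse = "\t")
  rows <- vapply(catalog, function(locus) {
    cells <- vapply(roles, function(role) {
      seg <- get_segment(locus, role)
      if (is.null(seg)) return("")
      iv <- seg$interval
      paste0(iv$chrom, ":", iv$start, "-", iv$end, " (", iv$strand, ")")
    }, character(1))
    paste(c(locus$name, locus$element_class, cells,
            paste(locus$aliases, collapse = ",")), collapse = "\t")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Simulate perfectly matching alignments with known per-locus counts
#'
#' Draws per-locus read counts proportional to expression weights, places
#' full-match reads (`<len>M`) at uniform positions within locus
#' footprints, adds background reads rejection-sampled outside every
#' footprint, and emits a `multimap_fraction` of reads as duplicate NH = 2
#' records at the two paralog sites (plus optional NH = 3 reads that the
#' multimapper filter must discard entirely). Ground-truth per-locus counts
#' under the best-overlap contract accompany the SAM: a unique read counts
#' toward its source locus, an NH = 2 paralog read toward the
#' lexicographically smaller paralog (both overlaps are full read length),
#' and NH = 3, background and unmapped records toward none.
#'
#' @param sim A [simulation_spec()].
#' @param genome_build Result of [build_genome()] for `sim`.
#' @param n_background Background reads outside all footprints.
#' @param nh3_reads Reads emitted as NH = 3 triplicate records.
#' @param n_unmapped Records flagged unmapped.
#' @return List with `sam_text`, `truth_counts` (named integer vector over
#'   all loci), and `truth_library_size` (fragments retained after NH <= 2
#'   filtering).
#' @export
simulate_alignments <- function(sim, genome_build, n_background = 100L,
                                nh3_reads = 0L, n_unmapped = 0L) {
  stopifnot(inherits(sim, "simulation_spec"))
  genome <- genome_build$genome
  catalog <- genome_build$catalog
  locus_names <- vapply(catalog, `[[`, character(1), "name")
  fps <- lapply(catalog, locus_footprint)
  names(fps) <- locus_names
  len <- sim$read_length
  for (fp in fps) {
    if (fp$end - fp$start + 1L < len) {
      stop("footprint narrower than the read length", call. = FALSE)
    }
  }
  weights <- sim$expression
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(catalog)), locus_names)
  }
  weights <- weights[locus_names]
  truth <- stats::setNames(integer(length(catalog)), locus_names)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  read_seq <- function(chrom, pos) {
    as.character(Biostrings::subseq(genome[[chrom]], pos, pos + len - 1L))
  }
  qual <- strrep("I", len)
  cigar <- paste0(len, "M")
  sam_line <- function(qname, flag, chrom, pos, nh) {
    paste(qname, flag, chrom, pos, 255L, cigar, "*", 0L, 0L,
          read_seq(chrom, pos), qual, paste0("NH:i:", nh), sep = "\t")
  }
  lines <- character()
  withr::with_seed(sim$seed + 104729L, {
    if (sim$n_reads > 0L && length(catalog) > 0L) {
      per_locus <- as.integer(stats::rmultinom(1L, sim$n_reads,
                                               prob = weights))
      for (i in seq_along(catalog)) {
        if (per_locus[i] == 0L) next
        fp <- fps[[i]]
        pos <- sample.int(fp$end - len + 1L - fp$start + 1L,
                          per_locus[i], replace = TRUE) + fp$start - 1L
        lines <- c(lines, vapply(seq_len(per_locus[i]), function(j) {
          sam_line(paste0("u", i, "_", j), 0L, fp$chrom, pos[j], 1L)
        }, character(1)))
        truth[i] <- truth[i] + per_locus[i]
      }
    }
    n_mm <- as.integer(round(sim$multimap_fraction * sim$n_reads))
    if (n_mm > 0L) {
      fp1 <- fps[[sim$paralogs[1]]]
      fp2 <- fps[[sim$paralogs[2]]]
      wmin <- min(fp1$end - fp1$start, fp2$end - fp2$start) + 1L
      rel <- sample.int(wmin - len + 1L, n_mm, replace = TRUE) - 1L
      for (j in seq_len(n_mm)) {
        q <- paste0("mm", j)
        lines <- c(lines,
                   sam_line(q, 0L, fp1$chrom, fp1$start + rel[j], 2L),
                   sam_line(q, 256L, fp2$chrom, fp2$start + rel[j], 2L))
      }
      winner <- sort(sim$paralogs)[1]
      truth[winner] <- truth[winner] + n_mm
    }
    sample_background <- function() {
      repeat {
        chrom <- sample(names(chrom_len), 1L)
        pos <- sample.int(chrom_len[[chrom]] - len + 1L, 1L)
        clash <- any(vapply(fps, function(fp) {
          fp$chrom == chrom && pos <= fp$end && pos + len - 1L >= fp$start
        }, logical(1)))
        if (!clash) return(list(chrom = chrom, pos = pos))
      }
    }
    if (nh3_reads > 0L) {
      fp1 <- fps[[sim$paralogs[1]]]
      fp2 <- fps[[sim$paralogs[2]]]
      for (j in seq_len(nh3_reads)) {
        q <- paste0("n3_", j)
        bg <- sample_background()
        lines <- c(lines,
                   sam_line(q, 0L, fp1$chrom, fp1$start, 3L),
                   sam_line(q, 256L, fp2$chrom, fp2$start, 3L),
                   sam_line(q, 256L, bg$chrom, bg$pos, 3L))
      }
    }
    if (n_background > 0L) {
      for (j in seq_len(n_background)) {
        bg <- sample_background()
        lines <- c(lines, sam_line(paste0("bg", j), 0L, bg$chrom, bg$pos, 1L))
      }
    }
    if (n_unmapped > 0L) {
      for (j in seq_len(n_unmapped)) {
        lines <- c(lines, paste(paste0("un", j), 4L, "*", 0L, 0L, "*", "*",
                                0L, 0L, strrep("A", len), qual, sep = "\t"))
      }
    }
  })
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(chrom_len), "\tLN:", chrom_len))
  list(sam_text = paste0(paste(c(header, lines), collapse = "\n"), "\n"),
       truth_counts = truth,
       truth_library_size = as.integer(sum(truth) + n_background))
}

#' Simulate an NB count matrix with planted differential expression
#'
#' Group-1 means are the baseline; group-2 means are baseline times the
#' per-feature fold change. Counts are NB draws at the stated dispersion
#' (`dispersion = 0` gives Poisson draws). The planted truth set is the
#' features whose fold change differs from 1.
#'
#' @param fold_change Numeric vector, one per feature.
#' @param n_per_group Samples per group (>= 2).
#' @param dispersion NB dispersion (>= 0).
#' @param seed Integer seed.
#' @param baseline_mean Per-feature baseline means; drawn lognormal
#'   (meanlog log 100, sdlog 1) when `NULL`.
#' @param feature_names Optional feature names.
#' @return List with `counts`, `groups`, `truth` (planted feature names),
#'   `baseline_mean`, `fold_change`.
#' @export
simulate_counts <- function(fold_change, n_per_group, dispersion, seed,
                            baseline_mean = NULL, feature_names = NULL) {
  stopifnot(n_per_group >= 2L, dispersion >= 0, length(fold_change) >= 1L)
  n <- length(fold_change)
  if (is.null(feature_names)) {
    feature_names <- sprintf("feature%04d", seq_len(n))
  }
  withr::with_seed(seed, {
    if (is.null(baseline_mean)) {
      baseline_mean <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    }
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(length(mu), lambda = mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    g1 <- vapply(seq_len(n_per_group), function(j) draw(baseline_mean),
                 numeric(n))
    g2 <- vapply(seq_len(n_per_group),
                 function(j) draw(baseline_mean * fold_change), numeric(n))
  })
  counts <- cbind(g1, g2)
  storage.mode(counts) <- "integer"
  rownames(counts) <- feature_names
  colnames(counts) <- c(paste0("ctrl", seq_len(n_per_group)),
                        paste0("case", seq_len(n_per_group)))
  list(counts = counts,
       groups = rep(c("ctrl", "case"), each = n_per_group),
       truth = feature_names[fold_change != 1],
       baseline_mean = baseline_mean, fold_change = fold_change)
}

#' Simulate a qPCR CT table with known expression ratios
#'
#' CT pairs are generated so that [relative_expression()] recovers the
#' planted per-target control value and ratio, up to Gaussian CT noise: the
#' control target CT is `ct_housekeeping - log2(value / 1e4)` and the case
#' target CT subtracts a further `log2(ratio)` cycles.
#'
#' @param ratio Named numeric vector: planted case/control expression ratio
#'   per target.
#' @param n_per_group Samples per group.
#' @param noise_sd Gaussian noise (cycles) added independently to each CT.
#' @param seed Integer seed.
#' @param ct_housekeeping Housekeeping CT baseline (cycles).
#' @param baseline_value Control-group relative-expression value.
#' @return List with `table` (columns `sample`, `group`, `target`,
#'   `ct_target`, `ct_housekeeping`) and `truth` (the `ratio` vector).
#' @export
simulate_ct_table <- function(ratio, n_per_group = 5L, noise_sd = 0,
                              seed = 1L, ct_housekeeping = 20,
                              baseline_value = 100) {
  stopifnot(!is.null(names(ratio)), all(ratio > 0), n_per_group >= 1L,
            noise_sd >= 0)
  rows <- list()
  withr::with_seed(seed, {
    for (tg in names(ratio)) {
      for (grp in c("unassociated", "associated")) {
        value <- baseline_value * if (grp == "associated") ratio[[tg]] else 1
        dct <- log2(value / 1e4)  # ct_hk - ct_target
        for (j in seq_len(n_per_group)) {
          ct_hk <- ct_housekeeping + stats::rnorm(1, sd = noise_sd)
          ct_tg <- ct_housekeeping - dct + stats::rnorm(1, sd = noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = paste0(substr(grp, 1, 5), j), group = grp, target = tg,
            ct_target = ct_tg, ct_housekeeping = ct_hk,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(table = do.call(rbind, rows), truth = ratio)
}

#' Simulate a flow-cytometry frequency/MFI table
#'
#' @param frequency Numeric vector of population frequencies (percent of
#'   parent, 0-100).
#' @param mfi Numeric vector of MFI values (same length).
#' @param population Optional population labels.
#' @return List with `table` (columns `population`, `frequency`, `mfi`) and
#'   `truth_imfi` (the planted frequency x MFI products).
#' @export
simulate_flow_table <- function(frequency, mfi, population = NULL) {
  stopifnot(length(frequency) == length(mfi))
  if (is.null(population)) {
    population <- paste0("pop", seq_along(frequency))
  }
  list(table = data.frame(population = population, frequency = frequency,
                          mfi = mfi, stringsAsFactors = FALSE),
       truth_imfi = stats::setNames(frequency * mfi, population))
}
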