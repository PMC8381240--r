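# Independent brute-force oracles. These deliberately share no code with the
# package: naive loops and table lookups only, so they can arbitrate.

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "", fixed = TRUE)[[1]]]), collapse = "")
}

# codon -> amino acid, via the standard-code table as data (not translate())
oracle_translate <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3L * i - 2L, 3L * i)
    out[i] <- if (grepl("[^ACGT]", codon)) "X" else code[[codon]]
  }
  paste(out, collapse = "")
}

# sliding-window motif scan with per-position character checks
oracle_scan_motifs <- function(aa) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  defs <- list(
    YxDD = list("Y", std, "D", "D"),
    DLKDAF = as.list(strsplit("DLKDAF", "", fixed = TRUE)[[1]]),
    `WY-LPQG` = c(list(c("W", "Y"), std, std, std),
                  as.list(strsplit("LPQG", "", fixed = TRUE)[[1]])),
    QDLREVNK = as.list(strsplit("QDLREVNK", "", fixed = TRUE)[[1]]))
  hits <- list()
  for (id in names(defs)) {
    def <- defs[[id]]
    w <- length(def)
    if (length(chars) < w) next
    for (p in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        if (!chars[p + k - 1L] %in% def[[k]]) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1L]] <- data.frame(
        motif_id = id, position = p - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif_id = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$position, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# walk a cigar op by op, tracking the reference cursor
oracle_cigar_blocks <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSH=X]", cigar))[[1]]
  ref <- pos
  blocks <- list()
  cur_start <- NA_integer_
  for (op in ops) {
    n <- as.integer(sub("[MIDNSH=X]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + n
    } else if (type == "N") {
      if (!is.na(cur_start)) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, ref - 1L)
        cur_start <- NA_integer_
      }
      ref <- ref + n
    }
    # I, S, H consume no reference
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1L]] <- c(cur_start, ref - 1L)
  if (!length(blocks)) return(matrix(integer(), ncol = 2))
  do.call(rbind, blocks)
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  mid <- paste(vapply(seq_len(n_ops), function(i) {
    paste0(sample(1:80, 1), sample(c("M", "M", "M", "=", "X", "I", "D", "N"), 1))
  }, character(1)), collapse = "")
  # ensure the alignment starts and ends with an aligned run
  paste0(sample(1:30, 1), "M", mid, sample(1:30, 1), "M")
}

# step-up definition, straight from the formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# brute-force fragment counting over footprints
oracle_count <- function(reads, blocks, loci, mode = "best") {
  fps <- lapply(loci, retrolocus::locus_footprint)
  names(fps) <- vapply(loci, `[[`, character(1), "name")
  counts <- setNames(integer(length(fps)), names(fps))
  for (rid in unique(reads$read_id)) {
    rows <- which(reads$read_id == rid)
    ov <- setNames(integer(length(fps)), names(fps))
    for (r in rows) {
      b <- blocks[[r]]
      for (k in seq_along(b)) {
        bs <- IRanges::start(b)[k]; be <- IRanges::end(b)[k]
        for (nm in names(fps)) {
          fp <- fps[[nm]]
          if (fp$chrom != reads$chrom[r]) next
          w <- min(be, fp$end) - max(bs, fp$start) + 1L
          if (w > 0L) ov[nm] <- ov[nm] + w
        }
      }
    }
    hit <- names(ov)[ov > 0L]
    if (!length(hit)) next
    if (mode == "any") {
      counts[hit] <- counts[hit] + 1L
    } else {
      best <- hit[ov[hit] == max(ov[hit])]
      best <- sort(best)[1]
      counts[best] <- counts[best] + 1L
    }
  }
  counts
}

# one-line SAM builder for hand-made fixtures
sam_record <- function(qname, chrom, pos, cigar, nh = NULL, flag = 0L,
                       seq = "*") {
  tags <- if (is.null(nh)) character() else paste0("NH:i:", nh)
  paste(c(qname, flag, chrom, pos, 255, cigar, "*", 0, 0, seq, "*", tags),
        collapse = "\t")
}

# small standard catalog used across quantification tests
two_locus_catalog <- function() {
  list(retro_locus("locusA", "ERV",
                   list(gene_segment("pol",
                                     genomic_interval("chr1", 101L, 400L, "+")))),
       retro_locus("locusB", "ERV",
                   list(gene_segment("pol",
                                     genomic_interval("chr1", 431L, 700L, "+")))))
}
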