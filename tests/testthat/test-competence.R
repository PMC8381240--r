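make_orf <- function(n_codons, seed = 1) {
  withr::with_seed(seed, {
    pool <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    paste(sample(pool, n_codons, replace = TRUE), collapse = "")
  })
}

test_that("ORF assessment detects premature stops and length erosion", {
  cfg <- competence_config()
  pol <- make_orf(1200, seed = 21)  # 3600 nt, canonical for pol
  rep_ok <- assess_orf(pol, "pol", cfg)
  expect_false(rep_ok$truncated)
  expect_true(is.na(rep_ok$premature_stop_index))
  expect_identical(nchar(rep_ok$aa_sequence), 1200L)

  # mutate codon 100 (0-based) to TAA
  mutated <- paste0(substr(pol, 1, 300), "TAA", substr(pol, 304, nchar(pol)))
  rep_stop <- assess_orf(mutated, "pol", cfg)
  expect_true(rep_stop$truncated)
  expect_identical(rep_stop$premature_stop_index, 100L)

  # a stop inside the terminal window does not truncate
  tail_stop <- paste0(substr(pol, 1, 3594), "TAA", substr(pol, 3598, 3600))
  expect_false(assess_orf(tail_stop, "pol", cfg)$truncated)

  # 300 nt of a 3600-nt-canonical role fails the length fraction
  frag <- assess_orf(substr(pol, 1, 300), "pol", cfg)
  expect_true(frag$truncated)
  expect_lt(frag$length_fraction, cfg$min_length_fraction)
  expect_true(is.na(frag$premature_stop_index))
})

test_that("stop-free full-length ORFs are never called truncated", {
  cfg <- competence_config()
  for (seed in 1:10) {
    rep <- assess_orf(make_orf(540, seed = seed), "gag", cfg)
    expect_true(is.na(rep$premature_stop_index))
    expect_gte(rep$length_fraction, cfg$min_length_fraction)
    expect_false(rep$truncated)
  }
})

test_that("gag/pol frame relation uses strand-oriented CDS starts", {
  mk <- function(gag_start, gag_end, pol_start, pol_end, strand = "+") {
    retro_locus("x", "ERV", list(
      gene_segment("gag", genomic_interval("chr1", gag_start, gag_end, strand)),
      gene_segment("pol", genomic_interval("chr1", pol_start, pol_end, strand))))
  }
  expect_identical(gag_pol_frame_relation(mk(1L, 300L, 301L, 600L)),
                   list(gag_pol_offset = 0L, in_frame = TRUE))
  r1 <- gag_pol_frame_relation(mk(1L, 300L, 302L, 601L))
  expect_identical(r1$gag_pol_offset, 1L)
  expect_false(r1$in_frame)
  # frameshift mode admits the configured offset
  cfg_fs <- competence_config(allowed_offsets = c(0L, 2L))
  r2 <- gag_pol_frame_relation(mk(1L, 300L, 303L, 602L), cfg_fs)
  expect_identical(r2$gag_pol_offset, 2L)
  expect_true(r2$in_frame)
  # minus strand orients by descending coordinate (offset from the ends)
  r3 <- gag_pol_frame_relation(mk(701L, 1000L, 401L, 700L, strand = "-"))
  expect_identical(r3$gag_pol_offset, 0L)
  # missing segment raises the coded condition
  gag_only <- retro_locus("y", "ERV", list(
    gene_segment("gag", genomic_interval("chr1", 1L, 300L, "+"))))
  expect_error(gag_pol_frame_relation(gag_only),
               class = "retrolocus_missing_segment")
})

test_that("motif scanning matches the stated patterns", {
  hits <- scan_rt_motifs("AAYMDDAA")
  expect_identical(hits$motif_id, "YxDD")
  expect_identical(hits$position, 2L)

  hits2 <- scan_rt_motifs("WAAALPQGQDLREVNK")
  expect_identical(hits2$motif_id, c("WY-LPQG", "QDLREVNK"))
  expect_identical(hits2$position, c(0L, 8L))

  # x never matches X or *
  expect_identical(nrow(scan_rt_motifs("YXDD")), 0L)
  expect_identical(nrow(scan_rt_motifs("Y*DD")), 0L)
  # overlapping occurrences are all reported
  y2 <- scan_rt_motifs("YYDDD")
  expect_identical(y2$position, c(0L, 1L))
})

test_that("motif scanning is shift-equivariant and matches the window oracle", {
  set.seed(403)
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  for (i in 1:40) {
    aa <- paste(sample(c(std, "X", "*"), 200, replace = TRUE,
                       prob = c(rep(0.93 / 20, 20), 0.05, 0.02)),
                collapse = "")
    got <- scan_rt_motifs(aa)
    want <- oracle_scan_motifs(aa)
    expect_identical(got$motif_id, want$motif_id)
    expect_identical(got$position, want$position)
    # prepending k residues shifts every hit by k
    k <- sample(1:10, 1)
    shifted <- scan_rt_motifs(paste0(strrep("G", k), aa))
    expect_identical(shifted$position, got$position + k)
  }
})

test_that("competence calls recover planted lesions on both strands", {
  classes <- list(ERV = c("intact", "gag_frameshift", "pol_premature_stop",
                          "pol_fragment", "motif_ablated"),
                  LINE1 = c("intact", "missing_orf1", "truncated_orf2"))
  k <- 0
  specs <- list()
  for (cls in names(classes)) for (ic in classes[[cls]]) for (st in c("+", "-")) {
    k <- k + 1
    specs[[k]] <- planted_locus_spec(sprintf("pl%02d_%s", k, ic), cls, ic,
                                     strand = st)
  }
  gb <- build_genome(simulation_spec(seed = 517, loci = specs))
  calls <- call_competence_all(gb$catalog, gb$genome)
  merged <- merge(gb$truth, calls, by = "locus")
  expect_identical(merged$verdict.y, merged$verdict.x)
  expect_identical(merged$reasons.y, merged$reasons.x)
})

test_that("relocating a locus to the minus strand leaves its call unchanged", {
  for (ic in c("intact", "pol_premature_stop", "motif_ablated")) {
    plus <- planted_locus_spec("p", "ERV", ic, strand = "+")
    minus <- planted_locus_spec("p", "ERV", ic, strand = "-")
    gb_p <- build_genome(simulation_spec(seed = 99, loci = list(plus)))
    gb_m <- build_genome(simulation_spec(seed = 99, loci = list(minus)))
    call_p <- call_competence(gb_p$catalog[[1]], gb_p$genome)
    call_m <- call_competence(gb_m$catalog[[1]], gb_m$genome)
    expect_identical(call_p$verdict, call_m$verdict)
    expect_identical(call_p$reasons, call_m$reasons)
    expect_identical(call_p$motif_hits, call_m$motif_hits)
  }
})

test_that("strict motif order is an opt-in extra requirement", {
  spec <- planted_locus_spec("p", "ERV", "intact")
  gb <- build_genome(simulation_spec(seed = 7, loci = list(spec)))
  # the generator plants motifs in the canonical order, so strict mode agrees
  strict <- competence_config(strict_motif_order = TRUE)
  expect_identical(call_competence(gb$catalog[[1]], gb$genome, strict)$verdict,
                   "competent")
})
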