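test_that("locus construction plants the intended lesions", {
  intact <- build_locus_sequence(planted_locus_spec("a", "ERV", "intact"),
                                 seed = 61)
  expect_identical(intact$verdict, "competent")
  expect_identical(intact$reasons, character())
  roles <- vapply(intact$segments, function(s) s$role, character(1))
  expect_identical(roles, c("gag", "pol", "env"))

  stopped <- build_locus_sequence(
    planted_locus_spec("b", "ERV", "pol_premature_stop"), seed = 61)
  expect_identical(stopped$verdict, "defective")
  expect_identical(stopped$reasons, "TRUNCATED_POL")

  # motif ablation removes YxDD but keeps the other three motifs
  ablated <- build_locus_sequence(
    planted_locus_spec("c", "ERV", "motif_ablated"), seed = 61)
  pol_seg <- ablated$segments[[2]]
  pol_nt <- substr(ablated$seq, pol_seg$interval$start, pol_seg$interval$end)
  hits <- oracle_scan_motifs(oracle_translate(pol_nt))
  expect_false("YxDD" %in% hits$motif_id)
  expect_true(all(c("DLKDAF", "WY-LPQG", "QDLREVNK") %in% hits$motif_id))

  # and the intact pol carries all four, by the same oracle
  pol_seg_i <- intact$segments[[2]]
  pol_nt_i <- substr(intact$seq, pol_seg_i$interval$start,
                     pol_seg_i$interval$end)
  hits_i <- oracle_scan_motifs(oracle_translate(pol_nt_i))
  expect_true(all(c("YxDD", "DLKDAF", "WY-LPQG", "QDLREVNK") %in%
                    hits_i$motif_id))

  expect_error(planted_locus_spec("x", "LINE1", "gag_frameshift"),
               "incompatible")
  expect_error(planted_locus_spec("x", "ERV", "missing_orf1"),
               "incompatible")
})

test_that("genome building is deterministic and round-trips sequences", {
  specs <- list(planted_locus_spec("p1", "ERV", "intact", strand = "+"),
                planted_locus_spec("p2", "LINE1", "intact", strand = "-"))
  sim <- simulation_spec(seed = 62, loci = specs)
  gb1 <- build_genome(sim)
  gb2 <- build_genome(sim)
  expect_identical(gb1$fasta_text, gb2$fasta_text)
  expect_identical(gb1$catalog_tsv, gb2$catalog_tsv)

  # extracting each cataloged segment reproduces the built construct
  for (i in seq_along(specs)) {
    built <- build_locus_sequence(specs[[i]], seed = sim$seed + i)
    locus <- gb1$catalog[[i]]
    for (seg in built$segments) {
      cat_seg <- locus$segments[[which(
        vapply(locus$segments, function(s) s$role, character(1)) ==
          seg$role)]]
      expect_identical(
        extract_segment_sequence(gb1$genome, cat_seg),
        substr(built$seq, seg$interval$start, seg$interval$end))
    }
  }

  # catalog TSV parses back to identical coordinates
  reparsed <- parse_locus_table(gb1$catalog_tsv)
  expect_identical(length(reparsed), length(gb1$catalog))
  for (i in seq_along(reparsed)) {
    fp_a <- locus_footprint(reparsed[[i]])
    fp_b <- locus_footprint(gb1$catalog[[i]])
    expect_identical(fp_a, fp_b)
  }

  # zero planted loci: pure background, empty catalog
  empty <- build_genome(simulation_spec(seed = 63, loci = list(),
                                        chrom_lengths = c(chrZ = 5000L)))
  expect_length(empty$catalog, 0L)
  expect_identical(Biostrings::width(empty$genome), 5000L)
})

test_that("simulated alignments carry exact ground-truth counts", {
  specs <- list(planted_locus_spec("ealpha", "ERV", "intact", "+"),
                planted_locus_spec("ebeta", "ERV", "intact", "-"),
                planted_locus_spec("lgamma", "LINE1", "intact", "+"))
  sim <- simulation_spec(seed = 64, loci = specs, n_reads = 400,
                         expression = c(ealpha = 4, ebeta = 2, lgamma = 1),
                         multimap_fraction = 0.08,
                         paralogs = c("ealpha", "ebeta"))
  gb <- build_genome(sim)
  al <- simulate_alignments(sim, gb, n_background = 40, nh3_reads = 12,
                            n_unmapped = 3)
  expect_identical(simulate_alignments(sim, gb, n_background = 40,
                                       nh3_reads = 12,
                                       n_unmapped = 3)$sam_text,
                   al$sam_text)  # same seed, byte-identical

  recs <- read_alignments(al$sam_text)
  kept <- filter_multimappers(recs, max_loci = 2)
  got <- count_by_locus(kept, gb$catalog)
  expect_identical(got$counts, al$truth_counts)
  expect_identical(got$library_size, al$truth_library_size)

  # NH = 3 reads contribute nothing anywhere
  nh3_ids <- unique(recs$reads$read_id[recs$reads$nh == 3L])
  expect_gt(length(nh3_ids), 0L)
  expect_false(any(nh3_ids %in% kept$reads$read_id))

  # with multimapping off, every record is NH = 1
  sim0 <- simulation_spec(seed = 65, loci = specs, n_reads = 100)
  al0 <- simulate_alignments(sim0, build_genome(sim0), n_background = 0)
  expect_true(all(read_alignments(al0$sam_text)$reads$nh == 1L))
})

test_that("count simulation honours its generative contract", {
  # fold changes all 1: empty truth set
  null_sim <- simulate_counts(rep(1, 20), n_per_group = 3, dispersion = 0.1,
                              seed = 66)
  expect_length(null_sim$truth, 0L)
  # same seed, identical matrix
  expect_identical(simulate_counts(rep(1, 20), 3, 0.1, seed = 66)$counts,
                   null_sim$counts)
  # dispersion 0 is Poisson: variance tracks the mean across replicates
  pois <- simulate_counts(rep(1, 2000), n_per_group = 50, dispersion = 0,
                          seed = 67, baseline_mean = rep(100, 2000))
  v <- apply(pois$counts[, 1:50], 1, var)
  expect_lt(abs(mean(v) - 100) / 100, 0.1)
})
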