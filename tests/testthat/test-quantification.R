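test_that("cigar arithmetic yields the expected reference blocks", {
  recs <- read_alignments(sam_record("r1", "chr1", 101, "50M", nh = 1))
  expect_identical(as.integer(IRanges::start(recs$blocks[[1]])), 101L)
  expect_identical(as.integer(IRanges::end(recs$blocks[[1]])), 150L)

  spliced <- read_alignments(sam_record("r2", "chr1", 1, "20M100N30M"))
  b <- spliced$blocks[[1]]
  expect_identical(as.integer(IRanges::start(b)), c(1L, 121L))
  expect_identical(as.integer(IRanges::end(b)), c(20L, 150L))

  # NH absent means unique; unmapped flag clears mapped
  expect_identical(spliced$reads$nh, 1L)
  un <- read_alignments(paste("u", 4, "*", 0, 0, "*", "*", 0, 0, "A", "*",
                              sep = "\t"))
  expect_false(un$reads$mapped)
})

test_that("malformed SAM lines are rejected with a line number", {
  expect_error(read_alignments("r1\t0\tchr1\t100"), "line 1")
  ok_then_bad <- c(sam_record("r1", "chr1", 1, "10M"),
                   "r2\t0\tchr1\txyz\t0\t10M\t*\t0\t0\tA\t*")
  expect_error(read_alignments(ok_then_bad), "line 2")
  expect_error(read_alignments(sam_record("r1", "chr1", 1, "10Q")),
               "unsupported cigar")
})

test_that("random cigars match the naive walker oracle", {
  set.seed(404)
  for (i in 1:1000) {
    cigar <- random_cigar()
    pos <- sample(1:5000, 1)
    recs <- read_alignments(sam_record("r", "chr1", pos, cigar))
    got <- cbind(as.integer(IRanges::start(recs$blocks[[1]])),
                 as.integer(IRanges::end(recs$blocks[[1]])))
    want <- oracle_cigar_blocks(cigar, pos)
    expect_identical(got, matrix(as.integer(want), ncol = 2))
  }
})

test_that("multimapper exclusion removes whole reads above the threshold", {
  sam <- c(sam_record("a", "chr1", 10, "10M", nh = 1),
           sam_record("b", "chr1", 20, "10M", nh = 2),
           sam_record("b", "chr2", 20, "10M", nh = 2, flag = 256),
           sam_record("c", "chr1", 30, "10M", nh = 3),
           sam_record("c", "chr2", 30, "10M", nh = 3, flag = 256),
           sam_record("c", "chr3", 30, "10M", nh = 3, flag = 256))
  recs <- read_alignments(sam)
  kept <- filter_multimappers(recs, max_loci = 2)
  expect_setequal(unique(kept$reads$read_id), c("a", "b"))
  # nh = 3 reads vanish entirely, not partially
  expect_false("c" %in% kept$reads$read_id)
  # raising the threshold is monotone: nothing previously kept is lost
  kept3 <- filter_multimappers(recs, max_loci = 3)
  expect_true(all(kept$reads$read_id %in% kept3$reads$read_id))
  expect_true("c" %in% kept3$reads$read_id)
  # empty input passes through
  empty <- filter_multimappers(read_alignments(character()), 2)
  expect_identical(nrow(empty$reads), 0L)
})

test_that("best-overlap assigns each fragment to its dominant locus", {
  loci <- two_locus_catalog()  # A: chr1 101-400, B: chr1 431-700
  inside <- read_alignments(sam_record("r1", "chr1", 150, "50M"))
  res <- count_by_locus(inside, loci)
  expect_identical(res$counts, c(locusA = 1L, locusB = 0L))

  # spans the gap: 30 bp in A (371..400), 10 bp in B (431..440)
  spanning <- read_alignments(sam_record("r2", "chr1", 371, "70M"))
  res2 <- count_by_locus(spanning, loci)
  expect_identical(res2$counts, c(locusA = 1L, locusB = 0L))
  res2any <- count_by_locus(spanning, loci, assignment = "any-overlap")
  expect_identical(res2any$counts, c(locusA = 1L, locusB = 1L))

  # exact tie goes to the lexicographically smaller name
  touching <- retro_locus("locusAA", "ERV", list(
    gene_segment("pol", genomic_interval("chr1", 401L, 430L, "+"))))
  tie_loci <- list(retro_locus("locusZ", "ERV", list(
    gene_segment("pol", genomic_interval("chr1", 341L, 400L, "+")))),
    touching)
  # read 391..430: 10 bp in locusZ, 30 bp in locusAA -> locusAA; make it a tie
  tie_read <- read_alignments(sam_record("r3", "chr1", 386, "30M"))
  # 386..415: 15 bp in each
  res3 <- count_by_locus(tie_read, tie_loci)
  expect_identical(res3$counts[["locusAA"]], 1L)
  expect_identical(res3$counts[["locusZ"]], 0L)
})

test_that("mates sharing a read id count as one fragment", {
  loci <- two_locus_catalog()
  pair <- c(sam_record("frag1", "chr1", 110, "30M", flag = 99),
            sam_record("frag1", "chr1", 200, "30M", flag = 147))
  res <- count_by_locus(read_alignments(pair), loci)
  expect_identical(res$counts[["locusA"]], 1L)
  expect_identical(res$library_size, 1L)
})

test_that("counts are order-invariant and match the brute-force oracle", {
  set.seed(405)
  loci <- two_locus_catalog()
  sam <- vapply(1:200, function(i) {
    sam_record(paste0("r", i), "chr1", sample(1:750, 1),
               paste0(sample(c(20, 35, 50), 1), "M"))
  }, character(1))
  recs <- read_alignments(sam)
  res <- count_by_locus(recs, loci)
  expect_identical(res$counts,
                   oracle_count(recs$reads, recs$blocks, loci, "best"))
  res_any <- count_by_locus(recs, loci, assignment = "any-overlap")
  expect_identical(res_any$counts,
                   oracle_count(recs$reads, recs$blocks, loci, "any"))
  shuffled <- read_alignments(sample(sam))
  expect_identical(count_by_locus(shuffled, loci)$counts, res$counts)
  # each fragment counted at most once under best-overlap
  expect_lte(sum(res$counts), res$library_size)
})

test_that("stranded counting restricts to same-strand overlap", {
  loci <- two_locus_catalog()  # both footprints on +
  minus_read <- sam_record("r1", "chr1", 150, "50M", flag = 16)
  res_un <- count_by_locus(read_alignments(minus_read), loci)
  res_st <- count_by_locus(read_alignments(minus_read), loci,
                           stranded = TRUE)
  expect_identical(res_un$counts[["locusA"]], 1L)
  expect_identical(res_st$counts[["locusA"]], 0L)
})

test_that("CPM normalisation is the stated linear identity", {
  cm <- list(counts = matrix(c(5L, 0L, 20L, 0L), nrow = 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))),
             library_size = c(s1 = 1000000L, s2 = 2000L))
  cpm <- cpm_normalize(cm)
  expect_identical(cpm["a", "s1"], 5)
  expect_identical(cpm["b", ], c(s1 = 0, s2 = 0))
  expect_identical(cpm["a", "s2"], 20 * 1e6 / 2000)
  # column sums recover 1e6 x assigned fraction
  expect_equal(colSums(cpm),
               1e6 * colSums(cm$counts) / cm$library_size)
})

test_that("count matrices round-trip through TSV and MTX triplets", {
  cm <- list(counts = matrix(c(5L, 0L, 20L, 3L), nrow = 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))),
             library_size = c(s1 = 100L, s2 = 200L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_identical(as.matrix(back[, -1]),
                   matrix(cm$counts, nrow = 2,
                          dimnames = list(NULL, c("s1", "s2"))))
  mtx <- withr::local_tempfile(fileext = ".mtx")
  export_counts_mtx(cm, mtx)
  lines <- readLines(mtx)
  expect_match(lines[1], "^%%MatrixMarket matrix coordinate integer")
  expect_identical(lines[2], "2 2 3")  # dims + nonzeros
  trip <- read.table(text = lines[-(1:2)])
  rebuilt <- matrix(0L, 2, 2)
  rebuilt[cbind(trip$V1, trip$V2)] <- trip$V3
  expect_identical(rebuilt, unname(cm$counts))
})
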