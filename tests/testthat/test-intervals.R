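test_that("read_bed parses BED3/BED6, skips comments, maps name and strand", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "chr1\t10\t20\tr1",
               "chr2\t5\t8\tr2\t0\t-", "chr1\t30\t40"), f)
  x <- read_bed(f)
  expect_s3_class(x, "interval_set")
  expect_equal(nrow(x), 3)
  expect_equal(x$start[x$name %in% "r1"], 10)
  expect_equal(x$end[x$name %in% "r1"], 20)
  expect_equal(x$strand[x$name %in% "r2"], "-")
  expect_true(is.na(x$name[x$chrom == "chr1" & x$start == 30]))
})

test_that("read_bed handles the empty file and rejects malformed lines", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0)
  writeLines("chr1\t20\t10", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t1\t2", "chr1\tx\t10"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t5", f)
  expect_error(read_bed(f), "3 columns")
})

test_that("write_bed then read_bed is the identity on normalized sets", {
  set.seed(11)
  x <- random_interval_set(40, chroms = c("chr1", "chr2"))
  f <- withr::local_tempfile()
  write_bed(x, f)
  expect_identical(read_bed(f), x)
  # and the emitted bytes are stable under a second round trip
  f2 <- withr::local_tempfile()
  write_bed(read_bed(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("interval_set normalizes (sorted, deduplicated) and validates", {
  x <- interval_set(c("chr2", "chr1", "chr1"), c(5, 10, 10), c(9, 20, 20),
                    name = c("b", "a", "a"))
  expect_equal(nrow(x), 2)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_error(interval_set("chr1", 20, 10), "end")
  expect_error(interval_set("chr1", -1, 10), "start")
  expect_error(interval_set("", 1, 10), "chrom")
})

test_that("intersect respects half-open coordinates and min_overlap_bp", {
  a <- interval_set("chr1", 10, 20, name = "a1")
  expect_equal(intersect_intervals(a, a)$overlap_bp, 10)
  b <- interval_set("chr1", 20, 30, name = "b1")
  expect_equal(nrow(intersect_intervals(a, b)), 0)  # abutment is not overlap
  c <- interval_set("chr1", 15, 30, name = "c1")
  expect_equal(intersect_intervals(a, c, min_overlap_bp = 5)$overlap_bp, 5)
  expect_equal(nrow(intersect_intervals(a, c, min_overlap_bp = 6)), 0)
  expect_error(intersect_intervals(a, c, min_overlap_bp = 0), "min_overlap_bp")
})

test_that("intersect matches the all-pairs brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    a <- random_interval_set(50, chrom_len = 10000,
                             chroms = c("chr1", "chr2"))
    b <- random_interval_set(50, chrom_len = 10000,
                             chroms = c("chr1", "chr2"))
    mo <- sample(c(1L, 5L, 50L), 1)
    got <- intersect_intervals(a, b, min_overlap_bp = mo)
    want <- oracle_intersect(a, b, min_overlap_bp = mo)
    expect_equal(got$a_idx, want$a_idx)
    expect_equal(got$b_idx, want$b_idx)
    expect_equal(got$overlap_bp, want$overlap_bp)
  }
})

test_that("nearest gene uses midpoint-to-TSS distance with the stated tie rule", {
  genes <- gene_annotation(c("A", "B"), c("chr1", "chr1"), c(150, 210),
                           c(650, 710), c("+", "+"))
  r <- interval_set("chr1", 100, 200, name = "r")
  expect_equal(nearest_gene(r, genes), list(gene_id = "A", distance = 0L))
  genes2 <- gene_annotation(c("A", "B"), c("chr1", "chr1"), c(100, 210),
                            c(600, 710), c("+", "+"))
  expect_equal(nearest_gene(r, genes2), list(gene_id = "A", distance = -50L))
  # exact tie at +/-50 -> lexicographically smaller id
  genes3 <- gene_annotation(c("B", "A"), c("chr1", "chr1"), c(100, 200),
                            c(600, 700), c("+", "+"))
  expect_equal(nearest_gene(r, genes3)$gene_id, "A")
  expect_equal(nearest_gene(r, genes3)$distance, 50L)
  # minus-strand TSS is end - 1
  gm <- gene_annotation("M", "chr1", 100, 152, "-")
  expect_equal(gm$tss, 151L)
  # chromosome with no gene -> NA, distinguishable from 0
  r2 <- interval_set("chrX", 0, 10)
  expect_true(is.na(nearest_gene(r2, genes)$gene_id))
  expect_true(is.na(nearest_gene(r2, genes)$distance))
})

test_that("nearest_genes matches the brute-force argmin on random instances", {
  set.seed(7)
  for (rep in 1:100) {
    ng <- sample(2:30, 1)
    genes <- gene_annotation(
      gene_id = sample(sprintf("G%03d", 1:200), ng),
      chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
      start = sample.int(5000, ng), end = 6000 + sample.int(500, ng),
      strand = sample(c("+", "-"), ng, replace = TRUE))
    regions <- random_interval_set(10, chrom_len = 8000,
                                   chroms = c("chr1", "chr2"))
    got <- nearest_genes(regions, genes)
    for (i in seq_len(nrow(regions))) {
      mid <- (regions$start[i] + regions$end[i]) %/% 2L
      want <- oracle_nearest(regions$chrom[i], mid, genes)
      expect_identical(got$gene_id[i], want$gene_id)
      expect_equal(got$distance[i], as.integer(want$distance))
    }
  }
})

test_that("merge_intervals collapses overlapping intervals", {
  x <- interval_set("chr1", c(10, 15, 40), c(20, 30, 50))
  m <- merge_intervals(x)
  expect_equal(m$start, c(10, 40))
  expect_equal(m$end, c(30, 50))
})
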