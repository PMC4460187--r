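# Post-calling QC: fragment joining and the five filters.

test_that("merge_adjacent joins fragments when the gap is under half the combined length", {
  one <- cnv_tbl(1e6, 1.1e6)
  expect_equal(merge_adjacent(one)$start, 1e6)
  expect_equal(merge_adjacent(one)$end, 1.1e6)

  # 100 kb + 40 kb fragments, 60 kb gap < 70 kb: joined
  near <- cnv_tbl(c(1e6, 1.16e6), c(1.1e6, 1.2e6), n_probes = c(20L, 10L))
  m <- merge_adjacent(near)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1e6)
  expect_equal(m$end, 1.2e6)
  expect_equal(m$n_probes, 30L)

  # same pair but 80 kb gap >= 70 kb: untouched
  far <- cnv_tbl(c(1e6, 1.18e6), c(1.1e6, 1.22e6))
  expect_equal(nrow(merge_adjacent(far)), 2)
})

test_that("merging respects (sample, chrom, copy_state) groups and rejects conflicting metadata", {
  two <- cnv_tbl(c(1e6, 1.16e6), c(1.1e6, 1.2e6),
    copy_state = c("del", "dup"))
  expect_equal(nrow(merge_adjacent(two)), 2)
  two_samp <- cnv_tbl(c(1e6, 1.16e6), c(1.1e6, 1.2e6),
    sample_id = c("S1", "S2"))
  expect_equal(nrow(merge_adjacent(two_samp)), 2)

  bad <- cnv_tbl(c(1e6, 2e6), c(1.1e6, 2.1e6), phenotype = c(0L, 1L))
  expect_error(merge_adjacent(bad), "conflicting")
})

test_that("cascading merges reach the all-orders fixpoint and merging is idempotent", {
  # merging the first two spans a region whose gap to the third then
  # qualifies: all three must collapse
  three <- cnv_tbl(c(0, 60e3, 185e3), c(50e3, 110e3, 235e3))
  m <- merge_adjacent(three)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 235e3))

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    start <- sort(sample.int(5e5, n))
    g <- cnv_tbl(start, start + sample.int(1e5, n))
    m <- merge_adjacent(g)
    # fixpoint: no remaining pair mergeable, second application is identity
    expect_identical(merge_adjacent(m), m)
    if (nrow(m) > 1) {
      gaps <- m$start[-1] - m$end[-nrow(m)]
      lens <- m$end - m$start
      expect_true(all(gaps >= 0.5 * (lens[-1] + lens[-nrow(m)])))
    }
    # equals the exhaustive pairwise oracle under several merge orders
    got <- as.data.frame(m[, c("start", "end", "n_probes")])
    for (os in 1:3) {
      want <- merge_oracle_group(as.data.frame(g), order_seed = os)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("low-copy-repeat filter removes calls covered more than the threshold by the LCR union", {
  lcr <- regions_tbl(120e3, 180e3) # 60 kb of a 100 kb call
  expect_equal(nrow(filter_lcr(cnv_tbl(100e3, 200e3), lcr)), 0)
  # exactly 50%: retained (strictly more-than rule)
  lcr50 <- regions_tbl(150e3, 210e3)
  expect_equal(nrow(filter_lcr(cnv_tbl(100e3, 200e3), lcr50)), 1)
  # two disjoint 30 kb overlaps unite to 60 kb: removed
  lcr2 <- regions_tbl(c(100e3, 160e3), c(130e3, 190e3))
  expect_equal(nrow(filter_lcr(cnv_tbl(100e3, 200e3), lcr2)), 0)
})

test_that("LCR coverage equals the per-base oracle and ignores region order", {
  set.seed(7)
  for (rep in 1:10) {
    cnvs <- cnv_tbl(sample_id = sprintf("S%d", 1:6),
      start = s <- sample.int(3000, 6), end = s + sample(200:1500, 6))
    reg <- regions_tbl(start = r <- sample.int(4000, 8),
      end = r + sample(50:800, 8))
    cov <- cnvenrich:::overlap_bp(cnvs, reg)
    want <- vapply(seq_len(6), function(i) {
      coverage_oracle(cnvs$start[i], cnvs$end[i], reg)
    }, numeric(1))
    expect_equal(cov, want)
    shuffled <- reg[sample.int(nrow(reg)), ]
    expect_identical(filter_lcr(cnvs, shuffled), filter_lcr(cnvs, reg))
  }
})

test_that("probe-density filter counts probes from the map, boundary inclusive", {
  probes <- tibble::tibble(chrom = "chr1", pos = seq(0, 1e6, by = 1000))
  # 200 kb window holding exactly 9 probes: removed; 10 probes: retained
  nine <- cnv_tbl(0, 200e3)
  map9 <- tibble::tibble(chrom = "chr1", pos = seq(10e3, 190e3, length.out = 9))
  expect_equal(nrow(filter_probe_density(nine, map9)), 0)
  map10 <- tibble::tibble(chrom = "chr1", pos = seq(10e3, 190e3, length.out = 10))
  expect_equal(nrow(filter_probe_density(nine, map10)), 1)

  expect_error(filter_probe_density(cnv_tbl(0, 2e5, chrom = "chrX"), probes),
    "chrX")
  expect_warning(filter_probe_density(cnv_tbl(0, 2e5), NULL), "n_probes")
})

test_that("binary-search probe counting equals a linear scan", {
  set.seed(11)
  probes <- tibble::tibble(chrom = "chr1",
    pos = sort(sample.int(1e6, 400)))
  cnvs <- cnv_tbl(sample_id = sprintf("S%d", 1:20),
    start = s <- sample.int(9e5, 20), end = s + sample(1e3:1e5, 20))
  got <- cnvenrich:::count_probes(cnvs, probes)
  want <- vapply(seq_len(20), function(i) {
    sum(probes$pos >= cnvs$start[i] & probes$pos < cnvs$end[i])
  }, integer(1))
  expect_equal(got, want)
})

test_that("size and probe-count thresholds are inclusive", {
  expect_equal(nrow(filter_size_probes(cnv_tbl(0, 1e5, n_probes = 15L))), 1)
  expect_equal(nrow(filter_size_probes(cnv_tbl(0, 99999, n_probes = 40L))), 0)
  expect_equal(nrow(filter_size_probes(cnv_tbl(0, 5e5, n_probes = 14L))), 0)
})

test_that("frequency filter removes reciprocal-overlap clusters above the carrier threshold", {
  solo <- cnv_tbl(1e6, 1.2e6)
  expect_equal(nrow(filter_frequency(solo, n_samples = 10000)), 1)

  # 12 mutually >=50%-overlapping deletions among 1,000 samples: 1.2% > 1%
  cluster <- cnv_tbl(
    start = seq(1e6, by = 2e3, length.out = 12),
    end = seq(1.2e6, by = 2e3, length.out = 12),
    sample_id = sprintf("S%02d", 1:12)
  )
  expect_equal(nrow(filter_frequency(cluster, n_samples = 1000)), 0)
  expect_equal(nrow(filter_frequency(cluster, n_samples = 2000)), 12)

  expect_error(filter_frequency(cluster, n_samples = 5), "n_samples")
})

test_that("single-linkage clustering equals the all-pairs transitive closure oracle", {
  set.seed(13)
  for (rep in 1:10) {
    cnvs <- random_cnvs(15)
    got <- cnvenrich:::overlap_clusters(cnvs, 0.5)
    want <- cluster_oracle(cnvs, 0.5)
    # same partition up to label names
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("known-locus removal uses any-overlap with half-open bounds", {
  loci <- regions_tbl(200e3, 300e3)
  expect_equal(nrow(remove_known_loci(cnv_tbl(100e3, 200001), loci)), 0)
  # abutting (call.end == locus.start): retained
  expect_equal(nrow(remove_known_loci(cnv_tbl(100e3, 200e3), loci)), 1)

  set.seed(17)
  cnvs <- random_cnvs(30)
  loci2 <- regions_tbl(start = r <- sample.int(9e5, 5),
    end = r + sample(1e4:1e5, 5), chrom = sample(c("chr1", "chr2"), 5, TRUE))
  keep_want <- vapply(seq_len(30), function(i) {
    !any(loci2$chrom == cnvs$chrom[i] & loci2$start < cnvs$end[i] &
      loci2$end > cnvs$start[i])
  }, logical(1))
  expect_equal(nrow(remove_known_loci(cnvs, loci2)), sum(keep_want))
})

test_that("filters are idempotent order-stable subsets and a clean fixture passes the whole chain", {
  set.seed(19)
  cnvs <- random_cnvs(40, max_pos = 5e6)
  lcr <- regions_tbl(start = r <- sample.int(5e6, 6), end = r + 2e4,
    chrom = sample(c("chr1", "chr2"), 6, TRUE))
  for (f in list(
    function(x) filter_lcr(x, lcr),
    function(x) filter_size_probes(x, min_len = 5e3, min_probes = 20),
    function(x) filter_frequency(x, n_samples = 50),
    function(x) remove_known_loci(x, lcr)
  )) {
    out <- f(cnvs)
    expect_lte(nrow(out), nrow(cnvs))
    # subsequence of the input rows
    expect_true(all(paste(out$sample_id, out$start) %in%
      paste(cnvs$sample_id, cnvs$start)))
    expect_identical(f(out), out)
  }

  # constructed to pass every rule: far apart, big, dense, rare, off-LCR
  clean <- cnv_tbl(
    start = seq(1e6, by = 3e6, length.out = 5),
    end = seq(1e6, by = 3e6, length.out = 5) + 150e3,
    sample_id = sprintf("S%d", 1:5), n_probes = 50L,
    phenotype = c(1L, 0L, 1L, 0L, 1L)
  )
  probes <- tibble::tibble(chrom = "chr1", pos = seq(0, 2e7, by = 2000))
  out <- cnv_qc(clean, lcr = regions_tbl(0, 1000), probes = probes,
    n_samples = 1000)
  expect_equal(as.data.frame(out), as.data.frame(clean))
})
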