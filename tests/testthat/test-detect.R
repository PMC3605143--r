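# planted odd pairs + background normals with controlled local coverage
planted_acc <- function(n_odd, n_norm, odd_mapq = 60L, base = 2e5) {
  odd <- pair_records(
    name = sprintf("odd%02d", seq_len(n_odd)),
    chromA = "chr1", posA = as.integer(base + seq_len(n_odd) * 7), strandA = "+",
    chromB = "chr2", posB = as.integer(3e5 + seq_len(n_odd) * 7), strandB = "-",
    mapqA = odd_mapq, mapqB = odd_mapq, seqnames = SEQ3)
  pairs <- odd
  if (n_norm > 0) {
    norm <- pair_records(
      name = sprintf("nrm%03d", seq_len(n_norm)),
      chromA = "chr1", posA = as.integer(base + (seq_len(n_norm) %% 900)),
      strandA = "+",
      chromB = "chr1", posB = as.integer(base + (seq_len(n_norm) %% 900) + 300),
      strandB = "-", mapqA = 60L, mapqB = 60L, seqnames = SEQ3)
    pairs <- rbind(odd, norm)
  }
  pass1(pairs, seqnames = SEQ3)
}

test_that("pass1 leaves the 2D structure empty on all-normal input", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
                    mismap_noise_rate = 0)
  p <- simulate_background(cfg, "s")
  acc <- pass1(p, seqnames = names(cfg$chrom_lengths))
  expect_identical(nrow(acc$odd2d), 0L)
})

test_that("pass1 collects co-binned interchromosomal pairs into one cell", {
  acc <- planted_acc(10, 0)
  cells <- odd_cells(acc)
  expect_identical(nrow(cells), 1L)
  expect_identical(cells$n_odd, 10L)
  expect_identical(cells$class, "INTERCHROM")
})

test_that("adjacent cells merge by single linkage; distant cells do not", {
  # two cells (chr1,5)x(chr2,7) and (chr1,6)x(chr2,7), same class
  p <- pair_records(
    c("a1", "a2"), "chr1", c(5500L, 6500L), "+",
    "chr2", c(7500L, 7600L), "-", 60L, 60L, SEQ3)
  cand <- cluster_cells(pass1(p, seqnames = SEQ3))
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$binA_min, cand$binA_max), c(5L, 6L))
  expect_identical(c(cand$binB_min, cand$binB_max), c(7L, 7L))
  expect_identical(cand$n_support, 2L)

  # three bins apart on the A axis: two candidates
  q <- pair_records(
    c("b1", "b2"), "chr1", c(5500L, 8500L), "+",
    "chr2", c(7500L, 7600L), "-", 60L, 60L, SEQ3)
  expect_identical(nrow(cluster_cells(pass1(q, seqnames = SEQ3))), 2L)
})

test_that("binned clustering matches brute-force single linkage", {
  for (seed in 1:25) {
    pairs <- clustered_instance(seed)
    cls <- classify_pairs(pairs)
    acc <- pass1(pairs, seqnames = SEQ3)
    cand <- cluster_cells(acc)
    got <- lapply(cand$names, sort)
    want <- brute_single_linkage(pairs, cls, 1000L)
    for (w in want) {
      if (w$spanA < 1000L && w$spanB < 1000L)
        expect_true(any(vapply(got, identical, TRUE, w$names)),
                    label = paste("cluster recovered, seed", seed))
    }
  }
})

test_that("the mapping-quality score matches its closed forms", {
  expect_identical(score_feature(0L), 0)
  expect_identical(score_feature(c(10L, 10L)), 0.99)
  expect_equal(score_feature(c(30L, 30L, 30L)), 1 - 1e-9, tolerance = 1e-15)
  expect_error(score_feature(integer()), "empty")
  # mapq 255 means unavailable and is scored at the configured default
  expect_identical(score_feature(255L), score_feature(20L))
  expect_identical(score_feature(255L, default_mapq_for_unavailable = 5L),
                   score_feature(5L))
  # monotone in count and in quality (strictly so until the score saturates
  # at 1 in double precision)
  set.seed(31)
  for (i in 1:200) {
    q <- sample(0:60, sample(1:8, 1), replace = TRUE)
    s0 <- score_feature(q)
    s1 <- score_feature(c(q, sample(1:60, 1)))
    j <- sample(seq_along(q), 1)
    q2 <- q; q2[j] <- q[j] + 5L
    s2 <- score_feature(q2)
    expect_gte(s1, s0)
    expect_gte(s2, s0)
    if (s0 < 1 - 1e-12) expect_gt(s1, s0)
  }
})

test_that("support-count and coverage-fraction filters gate calls", {
  # 2 supports at default min_support 3: rejected; permissive 2: called
  acc2 <- planted_acc(2, 20)
  expect_identical(nrow(call_svs(acc2)), 0L)
  expect_identical(nrow(call_svs(acc2, call_config(min_support = 2))), 1L)

  # 10 supports over local coverage 40 -> fraction 0.25, called
  acc10 <- planted_acc(10, 30)
  calls <- call_svs(acc10)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_support, 10L)
  expect_identical(calls$local_coverage, 40L)
  expect_equal(calls$support_fraction, 0.25)
  expect_true(all(calls$score > 0 & calls$score <= 1))
  # regions are bin-aligned multiples of bin_size
  expect_true(all(c(calls$startA, calls$endA, calls$startB, calls$endB)
                  %% 1000 == 0))

  # 10 supports over local coverage 500 -> fraction 0.02 < 0.05, rejected
  acc500 <- planted_acc(10, 490)
  expect_identical(nrow(call_svs(acc500)), 0L)
})

test_that("cluster-size distribution reflects planted events and conserves", {
  streams <- lapply(1:5, function(i) pair_records(
    name = sprintf("e%d_%02d", i, 1:8),
    chromA = "chr1", posA = as.integer(i * 1e5 + (1:8) * 11), strandA = "+",
    chromB = "chr2", posB = as.integer(i * 1e5 + (1:8) * 13), strandB = "-",
    mapqA = 60L, mapqB = 60L, seqnames = SEQ3))
  pairs <- data.table::rbindlist(streams)
  acc <- pass1(pairs, seqnames = SEQ3)
  tab <- cluster_size_distribution(acc)
  expect_identical(tab$size, 8L)
  expect_identical(tab$n_clusters, 5L)
  expect_identical(sum(tab$size * tab$n_clusters), nrow(acc$odd2d))

  # background mismapping noise yields almost exclusively size-1 clusters
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                    mismap_noise_rate = 0.002)
  p <- simulate_background(cfg, "s")
  tab2 <- cluster_size_distribution(pass1(p, seqnames = names(cfg$chrom_lengths)))
  expect_gte(sum(tab2$n_clusters[tab2$size == 1]) / sum(tab2$n_clusters), 0.95)
})

test_that("partitioned pass1 yields byte-identical BEDPE to one pass", {
  cfg <- tumor_config(seed = 77)
  sc <- scenario_matched_pair(cfg)
  pairs <- sc$tumor
  cls <- classify_pairs(pairs)
  sq <- names(cfg$chrom_lengths)
  whole <- accumulate(bin_accumulator(sq), pairs, cls)
  set.seed(78)
  part <- sample(1:6, nrow(pairs), replace = TRUE)
  merged <- Reduce(merge, lapply(1:6, function(k)
    accumulate(bin_accumulator(sq), pairs[part == k, ], cls[part == k])))
  expect_identical(merged, whole)
  f1 <- tempfile(); f2 <- tempfile()
  write_bedpe(call_svs(whole, sample_id = "t"), f1)
  write_bedpe(call_svs(merged, sample_id = "t"), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1L)
})

test_that("the local-topology tree follows calls depth-first, breaking cycles", {
  calls <- data.table::data.table(
    chromA = c("chr1", "chr2"), startA = c(1000L, 5000L),
    endA = c(2000L, 6000L),
    chromB = c("chr2", "chr1"), startB = c(5000L, 1000L),
    endB = c(6000L, 2000L),
    sv_class = "INTERCHROM", n_support = c(8L, 4L),
    local_coverage = 40L, support_fraction = 0.2, score = 0.999,
    sample_id = "s")

  lone <- local_topology_tree(calls, list(chrom = "chr3", start = 0L,
                                          end = 1000L), 3L, SEQ3)
  expect_identical(length(lone$children), 0L)
  expect_error(local_topology_tree(calls, list(chrom = "chrX", start = 0L,
                                               end = 1000L), 3L, SEQ3),
               "unknown chromosome")

  one <- local_topology_tree(calls[1, ], list(chrom = "chr1", start = 900L,
                                              end = 2100L), 3L, SEQ3)
  expect_identical(length(one$children), 1L)
  expect_identical(one$children[[1]]$chrom, "chr2")
  expect_identical(one$children[[1]]$n_support, 8L)

  # both calls link chr1:1000-2000 <-> chr2:5000-6000: a cycle; every
  # (call, direction) edge is used at most once so the traversal terminates
  cyc <- local_topology_tree(calls, list(chrom = "chr1", start = 1000L,
                                         end = 2000L), 10L, SEQ3)
  count_nodes <- function(node)
    1L + sum(vapply(node$children, count_nodes, 0L))
  expect_lte(count_nodes(cyc), 5L)  # root + at most 4 directed edges
})
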