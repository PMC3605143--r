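# exhaustive joint-histogram mutual information, kept independent of the
# implementation path
mi_oracle <- function(x, y) {
  xi <- as.integer(x > 0); yi <- as.integer(y > 0)
  n <- length(xi)
  h <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  hx <- h(table(xi)); hy <- h(table(yi))
  hxy <- h(table(paste(xi, yi)))
  if (hxy == 0) return(0)
  1 - (hx + hy - hxy) / hxy
}

test_that("disruption counts match a brute-force interval scan", {
  genes <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 8000L, 2000L), end = c(4000L, 12000L, 6000L),
    name = c("gA", "gB", "gC"))
  one <- data.table::data.table(
    chromA = "chr1", startA = 2000L, endA = 3000L,
    chromB = "chr1", startB = 2000L, endB = 3000L,
    sv_class = "ORIENTATION", n_support = 5L, local_coverage = 20L,
    support_fraction = 0.25, score = 0.9, sample_id = "s1")
  m <- disruption_counts(list(s1 = one), genes)
  expect_identical(m["gA", "s1"], 1L)  # both ends in one gene count once
  expect_identical(sum(m), 1L)

  tr <- data.table::copy(one)
  tr$chromB <- "chr2"; tr$startB <- 3000L; tr$endB <- 4000L
  tr$sv_class <- "INTERCHROM"
  m2 <- disruption_counts(list(s1 = tr), genes)
  expect_identical(m2["gA", "s1"], 1L)
  expect_identical(m2["gC", "s1"], 1L)

  expect_error(disruption_counts(list(s1 = one), genes[0, ]), "empty")

  # random calls vs brute-force overlap scan
  set.seed(51)
  rgenes <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), 30, TRUE),
    start = as.integer(sample(0:80, 30) * 1000))
  rgenes$end <- rgenes$start + as.integer(sample(1:5, 30, TRUE) * 1000)
  rgenes$name <- sprintf("g%02d", 1:30)
  for (s in 1:5) {
    calls <- data.table::data.table(
      chromA = sample(c("chr1", "chr2"), 20, TRUE),
      startA = as.integer(sample(0:84, 20, TRUE) * 1000))
    calls$endA <- calls$startA + 1000L
    calls$chromB <- sample(c("chr1", "chr2"), 20, TRUE)
    calls$startB <- as.integer(sample(0:84, 20, TRUE) * 1000)
    calls$endB <- calls$startB + 1000L
    got <- disruption_counts(list(x = calls), rgenes)[, 1]
    want <- vapply(seq_len(nrow(rgenes)), function(g) {
      hit <- (calls$chromA == rgenes$chrom[g] &
                calls$startA < rgenes$end[g] & rgenes$start[g] < calls$endA) |
        (calls$chromB == rgenes$chrom[g] &
           calls$startB < rgenes$end[g] & rgenes$start[g] < calls$endB)
      sum(hit)
    }, 0)
    expect_identical(unname(got), as.integer(want))
  }
})

test_that("mutual-information distance has its closed-form values", {
  expect_identical(mi_distance(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  expect_identical(mi_distance(c(0, 0, 1, 1), c(0, 1, 0, 1)), 1)
  expect_identical(mi_distance(c(0, 0, 0), c(0, 0, 0)), 0)  # H(X,Y) = 0
  expect_error(mi_distance(1:4, 1:5), "equal length")
})

test_that("mutual-information distance matches the exhaustive oracle", {
  set.seed(52)
  for (i in 1:200) {
    x <- rbinom(16, 1, 0.5); y <- rbinom(16, 1, 0.5)
    expect_equal(mi_distance(x, y), mi_oracle(x, y), tolerance = 1e-12)
    expect_equal(mi_distance(x, y), mi_distance(y, x), tolerance = 0)
  }
})

test_that("the normalized MI distance is a metric on binary profiles", {
  set.seed(53)
  for (i in 1:300) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5); z <- rbinom(12, 1, 0.5)
    dxy <- mi_distance(x, y); dyz <- mi_distance(y, z); dxz <- mi_distance(x, z)
    expect_lte(dxz, dxy + dyz + 1e-9)
    expect_identical(mi_distance(x, x), 0)
  }
})

test_that("count profiles can be compared with quantile binning", {
  set.seed(54)
  x <- rpois(40, 3); y <- x + rpois(40, 1)
  d_bin <- mi_distance(x, y, bins = "binary")
  d_q <- mi_distance(x, y, bins = "quantile")
  expect_true(d_q >= 0 && d_q <= 1)
  expect_false(identical(d_bin, d_q))
})

test_that("classical MDS first coordinate has its closed forms", {
  two <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(sort(mds_first_coordinate(two)), c(-2, 2), tolerance = 1e-12)

  coll <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  expect_equal(sort(mds_first_coordinate(coll)), c(-1, 0, 1),
               tolerance = 1e-10)

  expect_error(mds_first_coordinate(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  expect_error(mds_first_coordinate(matrix(1, 2, 2)), "zero diagonal")
  expect_error(mds_first_coordinate(matrix(0, 3, 3)), "degenerate")
})

test_that("MDS recovers a 1-D embedding and agrees with cmdscale", {
  set.seed(55)
  pos <- sort(runif(20, -5, 5))
  D <- abs(outer(pos, pos, "-"))
  got <- mds_first_coordinate(D)
  centered <- pos - mean(pos)
  err <- min(max(abs(got - centered)), max(abs(-got - centered)))
  expect_lt(err, 1e-8)
  # independent route: classical scaling in stats
  ref <- stats::cmdscale(D, k = 1)[, 1]
  expect_lt(min(max(abs(got - ref)), max(abs(got + ref))), 1e-8)
})

test_that("the compactness index hits its extremes and the 6-point oracle", {
  # 4 tight points + 2 far points: the cluster owns the m smallest distances
  pos <- c(0, 0.1, 0.2, 0.3, 100, 200)
  D <- abs(outer(pos, pos, "-"))
  expect_equal(c_index(D, 1:4), 1)
  # the two most distant points own the m largest distances
  expect_equal(c_index(D, c(1, 6)), 0)

  # exhaustive enumeration over all clusters of sizes 2..4 on 6 points
  set.seed(56)
  P <- matrix(runif(12), 6, 2)
  D2 <- as.matrix(stats::dist(P))
  all_d <- sort(D2[lower.tri(D2)])
  for (k in 2:4) {
    for (members in utils::combn(6, k, simplify = FALSE)) {
      w <- D2[members, members]
      s <- sum(w[lower.tri(w)])
      m <- k * (k - 1) / 2
      want <- 1 - (s - sum(head(all_d, m))) /
        (sum(tail(all_d, m)) - sum(head(all_d, m)))
      expect_equal(c_index(D2, members), want, tolerance = 1e-12)
    }
  }

  # invariance under scaling and under relabeling of non-members
  expect_equal(c_index(D2 * 7, 1:3), c_index(D2, 1:3), tolerance = 1e-12)
  perm <- c(1, 2, 3, 6, 4, 5)
  expect_equal(c_index(D2[perm, perm], 1:3), c_index(D2, 1:3),
               tolerance = 1e-12)

  expect_error(c_index(D2, 1), "cluster size")
  expect_warning(v <- c_index(matrix(1, 4, 4) - diag(4), 1:2), "degenerate")
  expect_identical(v, 1)
})

test_that("coverage/feature correlation flags undefined cases", {
  cov <- c(10, 20, 30, 40)
  r <- coverage_feature_correlation(cov, cov * 2)
  expect_true(r$defined)
  expect_equal(r$correlation, 1)
  set.seed(57)
  ind <- coverage_feature_correlation(rnorm(400), rnorm(400))
  expect_lt(abs(ind$correlation), 2 / sqrt(400))
  flat <- coverage_feature_correlation(cov, rep(3, 4))
  expect_false(flat$defined)
  expect_true(is.na(flat$correlation))
})

test_that("greedy biclustering keeps constant structure, drops wild rows", {
  M <- matrix(5, 8, 6)
  b <- bicluster_consistent(M, 0.01)
  expect_identical(b$rows, 1:8)
  expect_identical(b$cols, 1:6)
  expect_identical(b$msr, 0)

  set.seed(58)
  M2 <- matrix(5, 8, 6)
  M2[3, ] <- rnorm(6, 5, 10)  # one wildly variable row goes first
  b2 <- bicluster_consistent(M2, 0.01)
  expect_identical(b2$rows, setdiff(1:8, 3))
  expect_identical(b2$cols, 1:6)

  expect_warning(
    bicluster_consistent(matrix(rnorm(4), 2, 2), 1e-12), "unreachable")
})

test_that("biclustering recovers a planted consistent block in noisy coverage", {
  for (seed in 1:20) {
    set.seed(seed)
    M <- matrix(rnorm(900, 30, 10), 30, 30)     # erratic coverage
    M[1:10, 1:10] <- rnorm(100, 30, 0.5)        # consistent block
    b <- bicluster_consistent(M, 1)
    kept <- length(intersect(b$rows, 1:10)) * length(intersect(b$cols, 1:10))
    expect_gte(kept, 80L)  # block recovered up to a few cells, every replicate
  }
})

test_that("group density tables cover each label", {
  set.seed(59)
  v <- c(rnorm(30, -2), rnorm(30, 2))
  lab <- rep(c("blood", "tumor"), each = 30)
  tab <- group_density_table(v, lab)
  expect_setequal(unique(tab$label), c("blood", "tumor"))
  bl <- tab[tab$label == "blood", ]
  expect_lt(abs(bl$x[which.max(bl$density)] + 2), 1)
})
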