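# Fixture generators and independent oracles shared across tests.

SEQ3 <- c("chr1", "chr2", "chr3")

# random mixed pair stream (all classes), deterministic given seed
random_stream <- function(n, seed, seqnames = SEQ3, len = 1e6) {
  set.seed(seed)
  chromA <- sample(seqnames, n, replace = TRUE)
  chromB <- ifelse(runif(n) < 0.1, sample(seqnames, n, replace = TRUE),
                   chromA)
  posA <- as.integer(floor(runif(n) * (len - 2e4)))
  d <- as.integer(sample(c(300, 1500, 3500, 9000), n, replace = TRUE))
  posB <- ifelse(chromA == chromB, posA + d,
                 as.integer(floor(runif(n) * len)))
  strandA <- ifelse(runif(n) < 0.1, "-", "+")
  pair_records(
    name = sprintf("p%06d", seq_len(n)),
    chromA = chromA, posA = posA, strandA = strandA,
    chromB = chromB, posB = as.integer(posB),
    strandB = ifelse(runif(n) < 0.1, "+", "-"),
    mapqA = sample(0:60, n, replace = TRUE),
    mapqB = sample(0:60, n, replace = TRUE),
    seqnames = seqnames)
}

# strip the bookkeeping attributes read_pairs() adds, for value comparisons
plain <- function(dt) {
  df <- as.data.frame(dt)
  attr(df, "seqnames") <- NULL
  attr(df, "seqlengths") <- NULL
  attr(df, "skipped") <- NULL
  df
}

# brute-force single-linkage clustering of odd pairs: points (posA, posB) on
# one (class, chromA, chromB) stratum, Chebyshev metric, linkage distance h
brute_single_linkage <- function(pairs, classes, h) {
  odd <- which(classes != "NORMAL")
  if (!length(odd)) return(list())
  key <- paste(classes[odd], pairs$chromA[odd], pairs$chromB[odd])
  out <- list()
  for (g in unique(key)) {
    idx <- odd[key == g]
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dcheb <- max(abs(pairs$posA[idx[i]] - pairs$posA[idx[j]]),
                   abs(pairs$posB[idx[i]] - pairs$posB[idx[j]]))
      if (dcheb <= h) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    root <- vapply(seq_len(k), find, 0L)
    for (cl in unique(root))
      out[[length(out) + 1L]] <- list(
        names = sort(pairs$name[idx[root == cl]]),
        spanA = diff(range(pairs$posA[idx[root == cl]])),
        spanB = diff(range(pairs$posB[idx[root == cl]])))
  }
  out
}

# random clustered odd-pair instance: cluster centers separated by >= 3 bins
# on each axis, members jittered so each intended cluster spans < bin_size
clustered_instance <- function(seed, bin_size = 1000L) {
  set.seed(seed)
  k <- sample(1:6, 1)
  centersA <- (seq_len(k) * 5L + sample(0:2, k, replace = TRUE)) * bin_size
  centersB <- centersA + sample(c(20L, 40L, 60L), k, replace = TRUE) *
    bin_size
  rows <- list()
  for (i in seq_len(k)) {
    m <- sample(1:12, 1)
    jA <- sample(0:(bin_size %/% 2 - 1L), m, replace = TRUE)
    jB <- sample(0:(bin_size %/% 2 - 1L), m, replace = TRUE)
    rows[[i]] <- data.frame(posA = centersA[i] + jA, posB = centersB[i] + jB)
  }
  df <- do.call(rbind, rows)
  pair_records(
    name = sprintf("q%04d", seq_len(nrow(df))),
    chromA = "chr1", posA = df$posA, strandA = "+",
    chromB = "chr1", posB = df$posB, strandB = "-",
    mapqA = 60L, mapqB = 60L, seqnames = SEQ3)
}

# brute-force usable-region scan: per-bin boolean over a coverage matrix
brute_usable <- function(covmat, bin_size, min_cov, min_frac) {
  ok <- rowMeans(covmat >= min_cov) >= min_frac
  out <- NULL
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      out <- rbind(out, c((i - 1L) * bin_size, j * bin_size))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# calibrated insert-distance mixture: 99.9% N(400, 50^2), 0.1% long-range
mixture_pairs <- function(n, seed, long_rate = 0.001, n_groups = 2L) {
  set.seed(seed)
  long <- runif(n) < long_rate
  d <- integer(n)
  d[!long] <- pmax(1L, as.integer(round(rnorm(sum(!long), 400, 50))))
  d[long] <- as.integer(floor(runif(sum(long), 1001, 1e6)))
  posA <- as.integer(floor(runif(n) * 1e6))
  pair_records(
    name = sprintf("m%07d", seq_len(n)),
    chromA = "chr1", posA = posA, strandA = "+",
    chromB = "chr1", posB = posA + d, strandB = "-",
    mapqA = 60L, mapqB = 60L, seqnames = SEQ3,
    read_group = rep(sprintf("rg%02d", seq_len(n_groups)),
                     length.out = n))
}

# shift the insert distances of one read group (a batch anomaly)
shift_group <- function(pairs, group, by = 5000L) {
  out <- data.table::copy(pairs)
  sel <- out$read_group == group
  out$posB[sel] <- out$posB[sel] + as.integer(by)
  out
}

# default three-event tumor configuration on a 10-Mb two-chromosome genome
tumor_config <- function(seed, n_support = c(6L, 8L, 10L)) {
  sim_config(
    seed = seed, chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    planted = list(
      planted_sv("deletion", "chr1", 1e6, size = 3000L,
                 n_support = n_support[1]),
      planted_sv("inversion", "chr1", 3e6, n_support = n_support[2]),
      planted_sv("translocation", "chr1", 2e6, partner_chrom = "chr2",
                 partner_pos = 2.5e6, n_support = n_support[3])))
}
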