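# Cross-sample statistics: gene disruption matrices, mutual-information
# distance, classical MDS, cluster compactness index, coverage-bias
# diagnostics, and coverage-consistency biclustering.

#' Read a BED gene annotation
#'
#' @param path BED file (chrom, start, end, name; 0-based half-open).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(bed) < 4L) stop("BED annotation needs at least 4 columns")
  data.table::setnames(bed, 1:4, c("chrom", "start", "end", "name"))
  bed[, 1:4]
}

#' Gene disruption counts across samples
#'
#' Cell (g, s) counts the calls in sample s with regionA or regionB
#' overlapping gene g. A call whose two ends hit different genes increments
#' both; a call hitting the same gene with both ends counts once for it.
#' Overlap is computed on 0-based half-open intervals.
#'
#' @param calls_by_sample Named list of call tables ([call_svs()] output).
#' @param genes Gene annotation (`chrom`, `start`, `end`, `name`), half-open.
#' @return Integer matrix genes x samples, with an attribute `genes` carrying
#'   the annotation in row order.
#' @export
disruption_counts <- function(calls_by_sample, genes) {
  if (is.null(genes) || !nrow(genes)) stop("empty gene annotation")
  if (is.null(names(calls_by_sample)) || any(!nzchar(names(calls_by_sample))))
    stop("calls_by_sample must be a named list")
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  m <- matrix(0L, nrow = nrow(genes), ncol = length(calls_by_sample),
              dimnames = list(genes$name, names(calls_by_sample)))
  for (s in seq_along(calls_by_sample)) {
    calls <- calls_by_sample[[s]]
    if (is.null(calls) || !nrow(calls)) next
    grA <- GenomicRanges::GRanges(
      calls$chromA, IRanges::IRanges(calls$startA + 1L, calls$endA))
    grB <- GenomicRanges::GRanges(
      calls$chromB, IRanges::IRanges(calls$startB + 1L, calls$endB))
    hitA <- GenomicRanges::findOverlaps(grA, gr)
    hitB <- GenomicRanges::findOverlaps(grB, gr)
    hits <- unique(rbind(
      cbind(S4Vectors::queryHits(hitA), S4Vectors::subjectHits(hitA)),
      cbind(S4Vectors::queryHits(hitB), S4Vectors::subjectHits(hitB))))
    if (nrow(hits)) {
      tab <- table(hits[, 2])
      m[as.integer(names(tab)), s] <- as.integer(tab)
    }
  }
  attr(m, "genes") <- genes
  m
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

discretize_profile <- function(x, bins) {
  if (bins == "binary") return(as.integer(x > 0))
  # count-quantile binning into 4 bins
  qs <- unique(stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7))
  findInterval(x, qs, left.open = TRUE)
}

#' Mutual-information distance between two profiles
#'
#' `D = 1 - I(X; Y) / H(X, Y)` with plug-in entropies from the joint
#' histogram (natural log internally; the ratio is base-free). On discrete
#' profiles this normalized form is a metric: `D(x, x) = 0` for non-constant
#' `x`, it is symmetric, `D = 1` when the profiles are independent, and it
#' satisfies the triangle inequality. When both profiles are constant the
#' joint entropy is 0 and `D` is defined as 0. Profiles are binarized
#' (`count > 0`) by default; `bins = "quantile"` uses 4 count-quantile bins.
#'
#' @param x,y Equal-length numeric profiles (e.g. gene disruption columns).
#' @param bins `"binary"` or `"quantile"`.
#' @return Distance in `[0, 1]`.
#' @export
mi_distance <- function(x, y, bins = c("binary", "quantile")) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (!length(x)) stop("profiles must be non-empty")
  bins <- match.arg(bins)
  xi <- discretize_profile(x, bins)
  yi <- discretize_profile(y, bins)
  joint <- table(xi, yi) / length(xi)
  hxy <- entropy_nat(as.numeric(joint))
  if (hxy == 0) return(0)
  hx <- entropy_nat(rowSums(joint))
  hy <- entropy_nat(colSums(joint))
  i <- hx + hy - hxy
  d <- 1 - i / hxy
  min(max(d, 0), 1)
}

#' Pairwise mutual-information distance matrix
#'
#' @param m Profiles as a matrix (rows = features, columns = samples).
#' @param bins See [mi_distance()].
#' @return Symmetric distance matrix samples x samples with zero diagonal.
#' @export
mi_distance_matrix <- function(m, bins = "binary") {
  n <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mi_distance(m[, i], m[, j], bins = bins)
    }
  }
  D
}

#' First coordinate of a classical (Torgerson) MDS solution
#'
#' Double-centers `-D^2 / 2`, takes the top eigenpair, and returns
#' `eigenvector * sqrt(eigenvalue)`. The sign is fixed so that the
#' largest-magnitude coordinate is positive. Sample densities along this
#' coordinate, grouped by tissue or disease, are the standard view of how the
#' distance structure separates sample groups.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @return Numeric coordinate per sample (named like `D`'s columns).
#' @export
mds_first_coordinate <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- eig$values[1]
  if (lambda <= 1e-12)
    stop("degenerate geometry: top eigenvalue is not positive")
  coord <- eig$vectors[, 1] * sqrt(lambda)
  if (coord[which.max(abs(coord))] < 0) coord <- -coord
  stats::setNames(coord, colnames(D))
}

#' Per-group kernel density table of a coordinate
#'
#' @param values Numeric vector (e.g. MDS first coordinate).
#' @param labels Group label per value.
#' @param n Grid points per group.
#' @return `data.table` (`label`, `x`, `density`), one density per group.
#' @export
group_density_table <- function(values, labels, n = 256L) {
  out <- lapply(sort(unique(labels)), function(g) {
    v <- values[labels == g]
    if (length(v) < 2L)
      return(data.table::data.table(label = g, x = v, density = NA_real_))
    den <- stats::density(v, bw = "nrd0", n = n)
    data.table::data.table(label = g, x = den$x, density = den$y)
  })
  data.table::rbindlist(out)
}

#' Cluster compactness index
#'
#' Let S be the sum of within-cluster pairwise distances over the m pairs in
#' the cluster, and S_min / S_max the sums of the m smallest / largest
#' distances anywhere in D. The returned index is `1 - (S - S_min) / (S_max -
#' S_min)` — the complement of the Hubert-Levin C statistic, oriented so that
#' 1 means a maximally compact cluster and 0 a maximally dispersed one. It is
#' invariant under relabeling of non-cluster samples and under uniform
#' scaling of D.
#'
#' @param D Symmetric distance matrix.
#' @param cluster Indices, names or logical mask of the cluster members
#'   (at least 2, fewer than all samples).
#' @return Index in `[0, 1]`.
#' @export
c_index <- function(D, cluster) {
  D <- as.matrix(D)
  n <- nrow(D)
  idx <- if (is.logical(cluster)) which(cluster)
         else if (is.character(cluster)) match(cluster, rownames(D))
         else as.integer(cluster)
  if (any(is.na(idx))) stop("cluster members not found in D")
  k <- length(idx)
  if (k < 2 || k >= n) stop("cluster size must be in [2, n - 1]")
  within <- D[idx, idx][lower.tri(matrix(0, k, k))]
  m <- length(within)
  all_d <- sort(D[lower.tri(D)])
  s <- sum(within)
  s_min <- sum(all_d[seq_len(m)])
  s_max <- sum(all_d[seq(length(all_d) - m + 1L, length(all_d))])
  if (s_max == s_min) {
    warning("all pairwise distances equal; index degenerate, returning 1")
    return(1)
  }
  1 - (s - s_min) / (s_max - s_min)
}

#' Coverage/feature correlation diagnostic
#'
#' Pearson correlation between per-gene coverage and per-gene disruption
#' counts. A large value indicates that detected features track coverage
#' depth — a batch effect, and a generally undesired property of a caller.
#'
#' @param coverage_per_gene,disruptions_per_gene Equal-length vectors
#'   (length >= 3).
#' @return List with `correlation` (NA when undefined) and `defined`.
#' @export
coverage_feature_correlation <- function(coverage_per_gene,
                                         disruptions_per_gene) {
  if (length(coverage_per_gene) != length(disruptions_per_gene) ||
      length(coverage_per_gene) < 3L)
    stop("need two equal-length vectors of length >= 3")
  if (stats::sd(coverage_per_gene) == 0 ||
      stats::sd(disruptions_per_gene) == 0)
    return(list(correlation = NA_real_, defined = FALSE))
  list(correlation = stats::cor(coverage_per_gene, disruptions_per_gene),
       defined = TRUE)
}

mean_squared_residue <- function(M) {
  if (!length(M)) return(0)
  r <- M - outer(rowMeans(M), colMeans(M), "+") + mean(M)
  mean(r^2)
}

#' Greedy coverage-consistency biclustering
#'
#' Finds a subgroup of genes (rows) and samples (columns) with relatively
#' consistent coverage by greedy node deletion followed by node addition. In
#' the deletion phase the row or column with the largest mean squared residue
#' (against the additive row + column + grand mean fit) is removed until the
#' matrix's mean squared residue falls below `max_variance` or the matrix
#' would shrink below 2 x 2; ties prefer rows, then the earlier index. The
#' addition phase then re-admits, in index order, any deleted row or column
#' whose residue against the current bicluster is no worse than the achieved
#' residue, which repairs rows dropped on the greedy path. Restricting a
#' cross-sample analysis to this bicluster removes the genes and samples
#' whose coverage is inconsistent with the rest.
#'
#' @param coverage Numeric matrix genes x samples.
#' @param max_variance Target mean squared residue.
#' @return List with `rows`, `cols` (kept indices into the input, sorted),
#'   and `msr` (final mean squared residue). Warns when the threshold is
#'   unreachable.
#' @export
bicluster_consistent <- function(coverage, max_variance) {
  M0 <- as.matrix(coverage)
  if (any(!is.finite(M0))) stop("coverage matrix must be finite")
  rows <- seq_len(nrow(M0))
  cols <- seq_len(ncol(M0))
  M <- M0
  h <- mean_squared_residue(M)
  while (h > max_variance) {
    if (length(rows) <= 2L && length(cols) <= 2L) {
      warning("variance threshold unreachable; returning best found")
      break
    }
    r <- M - outer(rowMeans(M), colMeans(M), "+") + mean(M)
    dr <- if (length(rows) > 2L) rowMeans(r^2) else -Inf
    dc <- if (length(cols) > 2L) colMeans(r^2) else -Inf
    if (max(dr) >= max(dc)) {
      i <- which.max(dr)
      M <- M[-i, , drop = FALSE]
      rows <- rows[-i]
    } else {
      j <- which.max(dc)
      M <- M[, -j, drop = FALSE]
      cols <- cols[-j]
    }
    h <- mean_squared_residue(M)
  }
  # node addition: re-admit rows/columns consistent with the found bicluster
  repeat {
    changed <- FALSE
    h <- mean_squared_residue(M)
    bar <- max(h, max_variance)
    for (j in setdiff(seq_len(ncol(M0)), cols)) {
      dj <- mean((M0[rows, j] - rowMeans(M) - mean(M0[rows, j]) + mean(M))^2)
      if (dj <= bar) {
        cols <- sort(c(cols, j))
        M <- M0[rows, cols, drop = FALSE]
        changed <- TRUE
        bar <- max(mean_squared_residue(M), max_variance)
      }
    }
    for (i in setdiff(seq_len(nrow(M0)), rows)) {
      di <- mean((M0[i, cols] - colMeans(M) - mean(M0[i, cols]) + mean(M))^2)
      if (di <= bar) {
        rows <- sort(c(rows, i))
        M <- M0[rows, cols, drop = FALSE]
        changed <- TRUE
        bar <- max(mean_squared_residue(M), max_variance)
      }
    }
    if (!changed) break
  }
  list(rows = rows, cols = cols, msr = mean_squared_residue(M))
}
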