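# Pre-analysis quality assurance: nonparametric insert-size distribution,
# read-group anomaly detection, and selection of comparably covered regions.

intra_distances <- function(pairs) {
  same <- pairs$chromA == pairs$chromB
  pairs$posB[same] - pairs$posA[same]
}

#' Nonparametric insert-size distribution
#'
#' Gaussian-kernel density estimate (Silverman's bandwidth) of the
#' intrachromosomal pair distances, with empirical quantiles and tail
#' fractions. The distance used is `posB - posA` between leftmost mapped
#' positions, robust to clipped alignments. Distances above `max_d` are
#' excluded from the density grid (kept for tail fractions and quantiles) so
#' the grid stays bounded.
#'
#' @param pairs A pair table.
#' @param max_d Cap on distances entering the density grid (default 1e6).
#' @param n_grid Number of density grid points.
#' @return An `insert_distribution` object: list with `distances`, `grid`
#'   (data.table of `distance`, `density`), `bandwidth`, `n`.
#' @export
estimate_insert_distribution <- function(pairs, max_d = 1e6, n_grid = 512L) {
  d <- intra_distances(pairs)
  if (length(d) < 100L)
    stop("insufficient data: need >= 100 intrachromosomal pairs, got ",
         length(d))
  dd <- d[d <= max_d]
  den <- stats::density(dd, bw = "nrd0", from = 0, to = max(dd), n = n_grid)
  structure(list(
    distances = d,
    grid = data.table::data.table(distance = den$x, density = den$y),
    bandwidth = den$bw,
    n = length(d)), class = "insert_distribution")
}

#' @export
print.insert_distribution <- function(x, ...) {
  cat("<insert_distribution> n=", x$n,
      " median=", stats::median(x$distances),
      " bw=", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Empirical quantile of an insert distribution
#'
#' @param dist An `insert_distribution`.
#' @param p Probabilities.
#' @return Quantiles of the intrachromosomal distances.
#' @export
insert_quantile <- function(dist, p) {
  unname(stats::quantile(dist$distances, p, type = 7))
}

#' Proportion of pair distances greater than `d`
#'
#' In a clean germline sample roughly 0.1% of pairs map more than 1000 bp
#' apart; `tail_fraction(dist, 1000)` is the direct check of that regime.
#'
#' @param dist An `insert_distribution`.
#' @param d Distance threshold(s) in bases.
#' @return Tail fraction(s) in `[0, 1]`.
#' @export
tail_fraction <- function(dist, d) {
  vapply(d, function(x) mean(dist$distances > x), 0)
}

#' Per-read-group anomaly detection
#'
#' Each read group with at least `min_pairs` pairs is compared with the
#' pooled sample by the two-sample Kolmogorov-Smirnov statistic on
#' intrachromosomal distances and by the ratio of its discordant-pair rate to
#' the pooled rate. Because an anomalous group contaminates the pool it is
#' compared against, flagging is iterative: the worst offender exceeding a
#' threshold (`KS > ks_max` or `ratio > odd_rate_ratio_max`) is flagged and
#' removed from the pool, and the remaining groups are re-tested until the
#' pool is stable. Reported statistics are against the final clean pool, so a
#' single group with shifted inserts shows KS near 1 while clean groups show
#' only sampling noise. Groups below `min_pairs` are exempt and listed as
#' insufficient; records without read-group tags are treated as one group
#' (with a warning).
#'
#' @param pairs A pair table.
#' @param ks_max KS-statistic threshold (default 0.1).
#' @param odd_rate_ratio_max Odd-rate ratio threshold (default 2.0).
#' @param min_pairs Minimum group size to be testable (default 500).
#' @param rules [rule_config()] used for the odd-pair rate.
#' @return A list with `groups` (per-group table: `read_group`, `n_pairs`,
#'   `median_distance`, `ks`, `odd_rate`, `odd_rate_ratio`, `status`) and
#'   `flags` (data.table `read_group`, `reason`).
#' @export
detect_readgroup_anomalies <- function(pairs, ks_max = 0.1,
                                       odd_rate_ratio_max = 2.0,
                                       min_pairs = 500L,
                                       rules = rule_config()) {
  rg <- pairs$read_group
  if (all(is.na(rg))) {
    warning("no read-group tags; treating sample as one group")
    rg <- rep("all", nrow(pairs))
  }
  rg[is.na(rg)] <- "untagged"
  cls <- classify_pairs(pairs, rules)
  intra <- pairs$chromA == pairs$chromB
  dist_all <- pairs$posB - pairs$posA
  groups <- sort(unique(rg))
  n_by_g <- vapply(groups, function(g) sum(rg == g), 0L)
  testable <- groups[n_by_g >= min_pairs]

  stats_vs_pool <- function(g, pool_groups) {
    in_pool <- rg %in% pool_groups
    pooled_d <- dist_all[in_pool & intra]
    pooled_rate <- mean(cls[in_pool] != "NORMAL")
    in_g <- rg == g
    gd <- dist_all[in_g & intra]
    rate <- mean(cls[in_g] != "NORMAL")
    ks <- unname(suppressWarnings(stats::ks.test(gd, pooled_d)$statistic))
    ratio <- if (pooled_rate > 0) rate / pooled_rate
             else if (rate > 0) Inf else 1
    c(ks = ks, ratio = ratio)
  }

  flagged <- character()
  if (length(testable) > 1L) {
    repeat {
      pool <- setdiff(groups, flagged)
      cand <- setdiff(testable, flagged)
      if (length(cand) == 0L || length(pool) <= 1L) break
      st <- vapply(cand, stats_vs_pool, c(ks = 0, ratio = 0),
                   pool_groups = pool)
      exceed <- st["ks", ] > ks_max | st["ratio", ] > odd_rate_ratio_max
      if (!any(exceed)) break
      worst <- cand[exceed][which.max(st["ks", exceed])]
      flagged <- c(flagged, worst)
    }
  }

  pool <- setdiff(groups, flagged)
  rows <- lapply(groups, function(g) {
    in_g <- rg == g
    n <- sum(in_g)
    gd <- dist_all[in_g & intra]
    rate <- mean(cls[in_g] != "NORMAL")
    if (n < min_pairs) {
      return(data.table::data.table(
        read_group = g, n_pairs = n, median_distance = stats::median(gd),
        ks = NA_real_, odd_rate = rate, odd_rate_ratio = NA_real_,
        status = "insufficient"))
    }
    st <- stats_vs_pool(g, if (length(pool)) pool else groups)
    data.table::data.table(
      read_group = g, n_pairs = n, median_distance = stats::median(gd),
      ks = unname(st["ks"]), odd_rate = rate,
      odd_rate_ratio = unname(st["ratio"]),
      status = if (g %in% flagged) "flagged" else "ok")
  })
  tab <- data.table::rbindlist(rows)
  fl <- tab[tab$status == "flagged", ]
  reasons <- vapply(seq_len(nrow(fl)), function(i) {
    r <- character()
    if (fl$ks[i] > ks_max) r <- c(r, "ks")
    if (fl$odd_rate_ratio[i] > odd_rate_ratio_max) r <- c(r, "odd_rate")
    paste(r, collapse = "+")
  }, "")
  list(groups = tab,
       flags = data.table::data.table(read_group = fl$read_group,
                                      reason = reasons))
}

#' Extract a per-bin coverage track from an accumulator
#'
#' @param acc A `bin_accumulator`.
#' @param which `"COVERAGE"` (pair counted at both ends' bins) or
#'   `"COVERAGE_LEFT"` (once, at the leftmost end's bin).
#' @return A `data.table` (`chrom`, `bin`, `count`).
#' @export
coverage_track <- function(acc, which = "COVERAGE") {
  t <- acc$counts1d[acc$counts1d$class == which,
                    c("chrom", "bin", "count"), with = FALSE]
  data.table::copy(t)
}

#' Select regions with sufficient coverage across samples
#'
#' Maximal runs of consecutive bins in which coverage is at least `min_cov`
#' pairs/bin in at least `min_fraction_samples` of samples. Restricting
#' downstream comparison to these regions minimizes batch effects driven by
#' coverage depth. Output is sorted, non-overlapping and bin-aligned.
#'
#' @param tracks Named list of coverage tracks (see [coverage_track()]), one
#'   per sample, sharing bin size and sequence dictionary.
#' @param chrom_lengths Named vector of chromosome lengths in bases.
#' @param bin_size Bin width in bases.
#' @param min_cov Minimum pairs per bin (default 8).
#' @param min_fraction_samples Minimum fraction of samples meeting `min_cov`
#'   (default 0.9).
#' @return A `data.table` of regions (`chrom`, `start`, `end`) in bases.
#' @export
select_usable_regions <- function(tracks, chrom_lengths, bin_size = 1000L,
                                  min_cov = 8L, min_fraction_samples = 0.9) {
  if (!length(tracks)) stop("empty track set")
  ns <- length(tracks)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    nbins <- as.integer(ceiling(chrom_lengths[[chrom]] / bin_size))
    ok <- matrix(FALSE, nrow = nbins, ncol = ns)
    for (s in seq_len(ns)) {
      t <- tracks[[s]]
      sel <- t$chrom == chrom & t$bin < nbins
      t <- t[which(sel), ]
      cov <- integer(nbins)
      cov[t$bin + 1L] <- t$count
      ok[, s] <- cov >= min_cov
    }
    usable <- rowMeans(ok) >= min_fraction_samples
    r <- rle(usable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = chrom,
        start = (starts[i] - 1L) * bin_size,
        end = ends[i] * bin_size)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  data.table::rbindlist(out)
}

#' Assemble a QA report for one sample
#'
#' @param pairs A pair table.
#' @param usable_regions Regions from [select_usable_regions()].
#' @param ... Passed to [detect_readgroup_anomalies()].
#' @return A `qa_report`: list with `sample_id`, `groups`, `flags`,
#'   `usable_regions`, `pass` (TRUE iff no flags and usable regions exist).
#' @export
qa_report <- function(pairs, usable_regions, ...) {
  an <- detect_readgroup_anomalies(pairs, ...)
  structure(list(
    sample_id = pairs$sample_id[1],
    groups = an$groups,
    flags = an$flags,
    usable_regions = usable_regions,
    pass = nrow(an$flags) == 0L && nrow(usable_regions) > 0L),
    class = "qa_report")
}

#' QA verdict for a matched tumor/blood pair
#'
#' The pair passes only if both samples pass; failure reasons are propagated.
#'
#' @param tumor,blood `qa_report` objects (either may be `NULL` when the
#'   sample is missing).
#' @return List with `pass` and `reasons` (character vector).
#' @export
qa_verdict <- function(tumor, blood) {
  reasons <- character()
  for (nm in c("tumor", "blood")) {
    rep <- if (nm == "tumor") tumor else blood
    if (is.null(rep)) {
      reasons <- c(reasons, paste0(nm, ": unmatched"))
      next
    }
    if (nrow(rep$flags))
      reasons <- c(reasons, paste0(nm, ": flagged read group(s) ",
                                   paste(rep$flags$read_group,
                                         collapse = ",")))
    if (!nrow(rep$usable_regions))
      reasons <- c(reasons, paste0(nm, ": no usable regions"))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
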