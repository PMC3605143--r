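# The two-pass caller: pass 1 streams pairs into the bin accumulator; pass 2
# clusters 2D cells into candidate features, scores them by aggregated
# mapping quality, and filters on support count and local-coverage fraction.

#' Calling parameters
#'
#' A candidate becomes a call when it has at least `min_support` distinct
#' supporting pairs and those pairs account for more than
#' `min_support_fraction` of the local coverage. The defaults (3 and 0.05)
#' implement "more than two supporting reads, accounting for more than 5% of
#' local coverage"; `min_support = 2` reproduces the more permissive variant.
#'
#' @param min_support Minimum distinct supporting pairs (default 3).
#' @param min_support_fraction Support must exceed this fraction of local
#'   coverage (default 0.05).
#' @param adjacency_radius Cells whose bin indices differ by at most this, on
#'   both axes, are merged by single linkage (default 1), resolving clusters
#'   that straddle bin boundaries.
#' @return A `call_config` list.
#' @export
call_config <- function(min_support = 3L, min_support_fraction = 0.05,
                        adjacency_radius = 1L) {
  if (min_support < 1) stop("min_support must be >= 1")
  if (min_support_fraction < 0 || min_support_fraction >= 1)
    stop("min_support_fraction must be in [0, 1)")
  structure(list(min_support = as.integer(min_support),
                 min_support_fraction = min_support_fraction,
                 adjacency_radius = as.integer(adjacency_radius)),
            class = "call_config")
}

#' First pass: classify and accumulate a pair stream
#'
#' Every pair is classified once and accumulated into the coarse-bin
#' structure in a single linear pass. The result is mergeable with other
#' partial accumulators of the same stream (see [merge.bin_accumulator()]),
#' so a sample can be processed in partitions and reduced.
#'
#' @param pairs A pair table from one sample.
#' @param rules A [rule_config()].
#' @param seqnames Chromosome order; defaults to the `seqnames` attribute of
#'   `pairs` (set by [read_pairs()]).
#' @param bin_size Bin width in bases (default 1000).
#' @return A `bin_accumulator`.
#' @export
pass1 <- function(pairs, rules = rule_config(), seqnames = NULL,
                  bin_size = 1000L) {
  if (is.null(seqnames)) seqnames <- attr(pairs, "seqnames")
  if (is.null(seqnames))
    seqnames <- unique(c(pairs$chromA, pairs$chromB))
  acc <- bin_accumulator(seqnames, bin_size)
  accumulate(acc, pairs, classify_pairs(pairs, rules))
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Second pass: cluster 2D odd cells into candidate features
#'
#' Cells of the same class on the same chromosome pair whose bin indices
#' differ by at most `adjacency_radius` on both axes are merged by single
#' linkage. A candidate's extent is the bounding bin range on each axis and
#' its support is the union of the distinct read names in its cells. Output
#' order is deterministic (by regionA, then regionB, then class).
#'
#' @param acc A finalized `bin_accumulator`.
#' @param cfg A [call_config()].
#' @return A `data.table` of candidates with columns `sv_class`, `chromA`,
#'   `binA_min`, `binA_max`, `chromB`, `binB_min`, `binB_max`, `n_support`,
#'   and list columns `names` and `mapqs` (per distinct supporting pair).
#' @export
cluster_cells <- function(acc, cfg = call_config()) {
  cells <- odd_cells(acc)
  out <- data.table::data.table(
    sv_class = character(), chromA = character(),
    binA_min = integer(), binA_max = integer(), chromB = character(),
    binB_min = integer(), binB_max = integer(), n_support = integer(),
    names = list(), mapqs = list())
  if (!nrow(cells)) return(out)
  r <- cfg$adjacency_radius
  grp <- paste(cells$class, cells$chromA, cells$chromB, sep = "\r")
  res <- vector("list", 0L)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    k <- length(idx)
    parent <- seq_len(k)
    if (k > 1L) {
      bA <- cells$binA[idx]; bB <- cells$binB[idx]
      for (i in seq_len(k - 1L)) {
        near <- which(abs(bA[(i + 1L):k] - bA[i]) <= r &
                        abs(bB[(i + 1L):k] - bB[i]) <= r) + i
        for (j in near) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(k), function(i) uf_find(parent, i), 0L)
    for (cl in unique(root)) {
      sub <- cells[idx[root == cl], ]
      nm <- unlist(sub$names)
      mq <- unlist(sub$mapqs)
      keep <- !duplicated(nm)
      res[[length(res) + 1L]] <- data.table::data.table(
        sv_class = sub$class[1], chromA = sub$chromA[1],
        binA_min = min(sub$binA), binA_max = max(sub$binA),
        chromB = sub$chromB[1],
        binB_min = min(sub$binB), binB_max = max(sub$binB),
        n_support = sum(keep),
        names = list(nm[keep]), mapqs = list(mq[keep]))
    }
  }
  out <- data.table::rbindlist(res)
  out[, c("..rA", "..rB") := list(chrom_rank(out$chromA, acc$seqnames),
                                  chrom_rank(out$chromB, acc$seqnames))]
  data.table::setorderv(out, c("..rA", "binA_min", "..rB", "binB_min",
                               "sv_class"))
  out[, c("..rA", "..rB") := NULL]
  out
}

#' Probabilistic feature score from supporting mapping qualities
#'
#' With `p_i = 10^(-q_i / 10)` the mismapping probability of supporting pair
#' `i`, the score is `1 - prod(p_i)`: the probability that not all supporting
#' pairs were mismapped. It increases with both the number of supporting
#' pairs and each pair's quality; it is 0 only when every support has mapq 0.
#'
#' @param support_mapqs Non-empty vector of Phred-scaled qualities; 255
#'   ("unavailable") is replaced by `default_mapq_for_unavailable`.
#' @param default_mapq_for_unavailable Substitute for mapq 255 (default 20).
#' @return Probability in `[0, 1]`.
#' @export
score_feature <- function(support_mapqs, default_mapq_for_unavailable = 20L) {
  if (!length(support_mapqs)) stop("empty mapping-quality list")
  q <- as.numeric(support_mapqs)
  if (any(is.na(q) | q < 0)) stop("mapping qualities must be >= 0")
  q[q == 255] <- default_mapq_for_unavailable
  1 - 10^(-sum(q) / 10)
}

local_coverage_of <- function(acc, cand) {
  left <- acc$counts1d[acc$counts1d$class == "COVERAGE_LEFT", ]
  binsA <- data.table::data.table(chrom = cand$chromA,
                                  bin = seq(cand$binA_min, cand$binA_max))
  binsB <- data.table::data.table(chrom = cand$chromB,
                                  bin = seq(cand$binB_min, cand$binB_max))
  bins <- unique(data.table::rbindlist(list(binsA, binsB)))
  hit <- merge(bins, left, by = c("chrom", "bin"))
  sum(hit$count)
}

#' Call structural variants from an accumulator
#'
#' Candidates from [cluster_cells()] are kept when they have at least
#' `min_support` distinct supporting pairs and those pairs exceed
#' `min_support_fraction` of the local coverage. Local coverage is the number
#' of pairs (all classes, deduplicated) whose leftmost end lies in the
#' candidate's bins on either axis. `BEYOND_WINDOW` evidence is tallied but
#' excluded from calling unless `rules$count_beyond_window` is set. Classes
#' are never mixed within one call.
#'
#' @param acc A finalized `bin_accumulator`.
#' @param cfg A [call_config()].
#' @param rules The [rule_config()] used in pass 1.
#' @param sample_id Sample identifier for the output rows.
#' @return A `data.table` of calls: `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB` (bases, bin-aligned, 0-based half-open), `sv_class`,
#'   `n_support`, `local_coverage`, `support_fraction`, `score`, `sample_id`.
#' @export
call_svs <- function(acc, cfg = call_config(), rules = rule_config(),
                     sample_id = "sample") {
  cand <- cluster_cells(acc, cfg)
  callable <- c("WINDOW_DISTANCE", "ORIENTATION", "INTERCHROM",
                if (rules$count_beyond_window) "BEYOND_WINDOW")
  cand <- cand[cand$sv_class %in% callable, ]
  empty <- data.table::data.table(
    chromA = character(), startA = integer(), endA = integer(),
    chromB = character(), startB = integer(), endB = integer(),
    sv_class = character(), n_support = integer(),
    local_coverage = integer(), support_fraction = numeric(),
    score = numeric(), sample_id = character())
  if (!nrow(cand)) return(empty)
  bs <- acc$bin_size
  lc <- vapply(seq_len(nrow(cand)),
               function(i) local_coverage_of(acc, cand[i, ]), 0)
  frac <- cand$n_support / lc
  keep <- cand$n_support >= cfg$min_support & frac > cfg$min_support_fraction
  cand <- cand[keep, ]
  if (!nrow(cand)) return(empty)
  lc <- lc[keep]; frac <- frac[keep]
  data.table::data.table(
    chromA = cand$chromA,
    startA = cand$binA_min * bs, endA = (cand$binA_max + 1L) * bs,
    chromB = cand$chromB,
    startB = cand$binB_min * bs, endB = (cand$binB_max + 1L) * bs,
    sv_class = cand$sv_class,
    n_support = cand$n_support,
    local_coverage = as.integer(lc),
    support_fraction = frac,
    score = vapply(cand$mapqs, score_feature, 0,
                   default_mapq_for_unavailable =
                     rules$default_mapq_for_unavailable),
    sample_id = sample_id)
}

#' Diagnostic distribution of odd-pair cluster sizes
#'
#' Frequency table of cluster sizes per class, from the same single-linkage
#' clustering used for calling. Comparing tumor against matched blood samples
#' with this table is how the minimum-support threshold is chosen: background
#' mismapping produces almost exclusively size-1 clusters.
#'
#' @param acc A finalized `bin_accumulator`.
#' @param cfg A [call_config()] (for the adjacency radius).
#' @return A `data.table` with columns `sv_class`, `size`, `n_clusters`.
#' @export
cluster_size_distribution <- function(acc, cfg = call_config()) {
  cand <- cluster_cells(acc, cfg)
  if (!nrow(cand))
    return(data.table::data.table(sv_class = character(), size = integer(),
                                  n_clusters = integer()))
  out <- cand[, list(n_clusters = .N), by = list(sv_class = cand$sv_class,
                                                 size = cand$n_support)]
  data.table::setorderv(out, c("sv_class", "size"))
  out
}

regions_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  chrom1 == chrom2 & start1 < end2 & start2 < end1
}

#' Local-topology tree of a region under its structural variants
#'
#' Depth-first traversal from an anchor region: every call whose regionA or
#' regionB overlaps the current region spawns a child node for the call's
#' partner region. Each (call, direction) edge is used at most once so cycles
#' are broken, and the traversal is bounded by `max_depth`. The result is a
#' nested record (region, supporting-read count, children) describing how the
#' anchored locus connects to other regions and chromosomes.
#'
#' @param calls A call table for one sample.
#' @param anchor `list(chrom=, start=, end=)` in 0-based half-open bases.
#' @param max_depth Maximum tree depth below the root.
#' @param seqnames Known chromosome names (for anchor validation).
#' @return A nested list with elements `chrom`, `start`, `end`, `n_support`
#'   (NA at the root), `sv_class` (NA at the root) and `children`.
#' @export
local_topology_tree <- function(calls, anchor, max_depth = 3L,
                                seqnames = NULL) {
  if (!is.null(seqnames) && !(anchor$chrom %in% seqnames))
    stop("anchor on unknown chromosome: ", anchor$chrom)
  used <- new.env(parent = emptyenv())
  visit <- function(chrom, start, end, depth, n_support, sv_class) {
    node <- list(chrom = chrom, start = start, end = end,
                 n_support = n_support, sv_class = sv_class,
                 children = list())
    if (depth >= max_depth || !nrow(calls)) return(node)
    hitA <- regions_overlap(calls$chromA, calls$startA, calls$endA,
                            chrom, start, end)
    hitB <- regions_overlap(calls$chromB, calls$startB, calls$endB,
                            chrom, start, end)
    for (i in seq_len(nrow(calls))) {
      for (side in c("A", "B")[c(hitA[i], hitB[i])]) {
        key <- paste0(i, side)
        if (exists(key, envir = used)) next
        assign(key, TRUE, envir = used)
        if (side == "A")
          node$children[[length(node$children) + 1L]] <-
            visit(calls$chromB[i], calls$startB[i], calls$endB[i],
                  depth + 1L, calls$n_support[i], calls$sv_class[i])
        else
          node$children[[length(node$children) + 1L]] <-
            visit(calls$chromA[i], calls$startA[i], calls$endA[i],
                  depth + 1L, calls$n_support[i], calls$sv_class[i])
      }
    }
    node
  }
  visit(anchor$chrom, anchor$start, anchor$end, 0L, NA_integer_,
        NA_character_)
}

#' End-to-end detection for one alignment file
#'
#' Convenience wrapper: [read_pairs()], [pass1()], [call_svs()].
#'
#' @param path SAM/BAM file.
#' @param rules A [rule_config()].
#' @param cfg A [call_config()].
#' @param bin_size Bin width in bases.
#' @param sample_id Sample identifier.
#' @return A call table (see [call_svs()]).
#' @export
detect_sample <- function(path, rules = rule_config(), cfg = call_config(),
                          bin_size = 1000L, sample_id = "sample") {
  pairs <- read_pairs(path, sample_id = sample_id)
  acc <- pass1(pairs, rules, bin_size = bin_size)
  call_svs(acc, cfg, rules, sample_id = sample_id)
}
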