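# Coarse-bin spatial accumulators and the partition-merge contract.
#
# All internal coordinates are 0-based half-open; SAM's 1-based positions are
# converted at the I/O boundary. Chromosome order is the order of the sequence
# dictionary supplied at construction, so canonical 2D keys are deterministic
# without imposing a naming scheme.

PAIR_CLASSES <- c("NORMAL", "WINDOW_DISTANCE", "BEYOND_WINDOW",
                  "ORIENTATION", "INTERCHROM")
ODD_CLASSES <- setdiff(PAIR_CLASSES, "NORMAL")

# 1D tallies kept per (chrom, bin): COVERAGE counts a pair at both ends' bins
# (deduplicated per bin), COVERAGE_LEFT counts it once, at its leftmost end's
# bin, and is the tally used for local coverage of candidate features.
COUNT1D_CLASSES <- c("COVERAGE", "COVERAGE_LEFT", ODD_CLASSES)

#' Bin index of a genomic position
#'
#' Bins are half-open windows `[k * bin_size, (k + 1) * bin_size)` so the index
#' is simply `floor(pos / bin_size)`.
#'
#' @param pos Integer vector of 0-based base positions.
#' @param bin_size Bin width in bases.
#' @return Integer vector of 0-based bin indices.
#' @export
bin_index <- function(pos, bin_size) {
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (any(is.na(pos)) || any(pos < 0))
    stop("positions must be non-negative")
  as.integer(pos %/% bin_size)
}

chrom_rank <- function(chrom, seqnames) {
  match(chrom, seqnames)
}

#' Canonical ordering of a 2D bin key
#'
#' Returns the (min, max) ordering of two (chromosome, bin) locations under
#' (sequence-dictionary order, bin index), so that counts for A->B and B->A
#' pairs land in the same cell. Vectorized over locations.
#'
#' @param chromA,binA,chromB,binB Location components.
#' @param seqnames Character vector giving the chromosome order.
#' @return A `data.table` with columns `chromA`, `binA`, `chromB`, `binB` in
#'   canonical order.
#' @export
canonical_2d_key <- function(chromA, binA, chromB, binB, seqnames) {
  rA <- chrom_rank(chromA, seqnames)
  rB <- chrom_rank(chromB, seqnames)
  if (any(is.na(rA)) || any(is.na(rB)))
    stop("unknown chromosome in 2D key")
  swap <- rA > rB | (rA == rB & binA > binB)
  data.table::data.table(
    chromA = ifelse(swap, chromB, chromA),
    binA   = as.integer(ifelse(swap, binB, binA)),
    chromB = ifelse(swap, chromA, chromB),
    binB   = as.integer(ifelse(swap, binA, binB))
  )
}

#' Create an empty bin accumulator
#'
#' The accumulator holds 1D per-bin tallies (pair coverage and per-class
#' discordant counts) and the 2D odd-pair records (one row per distinct
#' supporting pair per cell, carrying `min(mapqA, mapqB)` — a feature is only
#' as reliable as its worse-mapped end). Accumulators with the same `bin_size`
#' and sequence dictionary merge associatively and commutatively, with the
#' empty accumulator as identity.
#'
#' @param seqnames Character vector of chromosome names; its order defines the
#'   canonical chromosome order.
#' @param bin_size Bin width in bases (default 1000, the resolution at which
#'   nearly all normal pairs fall within one bin).
#' @return An object of class `bin_accumulator`.
#' @export
bin_accumulator <- function(seqnames, bin_size = 1000L) {
  if (length(seqnames) < 1L || anyDuplicated(seqnames))
    stop("seqnames must be a non-empty set of unique chromosome names")
  if (length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be positive")
  structure(list(
    bin_size = as.integer(bin_size),
    seqnames = as.character(seqnames),
    counts1d = data.table::data.table(chrom = character(), bin = integer(),
                                      class = character(), count = integer()),
    odd2d = data.table::data.table(chromA = character(), binA = integer(),
                                   chromB = character(), binB = integer(),
                                   class = character(), name = character(),
                                   mapq = integer()),
    skipped = c(unknown_chromosome = 0L)
  ), class = "bin_accumulator")
}

# Canonical sorted/aggregated form so that merged and single-pass accumulators
# compare identical().
normalize_accumulator <- function(acc) {
  count <- chrom <- chromA <- chromB <- NULL
  c1 <- acc$counts1d[, list(count = as.integer(sum(count))),
                     by = c("chrom", "bin", "class")]
  data.table::setorderv(
    c1[, "r" := chrom_rank(chrom, acc$seqnames)],
    c("r", "bin", "class"))
  c1[, "r" := NULL]
  o2 <- unique(acc$odd2d,
               by = c("chromA", "binA", "chromB", "binB", "class", "name"))
  o2 <- data.table::copy(o2)
  o2[, c("rA", "rB") := list(chrom_rank(chromA, acc$seqnames),
                             chrom_rank(chromB, acc$seqnames))]
  data.table::setorderv(o2, c("rA", "binA", "rB", "binB", "class", "name"))
  o2[, c("rA", "rB") := NULL]
  acc$counts1d <- c1
  acc$odd2d <- o2
  acc
}

#' Accumulate classified read pairs
#'
#' Single-pass update: for every pair, `COVERAGE` is incremented at the bin of
#' `posA` and at the bin of `posB` when that is a different (chromosome, bin);
#' `COVERAGE_LEFT` is incremented once at the bin of `posA`. A discordant pair
#' additionally increments its class tally at the bin of `posA` and appends a
#' record to the canonical 2D cell for (binA, binB). Pairs on chromosomes not
#' in the sequence dictionary are rejected with a warning and counted in the
#' skip tally.
#'
#' @param acc A `bin_accumulator`.
#' @param pairs A pair table (see [pair_records()]).
#' @param classes Character vector of pair classes, one per row of `pairs`
#'   (see [classify_pairs()]).
#' @return The updated accumulator.
#' @export
accumulate <- function(acc, pairs, classes) {
  stopifnot(inherits(acc, "bin_accumulator"), nrow(pairs) == length(classes))
  if (nrow(pairs) == 0L) return(acc)
  bad <- !(pairs$chromA %in% acc$seqnames) | !(pairs$chromB %in% acc$seqnames)
  if (any(bad)) {
    warning(sum(bad), " pair(s) on unknown chromosomes skipped")
    acc$skipped["unknown_chromosome"] <-
      acc$skipped["unknown_chromosome"] + sum(bad)
    pairs <- pairs[!bad, ]
    classes <- classes[!bad]
    if (nrow(pairs) == 0L) return(normalize_accumulator(acc))
  }
  binA <- bin_index(pairs$posA, acc$bin_size)
  binB <- bin_index(pairs$posB, acc$bin_size)

  covA <- data.table::data.table(chrom = pairs$chromA, bin = binA,
                                 class = "COVERAGE")
  otherbin <- pairs$chromA != pairs$chromB | binA != binB
  covB <- data.table::data.table(chrom = pairs$chromB[otherbin],
                                 bin = binB[otherbin], class = "COVERAGE")
  covL <- data.table::data.table(chrom = pairs$chromA, bin = binA,
                                 class = "COVERAGE_LEFT")
  odd <- classes != "NORMAL"
  odd1 <- data.table::data.table(chrom = pairs$chromA[odd], bin = binA[odd],
                                 class = classes[odd])
  new1 <- data.table::rbindlist(list(covA, covB, covL, odd1))
  new1 <- new1[, list(count = .N), by = c("chrom", "bin", "class")]
  new1[, "count" := as.integer(new1$count)]
  acc$counts1d <- data.table::rbindlist(list(acc$counts1d, new1))

  if (any(odd)) {
    key <- canonical_2d_key(pairs$chromA[odd], binA[odd],
                            pairs$chromB[odd], binB[odd], acc$seqnames)
    key[, c("class", "name", "mapq") := list(
      classes[odd], pairs$name[odd],
      as.integer(pmin(pairs$mapqA[odd], pairs$mapqB[odd])))]
    acc$odd2d <- data.table::rbindlist(list(acc$odd2d, key))
  }
  normalize_accumulator(acc)
}

#' Merge two bin accumulators
#'
#' Pointwise sum of all 1D counts, union of the 2D odd-pair records, and sum
#' of skip tallies. Merging the partial accumulators of any partition of a
#' stream is bit-exact equal to accumulating the whole stream in one pass,
#' which is what makes the analysis distributable (map-reduce style) while
#' staying exactly reproducible.
#'
#' @param x,y Accumulators with identical `bin_size` and sequence dictionary.
#' @param ... Ignored.
#' @return The merged `bin_accumulator`.
#' @export
merge.bin_accumulator <- function(x, y, ...) {
  if (!inherits(y, "bin_accumulator"))
    stop("can only merge two bin_accumulator objects")
  if (x$bin_size != y$bin_size)
    stop("incompatible accumulators: bin_size differs")
  if (!identical(x$seqnames, y$seqnames))
    stop("incompatible accumulators: sequence dictionaries differ")
  x$counts1d <- data.table::rbindlist(list(x$counts1d, y$counts1d))
  x$odd2d <- data.table::rbindlist(list(x$odd2d, y$odd2d))
  x$skipped <- x$skipped + y$skipped
  normalize_accumulator(x)
}

#' Aggregate the 2D odd-pair cells of an accumulator
#'
#' @param acc A `bin_accumulator`.
#' @return A `data.table` with one row per (cell, class): `chromA`, `binA`,
#'   `chromB`, `binB`, `class`, `n_odd`, plus list columns `mapqs` and `names`.
#' @export
odd_cells <- function(acc) {
  mapq <- name <- NULL
  acc$odd2d[, list(n_odd = .N, mapqs = list(mapq), names = list(name)),
            by = c("chromA", "binA", "chromB", "binB", "class")]
}

#' @export
print.bin_accumulator <- function(x, ...) {
  cov <- x$counts1d[x$counts1d$class == "COVERAGE_LEFT", ]
  cat("<bin_accumulator> bin_size=", x$bin_size,
      " chroms=", length(x$seqnames),
      " pairs=", sum(cov$count),
      " odd=", nrow(x$odd2d),
      " skipped=", sum(x$skipped), "\n", sep = "")
  invisible(x)
}

#' Serialize an accumulator to a line-oriented TSV dump
#'
#' The dump is sorted and fully deterministic so that partial results written
#' by separate processes can be merged by an external reducer; a write/read
#' round trip is bit-exact. Record types: `META` (bin size, chromosome order),
#' `1D` rows carrying (chrom, bin, class, count), `2D` rows carrying the
#' odd-pair records, and `SKIP` tallies.
#'
#' @param acc A `bin_accumulator`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accumulator <- function(acc, path) {
  acc <- normalize_accumulator(acc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("META", "bin_size", acc$bin_size, sep = "\t"),
    paste("META", "seqnames", paste(acc$seqnames, collapse = ","), sep = "\t")
  ), con)
  if (nrow(acc$counts1d))
    writeLines(paste("1D", acc$counts1d$chrom, acc$counts1d$bin,
                     acc$counts1d$class, acc$counts1d$count, sep = "\t"), con)
  if (nrow(acc$odd2d))
    writeLines(paste("2D", acc$odd2d$chromA, acc$odd2d$binA, acc$odd2d$chromB,
                     acc$odd2d$binB, acc$odd2d$class, acc$odd2d$name,
                     acc$odd2d$mapq, sep = "\t"), con)
  writeLines(paste("SKIP", names(acc$skipped), acc$skipped, sep = "\t"), con)
  invisible(path)
}

#' Read an accumulator dump written by [write_accumulator()]
#'
#' @param path Path to a dump file.
#' @return A `bin_accumulator`.
#' @export
read_accumulator <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty accumulator dump: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(fields, `[`, "", 1L)
  meta <- fields[type == "META"]
  kv <- stats::setNames(vapply(meta, `[`, "", 3L), vapply(meta, `[`, "", 2L))
  acc <- bin_accumulator(strsplit(kv[["seqnames"]], ",", fixed = TRUE)[[1]],
                         as.integer(kv[["bin_size"]]))
  d1 <- fields[type == "1D"]
  if (length(d1)) {
    m <- do.call(rbind, d1)
    acc$counts1d <- data.table::data.table(
      chrom = m[, 2], bin = as.integer(m[, 3]),
      class = m[, 4], count = as.integer(m[, 5]))
  }
  d2 <- fields[type == "2D"]
  if (length(d2)) {
    m <- do.call(rbind, d2)
    acc$odd2d <- data.table::data.table(
      chromA = m[, 2], binA = as.integer(m[, 3]),
      chromB = m[, 4], binB = as.integer(m[, 5]),
      class = m[, 6], name = m[, 7], mapq = as.integer(m[, 8]))
  }
  sk <- fields[type == "SKIP"]
  if (length(sk))
    acc$skipped <- stats::setNames(as.integer(vapply(sk, `[`, "", 3L)),
                                   vapply(sk, `[`, "", 2L))
  normalize_accumulator(acc)
}
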