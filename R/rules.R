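# Pair records and the rule system that classifies each mate pair as normal
# or one of the discordant ("odd") categories.

#' Construct a canonical table of read-pair records
#'
#' One row per sequenced template. Ends are stored in canonical order: the
#' (chromA, posA) end sorts before or equal to (chromB, posB) under
#' (sequence-dictionary order, position); inputs are swapped end-for-end where
#' needed. Positions are 0-based.
#'
#' @param name Template names.
#' @param chromA,posA,strandA First end (chromosome, 0-based position, strand
#'   `"+"`/`"-"`).
#' @param chromB,posB,strandB Second end.
#' @param mapqA,mapqB Phred-scaled mapping qualities in `[0, 255]`; 255 means
#'   "quality unavailable".
#' @param seqnames Chromosome order used for canonicalization.
#' @param read_group Read-group tags (recycled).
#' @param sample_id Sample identifier (recycled).
#' @return A `data.table` with one row per pair.
#' @export
pair_records <- function(name, chromA, posA, strandA, chromB, posB, strandB,
                         mapqA, mapqB, seqnames,
                         read_group = "rg0", sample_id = "sample") {
  n <- length(name)
  dt <- data.table::data.table(
    name = as.character(name),
    chromA = as.character(chromA), posA = as.integer(posA),
    strandA = as.character(strandA),
    chromB = as.character(chromB), posB = as.integer(posB),
    strandB = as.character(strandB),
    mapqA = as.integer(mapqA), mapqB = as.integer(mapqB),
    read_group = rep_len(as.character(read_group), n),
    sample_id = rep_len(as.character(sample_id), n))
  if (any(dt$posA < 0 | dt$posB < 0, na.rm = TRUE))
    stop("positions must be >= 0")
  if (any(dt$mapqA < 0 | dt$mapqA > 255 | dt$mapqB < 0 | dt$mapqB > 255))
    stop("mapping qualities must be in [0, 255]")
  if (!all(c(dt$strandA, dt$strandB) %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  rA <- chrom_rank(dt$chromA, seqnames)
  rB <- chrom_rank(dt$chromB, seqnames)
  if (any(is.na(rA)) || any(is.na(rB)))
    stop("chromosome not in sequence dictionary")
  swap <- rA > rB | (rA == rB & dt$posA > dt$posB)
  if (any(swap)) {
    a <- c("chromA", "posA", "strandA", "mapqA")
    b <- c("chromB", "posB", "strandB", "mapqB")
    tmp <- dt[swap, a, with = FALSE]
    for (i in seq_along(a)) {
      data.table::set(dt, which(swap), a[i], dt[[b[i]]][swap])
      data.table::set(dt, which(swap), b[i], tmp[[i]])
    }
  }
  dt
}

#' Rule parameters for pair classification
#'
#' Normal pairs have small insert distances: in the germline regime only about
#' 0.1% of pairs map more than 1000 bp apart, which sets the bin size and the
#' lower edge of the discordant-distance window. Tumor samples show an
#' enrichment of pair distances in the 1000-7000 bp window; distances beyond
#' 7000 bp are tallied (`BEYOND_WINDOW`) but excluded from calling by default
#' because they are not enriched over background.
#'
#' @param normal_max_distance Largest insert distance regarded as normal, in
#'   bases (default 1000).
#' @param window_min,window_max Discordant-distance window `(window_min,
#'   window_max]` in bases (defaults 1000 and 7000).
#' @param expected_orientation Library geometry; only `"FR-inward"` (leftmost
#'   read forward, rightmost reverse) is currently implemented.
#' @param count_beyond_window Should `BEYOND_WINDOW` pairs enter SV calling?
#'   Default `FALSE`.
#' @param default_mapq_for_unavailable Phred value substituted for mapq 255
#'   when scoring features (never used in classification). Default 20.
#' @return A `rule_config` list.
#' @export
rule_config <- function(normal_max_distance = 1000L,
                        window_min = 1000L,
                        window_max = 7000L,
                        expected_orientation = "FR-inward",
                        count_beyond_window = FALSE,
                        default_mapq_for_unavailable = 20L) {
  if (!(normal_max_distance > 0 && normal_max_distance <= window_min &&
        window_min < window_max))
    stop("need 0 < normal_max_distance <= window_min < window_max")
  expected_orientation <- match.arg(expected_orientation, "FR-inward")
  structure(list(normal_max_distance = as.integer(normal_max_distance),
                 window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 expected_orientation = expected_orientation,
                 count_beyond_window = isTRUE(count_beyond_window),
                 default_mapq_for_unavailable =
                   as.integer(default_mapq_for_unavailable)),
            class = "rule_config")
}

#' Classify read pairs as normal or discordant
#'
#' Each pair receives exactly one class, by precedence:
#' 1. `INTERCHROM` — ends on different chromosomes (no meaningful single-axis
#'    distance exists, so this outranks everything);
#' 2. `ORIENTATION` — strands differ from the expected FR-inward geometry
#'    (leftmost end `+`, rightmost end `-`), regardless of distance;
#' 3. distance `d = posB - posA`: `WINDOW_DISTANCE` when
#'    `window_min < d <= window_max`, `BEYOND_WINDOW` when `d > window_max`,
#'    otherwise `NORMAL`.
#'
#' The boundary convention makes `d = 1000` normal ("more than 1000 bp" is the
#' abnormal tail) and `d = 7000` in-window.
#'
#' @param pairs A pair table from [pair_records()].
#' @param cfg A [rule_config()].
#' @return Character vector of classes, one per pair.
#' @export
classify_pairs <- function(pairs, cfg = rule_config()) {
  d <- pairs$posB - pairs$posA
  cls <- rep("NORMAL", nrow(pairs))
  cls[d > cfg$window_min & d <= cfg$window_max] <- "WINDOW_DISTANCE"
  cls[d > cfg$window_max] <- "BEYOND_WINDOW"
  cls[pairs$strandA != "+" | pairs$strandB != "-"] <- "ORIENTATION"
  cls[pairs$chromA != pairs$chromB] <- "INTERCHROM"
  cls
}

#' @rdname classify_pairs
#' @export
classify_pair <- classify_pairs

#' Read a key-value configuration file
#'
#' Lines of the form `key = value` or `key: value`; `#` starts a comment.
#' Recognized rule keys (`normal_max_distance`, `window_min`, `window_max`,
#' `count_beyond_window`, `default_mapq_for_unavailable`) feed
#' [rule_config()]; callers may read other keys from the returned list.
#'
#' @param path Config file path.
#' @return Named list of values (numbers parsed where possible).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("unparseable config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  parsed <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(parsed, keys)
}

#' Build a [rule_config()] from a parsed configuration list
#'
#' @param conf Named list, e.g. from [read_config()].
#' @return A `rule_config`.
#' @export
rule_config_from_list <- function(conf) {
  take <- function(key, default) if (!is.null(conf[[key]])) conf[[key]] else default
  rule_config(
    normal_max_distance = take("normal_max_distance", 1000),
    window_min = take("window_min", 1000),
    window_max = take("window_max", 7000),
    count_beyond_window = take("count_beyond_window", FALSE),
    default_mapq_for_unavailable = take("default_mapq_for_unavailable", 20))
}
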