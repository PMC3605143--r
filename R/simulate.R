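# Seeded mate-pair simulator: background library pairs, planted structural
# variants (deletion, inversion, inter-chromosomal translocation), SAM
# emission with a truth record, and a matched tumor/blood scenario.
#
# No sequence bases are simulated: reads are position-only with placeholder
# sequence, because the caller consumes only the output of mapping (positions,
# strands, qualities), never the reads themselves.

#' Simulation parameters
#'
#' Defaults emulate a clean paired-end library: insert sizes N(400, 50^2)
#' (so essentially no normal pair maps more than 1000 bp from its mate), and
#' a mismapped-noise fraction of 0.001 — the regime in which 0.1% of germline
#' pairs show distances above 1000 bp. `pairs_per_kb = 10` gives roughly ten
#' pairs per 1000-bp bin, a desk-scale stand-in for exome-like depth.
#'
#' @param seed Integer seed; identical seeds yield byte-identical streams.
#' @param chrom_lengths Named vector of chromosome lengths in bases.
#' @param insert_mean,insert_sd Insert-size distribution in bases.
#' @param pairs_per_kb Background pair density.
#' @param mismap_noise_rate Fraction of pairs whose mate is re-mapped to a
#'   uniformly random chromosome/position/strand.
#' @param mapq_true,mapq_noise Phred mapping qualities for correctly mapped
#'   and mismapped ends.
#' @param read_groups Read-group labels cycled over background pairs.
#' @param planted List of [planted_sv()] events (tumor scenarios).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       insert_mean = 400, insert_sd = 50,
                       pairs_per_kb = 10,
                       mismap_noise_rate = 0.001,
                       mapq_true = 60L, mapq_noise = 15L,
                       read_groups = c("rg1", "rg2"),
                       planted = list()) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (mismap_noise_rate < 0 || mismap_noise_rate >= 1)
    stop("mismap_noise_rate must be in [0, 1)")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 pairs_per_kb = pairs_per_kb,
                 mismap_noise_rate = mismap_noise_rate,
                 mapq_true = as.integer(mapq_true),
                 mapq_noise = as.integer(mapq_noise),
                 read_groups = read_groups,
                 planted = planted),
            class = "sim_config")
}

#' A planted structural variant
#'
#' @param kind `"deletion"`, `"inversion"` or `"translocation"`.
#' @param chrom,pos Breakpoint locus (0-based).
#' @param size Deletion size in bases (default 3000, inside the 1000-7000 bp
#'   window that discordant-distance calling targets; larger sizes exercise
#'   the beyond-window exclusion).
#' @param partner_chrom,partner_pos Partner locus (translocations).
#' @param n_support Number of supporting pairs to emit.
#' @return A `planted_sv` list.
#' @export
planted_sv <- function(kind = c("deletion", "inversion", "translocation"),
                       chrom, pos, size = 3000L,
                       partner_chrom = NULL, partner_pos = NULL,
                       n_support = 8L) {
  kind <- match.arg(kind)
  if (kind == "translocation") {
    if (is.null(partner_chrom) || is.null(partner_pos))
      stop("translocation needs a partner locus")
    if (identical(partner_chrom, chrom))
      stop("translocation partner must be on a different chromosome")
  }
  structure(list(kind = kind, chrom = chrom, pos = as.integer(pos),
                 size = as.integer(size),
                 partner_chrom = partner_chrom,
                 partner_pos = if (is.null(partner_pos)) NULL
                               else as.integer(partner_pos),
                 n_support = as.integer(n_support)),
            class = "planted_sv")
}

# positive-truncated normal insert draws; redraws negatives so the sample is
# a genuine truncation, deterministic given the RNG state
draw_inserts <- function(n, mean, sd) {
  d <- round(stats::rnorm(n, mean, sd))
  while (any(d < 1)) {
    bad <- d < 1
    d[bad] <- round(stats::rnorm(sum(bad), mean, sd))
  }
  as.integer(d)
}

#' Simulate background (reference-consistent) pairs
#'
#' Leftmost positions uniform over the chromosomes, FR-inward orientation,
#' insert distances N(insert_mean, insert_sd^2) truncated positive, mapping
#' quality `mapq_true`. A `mismap_noise_rate` fraction of pairs then has its
#' mate re-assigned to a uniformly random chromosome, position and strand
#' with `mapq_noise`. Draw order (positions, inserts, noise mask, noise
#' coordinates) is fixed, so streams are reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @param sample_id Sample identifier.
#' @param set_seed Seed the RNG from `cfg$seed` first (default TRUE; scenario
#'   drivers seed once and pass FALSE for subsequent draws).
#' @return A canonical pair table.
#' @export
simulate_background <- function(cfg, sample_id = "sample", set_seed = TRUE) {
  if (set_seed) set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  margin <- as.integer(cfg$insert_mean + 8 * cfg$insert_sd)
  n_per <- pmax(1L, as.integer(round(cfg$chrom_lengths / 1000 *
                                       cfg$pairs_per_kb)))
  chrom <- rep(chroms, n_per)
  n <- length(chrom)
  maxA <- rep(cfg$chrom_lengths - margin, n_per)
  posA <- as.integer(floor(stats::runif(n) * maxA))
  d <- draw_inserts(n, cfg$insert_mean, cfg$insert_sd)
  posB <- posA + d
  strandA <- rep("+", n)
  strandB <- rep("-", n)
  chromB <- chrom
  mapqA <- rep(cfg$mapq_true, n)
  mapqB <- rep(cfg$mapq_true, n)
  noise <- stats::runif(n) < cfg$mismap_noise_rate
  if (any(noise)) {
    k <- sum(noise)
    nc <- chroms[sample.int(length(chroms), k, replace = TRUE)]
    npos <- as.integer(floor(stats::runif(k) * cfg$chrom_lengths[nc]))
    nstr <- c("+", "-")[sample.int(2L, k, replace = TRUE)]
    chromB[noise] <- nc
    posB[noise] <- npos
    strandB[noise] <- nstr
    mapqB[noise] <- cfg$mapq_noise
  }
  pair_records(
    name = sprintf("bg_%07d", seq_len(n)),
    chromA = chrom, posA = posA, strandA = strandA,
    chromB = chromB, posB = posB, strandB = strandB,
    mapqA = mapqA, mapqB = mapqB,
    seqnames = chroms,
    read_group = cfg$read_groups[((seq_len(n) - 1L) %%
                                    length(cfg$read_groups)) + 1L],
    sample_id = sample_id)
}

#' Simulate the supporting pairs of one planted variant
#'
#' Deletions emit same-chromosome FR pairs whose distance is an insert draw
#' plus the deletion size (inside the discordant window for default sizes);
#' inversions emit same-strand pairs straddling the locus; translocations
#' emit pairs with one end at the locus and one at the partner chromosome.
#' Positions are jittered within one bin of the breakpoint. Uses the current
#' RNG state (seed under the caller's control).
#'
#' @param sv A [planted_sv()].
#' @param cfg A [sim_config()].
#' @param sample_id Sample identifier.
#' @param prefix Name prefix for the emitted pairs.
#' @param bin_size Jitter scale in bases (default 1000).
#' @return A canonical pair table of `sv$n_support` rows.
#' @export
simulate_sv_support <- function(sv, cfg, sample_id = "sample",
                                prefix = "sv", bin_size = 1000L) {
  chroms <- names(cfg$chrom_lengths)
  len <- cfg$chrom_lengths[[sv$chrom]]
  if (is.null(len)) stop("planted locus on unknown chromosome: ", sv$chrom)
  n <- sv$n_support
  jitter <- as.integer(floor(stats::runif(n) * bin_size))
  posA <- sv$pos - jitter
  if (any(posA < 0)) stop("planted locus too close to chromosome start")
  if (sv$kind == "deletion") {
    d <- draw_inserts(n, cfg$insert_mean, cfg$insert_sd) + sv$size
    posB <- posA + d
    if (any(posB >= len)) stop("deletion extends past chromosome end")
    chromB <- sv$chrom; strandA <- "+"; strandB <- "-"
  } else if (sv$kind == "inversion") {
    d <- draw_inserts(n, cfg$insert_mean, cfg$insert_sd)
    posB <- posA + d
    if (any(posB >= len)) stop("inversion locus too close to chromosome end")
    chromB <- sv$chrom; strandA <- "+"; strandB <- "+"
  } else {
    plen <- cfg$chrom_lengths[[sv$partner_chrom]]
    if (is.null(plen))
      stop("partner locus on unknown chromosome: ", sv$partner_chrom)
    pj <- as.integer(floor(stats::runif(n) * bin_size))
    posB <- sv$partner_pos - pj
    if (any(posB < 0) || any(posB >= plen))
      stop("partner locus out of chromosome bounds")
    chromB <- sv$partner_chrom; strandA <- "+"; strandB <- "-"
  }
  pair_records(
    name = sprintf("%s_%04d", prefix, seq_len(n)),
    chromA = sv$chrom, posA = posA, strandA = strandA,
    chromB = chromB, posB = posB, strandB = strandB,
    mapqA = cfg$mapq_true, mapqB = cfg$mapq_true,
    seqnames = chroms,
    read_group = cfg$read_groups[1],
    sample_id = sample_id)
}

truth_record <- function(sv) {
  if (sv$kind == "deletion") {
    data.table::data.table(chrom1 = sv$chrom, start1 = sv$pos,
                           end1 = sv$pos + 1L, chrom2 = sv$chrom,
                           start2 = sv$pos + sv$size,
                           end2 = sv$pos + sv$size + 1L,
                           kind = sv$kind, n_support = sv$n_support)
  } else if (sv$kind == "inversion") {
    data.table::data.table(chrom1 = sv$chrom, start1 = sv$pos,
                           end1 = sv$pos + 1L, chrom2 = sv$chrom,
                           start2 = sv$pos, end2 = sv$pos + 1L,
                           kind = sv$kind, n_support = sv$n_support)
  } else {
    data.table::data.table(chrom1 = sv$chrom, start1 = sv$pos,
                           end1 = sv$pos + 1L, chrom2 = sv$partner_chrom,
                           start2 = sv$partner_pos,
                           end2 = sv$partner_pos + 1L,
                           kind = sv$kind, n_support = sv$n_support)
  }
}

#' Truth table of a planted-SV list
#'
#' @param planted List of [planted_sv()] events.
#' @return `data.table` with one row per event (breakpoint loci, kind,
#'   planted support).
#' @export
truth_table <- function(planted) {
  if (!length(planted))
    return(data.table::data.table(chrom1 = character(), start1 = integer(),
                                  end1 = integer(), chrom2 = character(),
                                  start2 = integer(), end2 = integer(),
                                  kind = character(), n_support = integer()))
  data.table::rbindlist(lapply(planted, truth_record))
}

#' Write pair records as a coordinate-sorted SAM file
#'
#' Emits a well-formed SAM file: header with the sequence dictionary and read
#' groups, two records per template with correct flags, mate fields and
#' 1-based positions, placeholder sequence (`SEQ`/`QUAL` `*`, nominal 50M
#' CIGAR). [read_pairs()] on the output reconstructs the input records
#' exactly.
#'
#' @param pairs A canonical pair table.
#' @param path Output SAM path.
#' @param chrom_lengths Named chromosome lengths for the `@SQ` lines.
#' @param sample_id Sample name for the `@RG` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, chrom_lengths, sample_id = "sample") {
  chroms <- names(chrom_lengths)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                   as.integer(chrom_lengths)),
           sprintf("@RG\tID:%s\tSM:%s",
                   sort(unique(pairs$read_group)), sample_id))
  n <- nrow(pairs)
  if (n) {
    flag1 <- 0x1 + 0x40 + ifelse(pairs$strandA == "-", 0x10, 0) +
      ifelse(pairs$strandB == "-", 0x20, 0)
    flag2 <- 0x1 + 0x80 + ifelse(pairs$strandB == "-", 0x10, 0) +
      ifelse(pairs$strandA == "-", 0x20, 0)
    rnext1 <- ifelse(pairs$chromB == pairs$chromA, "=", pairs$chromB)
    rnext2 <- ifelse(pairs$chromA == pairs$chromB, "=", pairs$chromA)
    rec <- data.table::data.table(
      qname = c(pairs$name, pairs$name),
      flag = as.integer(c(flag1, flag2)),
      rname = c(pairs$chromA, pairs$chromB),
      pos = c(pairs$posA, pairs$posB) + 1L,
      mapq = c(pairs$mapqA, pairs$mapqB),
      rnext = c(rnext1, rnext2),
      pnext = c(pairs$posB, pairs$posA) + 1L,
      rg = c(pairs$read_group, pairs$read_group))
    rec[, "..r" := chrom_rank(rec$rname, chroms)]
    data.table::setorderv(rec, c("..r", "pos", "qname", "flag"))
    body <- paste(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq,
                  "50M", rec$rnext, rec$pnext, 0L, "*", "*",
                  paste0("RG:Z:", rec$rg), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a matched tumor/blood sample pair
#'
#' Blood is background only; tumor is background plus the supporting pairs of
#' the planted variants in `cfg_tumor$planted`. When `dir` is given, writes
#' `tumor.sam`, `blood.sam`, the truth BEDPE-style table `truth.tsv` and a
#' `manifest.tsv` consumable by the QA/detect/compare drivers.
#'
#' @param cfg_tumor,cfg_blood [sim_config()] objects sharing a chromosome
#'   dictionary.
#' @param dir Optional output directory.
#' @param patient_id Patient identifier used in sample ids and the manifest.
#' @return List with `tumor`, `blood` (pair tables), `truth`, and `dir`.
#' @export
scenario_matched_pair <- function(cfg_tumor,
                                  cfg_blood = NULL,
                                  dir = NULL,
                                  patient_id = "patient1") {
  if (is.null(cfg_blood)) {
    cfg_blood <- cfg_tumor
    cfg_blood$seed <- cfg_tumor$seed + 1L
    cfg_blood$planted <- list()
  }
  if (!identical(names(cfg_tumor$chrom_lengths),
                 names(cfg_blood$chrom_lengths)))
    stop("tumor and blood configs must share a chromosome dictionary")
  tumor_id <- paste0(patient_id, "_tumor")
  blood_id <- paste0(patient_id, "_blood")
  set.seed(cfg_tumor$seed)
  tumor <- simulate_background(cfg_tumor, tumor_id, set_seed = FALSE)
  sv_streams <- lapply(seq_along(cfg_tumor$planted), function(i)
    simulate_sv_support(cfg_tumor$planted[[i]], cfg_tumor, tumor_id,
                        prefix = sprintf("sv%02d", i)))
  tumor <- data.table::rbindlist(c(list(tumor), sv_streams))
  blood <- simulate_background(cfg_blood, blood_id, set_seed = TRUE)
  truth <- truth_table(cfg_tumor$planted)
  out <- list(tumor = tumor, blood = blood, truth = truth, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sam(tumor, file.path(dir, "tumor.sam"), cfg_tumor$chrom_lengths,
              tumor_id)
    write_sam(blood, file.path(dir, "blood.sam"), cfg_blood$chrom_lengths,
              blood_id)
    data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
    write_manifest(data.table::data.table(
      sample_id = c(tumor_id, blood_id),
      path = file.path(dir, c("tumor.sam", "blood.sam")),
      tissue = c("tumor", "blood"),
      patient_id = patient_id), file.path(dir, "manifest.tsv"))
  }
  out
}

#' Match calls against a planted truth table
#'
#' A truth event is recovered when some call's regionA and regionB overlap
#' the event's two breakpoint bins (in canonical order, with `slack_bins`
#' bins of slack on each side).
#'
#' @param calls A call table.
#' @param truth A [truth_table()].
#' @param seqnames Chromosome order (for canonical orientation of truth).
#' @param bin_size Bin width in bases.
#' @param slack_bins Slack around each breakpoint bin (default 1).
#' @return Logical vector, one per truth row.
#' @export
match_calls_to_truth <- function(calls, truth, seqnames, bin_size = 1000L,
                                 slack_bins = 1L) {
  if (!nrow(truth)) return(logical())
  vapply(seq_len(nrow(truth)), function(i) {
    key <- canonical_2d_key(truth$chrom1[i], bin_index(truth$start1[i],
                                                       bin_size),
                            truth$chrom2[i], bin_index(truth$start2[i],
                                                       bin_size),
                            seqnames)
    if (!nrow(calls)) return(FALSE)
    s <- slack_bins * bin_size
    any(regions_overlap(calls$chromA, calls$startA - s, calls$endA + s,
                        key$chromA, key$binA * bin_size,
                        (key$binA + 1L) * bin_size) &
          regions_overlap(calls$chromB, calls$startB - s, calls$endB + s,
                          key$chromB, key$binB * bin_size,
                          (key$binB + 1L) * bin_size))
  }, TRUE)
}
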