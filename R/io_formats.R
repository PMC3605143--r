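# Input/output boundary: mapped pairs from SAM/BAM, calls as BEDPE,
# diagnostics as tab-separated tables. All writers are deterministic given
# identical inputs (stable sorts, fixed rounding).

#' Read mate pairs from a SAM/BAM file
#'
#' Yields one record per template, built from the first-encountered primary
#' record of each mate. Unmapped, secondary, supplementary and duplicate
#' records are skipped and tallied per reason, as are templates with a missing
#' or inconsistent mate. SAM input is converted to BAM in a temporary file.
#' Positions are converted from SAM's 1-based to 0-based; strand comes from
#' the reverse flag; pairing is by template name, with the mate-reference
#' fields used as a consistency check.
#'
#' @param path SAM or BAM file with a sequence dictionary.
#' @param sample_id Sample identifier attached to every record.
#' @return A pair table (see [pair_records()]) with attributes `seqnames`
#'   (header chromosome order), `seqlengths`, and `skipped` (named tally of
#'   skipped records).
#' @export
read_pairs <- function(path, sample_id = "sample") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!length(hdr)) stop("alignment file has no sequence dictionary: ", path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq",
             "mrnm", "mpos"),
    tag = "RG")
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  rg <- rec$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(rec$qname))

  flag <- rec$flag
  skipped <- c(unmapped = 0L, mate_unmapped = 0L, secondary = 0L,
               supplementary = 0L, duplicate = 0L, unpaired = 0L,
               mate_missing = 0L, inconsistent_mates = 0L)
  reason <- rep(NA_character_, length(flag))
  reason[is.na(reason) & bitwAnd(flag, 0x4) != 0] <- "unmapped"
  reason[is.na(reason) & bitwAnd(flag, 0x100) != 0] <- "secondary"
  reason[is.na(reason) & bitwAnd(flag, 0x800) != 0] <- "supplementary"
  reason[is.na(reason) & bitwAnd(flag, 0x400) != 0] <- "duplicate"
  reason[is.na(reason) & bitwAnd(flag, 0x1) == 0] <- "unpaired"
  reason[is.na(reason) & bitwAnd(flag, 0x8) != 0] <- "mate_unmapped"
  for (r in names(skipped)) skipped[r] <- sum(reason == r, na.rm = TRUE)
  keep <- is.na(reason)

  dt <- data.table::data.table(
    qname = rec$qname[keep],
    first = bitwAnd(flag[keep], 0x40) != 0,
    chrom = as.character(rec$rname[keep]),
    pos = rec$pos[keep],
    strand = as.character(rec$strand[keep]),
    mapq = rec$mapq[keep],
    mchrom = as.character(rec$mrnm[keep]),
    mpos = rec$mpos[keep],
    rg = rg[keep])
  dt$mapq[is.na(dt$mapq)] <- 255L
  # first-encountered primary record of each mate
  dt <- unique(dt, by = c("qname", "first"))
  d1 <- dt[dt$first, ]
  d2 <- dt[!dt$first, ]
  m <- merge(d1, d2, by = "qname", suffixes = c("1", "2"))
  lone <- nrow(d1) + nrow(d2) - 2L * nrow(m)
  skipped["mate_missing"] <- skipped["mate_missing"] + lone
  consistent <- m$mchrom1 == m$chrom2 & m$mpos1 == m$pos2 &
    m$mchrom2 == m$chrom1 & m$mpos2 == m$pos1
  consistent[is.na(consistent)] <- FALSE
  skipped["inconsistent_mates"] <- sum(!consistent)
  m <- m[consistent, ]
  pairs <- pair_records(
    name = m$qname,
    chromA = m$chrom1, posA = m$pos1 - 1L, strandA = m$strand1,
    chromB = m$chrom2, posB = m$pos2 - 1L, strandB = m$strand2,
    mapqA = m$mapq1, mapqB = m$mapq2,
    seqnames = names(hdr),
    read_group = ifelse(is.na(m$rg1), m$rg2, m$rg1),
    sample_id = sample_id)
  r <- chrom_rank(pairs$chromA, names(hdr))
  data.table::setorderv(pairs[, "..r" := r], c("..r", "posA", "name"))
  pairs[, "..r" := NULL]
  data.table::setattr(pairs, "seqnames", names(hdr))
  data.table::setattr(pairs, "seqlengths", unname(hdr))
  data.table::setattr(pairs, "skipped", skipped)
  pairs
}

bedpe_header <- paste("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score", "strand1", "strand2", "class",
                      "n_support", "support_fraction", sep = "\t")

#' Write SV calls as BEDPE
#'
#' Standard ten BEDPE columns plus `class`, `n_support` and
#' `support_fraction`. Coordinates are 0-based half-open and bin-aligned;
#' rows are sorted by (chrom1, start1, chrom2, start2); the score column is
#' the probabilistic mapping-quality score rounded to 4 decimals. Strand
#' columns are `"."` (calls are bin-level features without strand).
#'
#' @param calls A call table from [call_svs()] (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(bedpe_header, con)
  if (!is.null(calls) && nrow(calls)) {
    calls <- data.table::as.data.table(calls)
    data.table::setorderv(calls, c("chromA", "startA", "chromB", "startB"))
    writeLines(paste(
      calls$chromA, calls$startA, calls$endA,
      calls$chromB, calls$startB, calls$endB,
      sprintf("sv_%d", seq_len(nrow(calls))),
      sprintf("%.4f", calls$score),
      ".", ".",
      calls$sv_class, calls$n_support,
      sprintf("%.6f", calls$support_fraction), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' @param path BEDPE path.
#' @param sample_id Sample identifier to attach.
#' @return A call table (zero rows for a header-only file).
#' @export
read_bedpe <- function(path, sample_id = "sample") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.table::data.table(
    chromA = character(), startA = integer(), endA = integer(),
    chromB = character(), startB = integer(), endB = integer(),
    name = character(), score = numeric(), sv_class = character(),
    n_support = integer(), support_fraction = numeric(),
    sample_id = character())
  if (!length(lines)) return(empty)
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.table::data.table(
    chromA = m[, 1], startA = as.integer(m[, 2]), endA = as.integer(m[, 3]),
    chromB = m[, 4], startB = as.integer(m[, 5]), endB = as.integer(m[, 6]),
    name = m[, 7], score = as.numeric(m[, 8]), sv_class = m[, 11],
    n_support = as.integer(m[, 12]), support_fraction = as.numeric(m[, 13]),
    sample_id = sample_id)
}

#' Write a kernel-density table of insert distances
#'
#' Two-column tab-separated table (grid point, density estimate) of the
#' Gaussian-kernel density (Silverman bandwidth) of intrachromosomal pair
#' distances, suitable for external plotting; the grid covers
#' `[0, max(distances)]`.
#'
#' @param distances Numeric vector of same-chromosome pair distances.
#' @param path Output path.
#' @param n Number of grid points (default 512).
#' @return `path`, invisibly.
#' @export
write_density_table <- function(distances, path, n = 512L) {
  if (!length(distances)) stop("no intrachromosomal pairs")
  den <- stats::density(distances, bw = "nrd0", from = 0, to = max(distances),
                        n = n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("distance\tdensity", con)
  writeLines(paste(format(den$x, trim = TRUE, scientific = FALSE),
                   format(den$y, trim = TRUE, digits = 10), sep = "\t"), con)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' Tab-separated table with columns `sample_id`, `path`, `tissue`
#' (tumor / blood / unknown) and `patient_id`; matched tumor/blood samples
#' from the same patient share `patient_id`.
#'
#' @param path Manifest path.
#' @return A `data.table`.
#' @export
read_manifest <- function(path) {
  man <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("sample_id", "path", "tissue", "patient_id")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$sample_id)) stop("duplicate sample_id in manifest")
  man
}

#' @rdname read_manifest
#' @param manifest A manifest `data.table`.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t")
  invisible(path)
}
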