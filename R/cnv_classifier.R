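# Printed microarray calling thresholds: gains at log2 ratio >= 0.58,
# losses at <= -1, both with >= 50 consecutive probes, and a minimum size
# of 500 kb for gains and 200 kb for losses.
CNV_GAIN_LOG2 <- 0.58
CNV_LOSS_LOG2 <- -1
CNV_MIN_PROBES <- 50L
CNV_MIN_GAIN_BP <- 500000L
CNV_MIN_LOSS_BP <- 200000L

#' Validate a table of pre-segmented CNV calls
#'
#' Segments come from array segmentation (columns `sample_id`, `chrom`,
#' `start`, `end` in 1-based inclusive coordinates, `mean_log2`,
#' `n_probes`); segment length is `end - start + 1`.
#'
#' @param segs Data.frame of segments.
#' @return The validated data.frame with a `length` column added.
#' @export
cnv_segments <- function(segs) {
  required <- c("chrom", "start", "end", "mean_log2", "n_probes")
  missing <- setdiff(required, names(segs))
  if (length(missing) > 0L)
    stop("segment table lacks columns: ", paste(missing, collapse = ", "))
  if (!"sample_id" %in% names(segs)) segs$sample_id <- NA_character_
  if (nrow(segs) > 0L) {
    if (any(!is.finite(segs$mean_log2)))
      stop("mean_log2 must be finite for every segment")
    if (any(segs$start > segs$end)) stop("segments must satisfy start <= end")
    if (any(segs$n_probes < 1L)) stop("n_probes must be >= 1")
  }
  segs$length <- segs$end - segs$start + 1L
  segs
}

#' Copy-number state from the mean log2 ratio
#'
#' Gain when `mean_log2 >= 0.58`, loss when `mean_log2 <= -1`, neutral
#' otherwise; both boundaries inclusive. The three states partition the
#' real line.
#'
#' @param mean_log2 Numeric vector of segment mean log2 ratios.
#' @param gain_log2,loss_log2 State thresholds.
#' @return Character vector in `c("gain", "loss", "neutral")`.
#' @export
classify_state <- function(mean_log2, gain_log2 = CNV_GAIN_LOG2,
                           loss_log2 = CNV_LOSS_LOG2) {
  if (any(!is.finite(mean_log2))) stop("mean_log2 must be finite")
  ifelse(mean_log2 >= gain_log2, "gain",
         ifelse(mean_log2 <= loss_log2, "loss", "neutral"))
}

#' Probe-count and size noise filters
#'
#' Guards against microarray noise: a gain must span at least 50
#' consecutive probes and 500 kb; a loss at least 50 probes and 200 kb
#' (all bounds inclusive). Neutral segments never pass.
#'
#' @param state Character vector of states from [classify_state()].
#' @param length Segment lengths in bp (1-based inclusive arithmetic).
#' @param n_probes Probe counts.
#' @param min_probes,min_gain_bp,min_loss_bp Filter thresholds.
#' @return Logical vector.
#' @export
passes_size_probe_filters <- function(state, length, n_probes,
                                      min_probes = CNV_MIN_PROBES,
                                      min_gain_bp = CNV_MIN_GAIN_BP,
                                      min_loss_bp = CNV_MIN_LOSS_BP) {
  ifelse(state == "gain", n_probes >= min_probes & length >= min_gain_bp,
  ifelse(state == "loss", n_probes >= min_probes & length >= min_loss_bp,
         FALSE))
}

segments_granges <- function(segs) {
  GenomicRanges::GRanges(segs$chrom,
                         IRanges::IRanges(segs$start, segs$end))
}

# For each query segment: does any same-state track interval overlap it
# reciprocally by at least min_reciprocal of both lengths?
reciprocal_hits <- function(segs, track, min_reciprocal) {
  out <- rep(FALSE, nrow(segs))
  if (is.null(track) || nrow(track) == 0L || nrow(segs) == 0L) return(out)
  q <- segments_granges(segs)
  s <- segments_granges(track)
  # disjoint chromosome sets between query and track are legitimate
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(q[qi], s[si]))
  rec <- ov / GenomicRanges::width(q)[qi] >= min_reciprocal &
         ov / GenomicRanges::width(s)[si] >= min_reciprocal
  same_state <- segs$state[qi] == track$state[si]
  hit_rows <- unique(qi[rec & same_state])
  out[hit_rows] <- TRUE
  out
}

#' Match segments against a benign-CNV track
#'
#' A segment is considered a common benign CNV when some interval of the
#' same state (gain/loss) in the benign track (a population CNV catalogue
#' or normal-individual in-house track) overlaps it with reciprocal
#' overlap of at least `min_reciprocal` (default 0.5, the community
#' convention; configurable since no canonical fraction exists).
#'
#' @param segs Segment table carrying a `state` column.
#' @param benign_track Data.frame with `chrom`, `start`, `end`, `state`.
#' @param min_reciprocal Minimum reciprocal-overlap fraction.
#' @return Logical vector, one per segment.
#' @export
benign_overlap <- function(segs, benign_track, min_reciprocal = 0.5) {
  segs <- as.data.frame(segs)
  if (!"state" %in% names(segs)) stop("segments need a 'state' column")
  if (!is.null(benign_track) && nrow(benign_track) > 0L &&
      (any(benign_track$start > benign_track$end)))
    stop("malformed benign track interval (start > end)")
  reciprocal_hits(segs, benign_track, min_reciprocal)
}

#' De novo status and pathogenicity call
#'
#' A filtered, non-benign gain or loss is classified pathogenic if and only
#' if it is de novo: found in neither parent. With parental data missing,
#' inheritance is `unknown` and the segment stays `not_classified` (the
#' possibility of incompletely penetrant pathogenic CNVs in a parent is a
#' reporting caveat, not encoded in the call).
#'
#' @param calls Data.frame with `state`, `passes_filters`, `benign_overlap`
#'   columns (e.g. from [classify_cnvs()] internals).
#' @param in_mother,in_father Logical vectors (NA = parent not tested).
#' @return `calls` with `inheritance` and `classification` columns.
#' @export
call_pathogenic <- function(calls, in_mother, in_father) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  in_mother <- rep_len(in_mother, n)
  in_father <- rep_len(in_father, n)
  inheritance <- ifelse(is.na(in_mother) | is.na(in_father), "unknown",
                 ifelse(in_mother | in_father, "inherited", "de_novo"))
  calls$inheritance <- inheritance
  calls$classification <- ifelse(
    calls$state != "neutral" & calls$passes_filters & !calls$benign_overlap &
      inheritance == "de_novo",
    "pathogenic", "not_classified")
  calls
}

#' Classify CNV segments end to end
#'
#' Assigns the copy-number state from the log2 ratio, applies the
#' probe-count/size noise filters, matches against a benign track, derives
#' de novo status from parental segment tables (a variant counts as present
#' in a parent under the same reciprocal-overlap rule used for benign
#' matching), and calls pathogenicity.
#'
#' @param segs Segment table (see [cnv_segments()]).
#' @param benign_track Optional benign CNV track (`chrom`, `start`, `end`,
#'   `state`).
#' @param mother,father Optional parental segment tables with the same
#'   columns as `segs`; `NULL` means the parent was not tested.
#' @param min_reciprocal Reciprocal-overlap fraction for benign and
#'   parental matching.
#' @return Data.frame of calls: the segment columns plus `state`,
#'   `passes_filters`, `benign_overlap`, `inheritance`, `classification`.
#' @examples
#' segs <- data.frame(sample_id = "s1", chrom = "2", start = 1e6,
#'                    end = 1e6 + 6e5, mean_log2 = 0.8, n_probes = 60)
#' classify_cnvs(segs)  # no parents -> inheritance unknown
#' @export
classify_cnvs <- function(segs, benign_track = NULL, mother = NULL,
                          father = NULL, min_reciprocal = 0.5) {
  segs <- cnv_segments(segs)
  segs$state <- classify_state(segs$mean_log2)
  segs$passes_filters <- passes_size_probe_filters(segs$state, segs$length,
                                                   segs$n_probes)
  segs$benign_overlap <- benign_overlap(segs, benign_track, min_reciprocal)
  parent_presence <- function(parent) {
    if (is.null(parent)) return(rep(NA, nrow(segs)))
    parent <- cnv_segments(parent)
    parent$state <- classify_state(parent$mean_log2)
    reciprocal_hits(segs, parent, min_reciprocal)
  }
  call_pathogenic(segs, parent_presence(mother), parent_presence(father))
}
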