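#' Normalize a raw probe table to Cy5/Cy3 ratios
#'
#' The bound-fraction channel is divided by the reference-library channel
#' probe-wise. Zero or near-zero reference intensities are floored at
#' `floor_frac` times the median positive Cy3 so degenerate probes yield a
#' finite (large) ratio instead of a division blowup.
#'
#' @param track Data.frame with columns `probe_start`, `cy5`, `cy3`,
#'   strictly increasing in `probe_start`.
#' @param floor_frac Floor for Cy3 as a fraction of its median.
#' @return The track with an added `ratio` column; input attributes
#'   (`probe_interval`, `probe_length`, `genome_length`) are preserved.
#' @export
normalize_ratio <- function(track, floor_frac = 1e-6) {
  if (is.null(track) || nrow(track) == 0L) stop("empty probe track")
  stopifnot(all(c("probe_start", "cy5", "cy3") %in% names(track)))
  if (is.unsorted(track$probe_start, strictly = TRUE))
    stop("probes must be strictly increasing in position")
  med <- stats::median(track$cy3[track$cy3 > 0])
  if (!is.finite(med)) med <- 1
  fl <- max(floor_frac * med, .Machine$double.xmin)
  out <- track
  out$ratio <- track$cy5 / pmax(track$cy3, fl)
  for (a in c("probe_interval", "probe_length", "genome_length"))
    attr(out, a) <- attr(track, a)
  out
}

#' Call holoenzyme-binding peaks from a normalized probe track
#'
#' Two criteria define a peak, mirroring the selection-library fragment
#' size relative to the probe spacing: (1) a probe ratio of at least
#' `cutoff_frac` of the genome-wide maximum ratio, and (2) at least
#' `min_probes` consecutive probes above that threshold (a ~300-bp bound
#' fragment must cover two or more 105-bp-spaced probes; isolated
#' single-probe signals are treated as noise). Maximal qualifying runs
#' become peaks spanning from the first probe start to the last probe
#' start plus the probe length. Adjacent runs separated by a sub-threshold
#' probe are not merged. On a circular track, a run crossing the origin is
#' stitched.
#'
#' @param track Normalized track from [normalize_ratio()] (must carry a
#'   `ratio` column).
#' @param cutoff_frac Relative-height cutoff (default 0.02, i.e. 2% of the
#'   highest peak).
#' @param min_probes Minimum consecutive above-threshold probes (default 2).
#' @param probe_length Probe length used to extend the peak's right edge;
#'   taken from the track attribute when present.
#' @param circular Stitch runs across the origin; taken from `track`
#'   attribute `circular` if present.
#' @return A data.frame of peaks: `start`, `end`, `summit`, `height`,
#'   `rel_height`, `n_probes`, ordered by `start`.
#' @export
call_peaks <- function(track, cutoff_frac = 0.02, min_probes = 2L,
                       probe_length = NULL, circular = FALSE) {
  if (!"ratio" %in% names(track))
    stop("track is not normalized; run normalize_ratio() first")
  if (is.null(probe_length))
    probe_length <- attr(track, "probe_length") %||% 60L
  if (!missing(circular)) circular <- isTRUE(circular)
  else circular <- isTRUE(attr(track, "circular"))

  empty <- data.frame(start = integer(), end = integer(), summit = integer(),
                      height = numeric(), rel_height = numeric(),
                      n_probes = integer())
  gmax <- max(track$ratio)
  if (!is.finite(gmax) || gmax <= 0) {
    warning("no signal above zero; no peaks definable")
    return(empty)
  }
  thr <- cutoff_frac * gmax
  above <- track$ratio >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values],
                     len = r$lengths[r$values])

  # Run indices, each a vector of track rows. On a circular track the run
  # touching the right edge is stitched onto the run at the left edge; the
  # stitched peak keeps the tail run's start and an end that wraps modulo
  # the genome.
  run_idx <- lapply(seq_len(nrow(runs)),
                    function(i) seq.int(runs$first[i], runs$last[i]))
  wrap_tail <- NULL
  n_runs <- length(run_idx)
  if (circular && n_runs >= 2L && above[1L] && above[length(above)]) {
    wrap_tail <- run_idx[[n_runs]]
    run_idx[[1L]] <- c(wrap_tail, run_idx[[1L]])
    run_idx <- run_idx[-n_runs]
  }
  run_idx <- run_idx[lengths(run_idx) >= min_probes]
  if (length(run_idx) == 0L) return(empty)

  gl <- attr(track, "genome_length") %||%
    (track$probe_start[nrow(track)] + probe_length)
  out <- lapply(run_idx, function(idx) {
    h <- track$ratio[idx]
    s_i <- idx[which.max(h)]          # first occurrence wins ties
    wrapped <- is.unsorted(idx)       # stitched origin-crossing run
    start <- track$probe_start[idx[1L]]
    end <- track$probe_start[idx[length(idx)]] + probe_length
    if (wrapped) end <- end %% gl
    data.frame(start = start, end = end,
               summit = track$probe_start[s_i],
               height = track$ratio[s_i],
               rel_height = track$ratio[s_i] / gmax,
               n_probes = length(idx))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank peaks by relative height
#'
#' Stable sort, descending in `rel_height`; ties keep genome order.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @return The peaks reordered, with a `rank` column added.
#' @export
rank_peaks <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) stop("empty peak list")
  o <- order(-peaks$rel_height, peaks$start)
  out <- peaks[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read and write probe tables and peak files
#'
#' Probe tables are TSV with columns `probe_start`, `cy5`, `cy3`; peaks are
#' written both as BED6 (name = rank, score = `round(1000 * rel_height)`)
#' and, via [utils::write.table()], as a full TSV.
#'
#' @param path File path.
#' @return `read_probe_tsv` returns the probe data.frame.
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("probe_start", "cy5", "cy3") %in% names(df)))
  df
}

#' @rdname read_probe_tsv
#' @param track Probe data.frame.
#' @export
write_probe_tsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_probe_tsv
#' @param peaks Ranked peak data.frame (see [rank_peaks()]).
#' @param genome_name Sequence name for the BED chrom field.
#' @export
write_peaks_bed <- function(peaks, path, genome_name = "genome") {
  if (!"rank" %in% names(peaks)) peaks <- rank_peaks(peaks)
  gr <- GenomicRanges::GRanges(
    seqnames = genome_name,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    name = as.character(peaks$rank),
    score = round(1000 * peaks$rel_height))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
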