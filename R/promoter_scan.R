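#' @keywords internal
"_PACKAGE"

CONSENSUS_35 <- "TTGACA"
CONSENSUS_10 <- "TATAAT"

# Spacer-length bonus: +3 at the optimal 17 bp, +2 at 16/18, +1 at 15/19,
# 0 outside the 17 +/- 2 window.
SPACER_SCORES <- c(`15` = 1L, `16` = 2L, `17` = 3L, `18` = 2L, `19` = 1L)

#' Scoring scheme for the consensus-hexamer promoter scan
#'
#' The scan scores a candidate promoter as the number of bases matching the
#' -35 consensus `TTGACA`, plus the number matching the -10 consensus
#' `TATAAT` (one point per identical base, no gaps), plus a spacer-length
#' bonus of +3/+2/+1 for spacers of 17/16,18/15,19 bp. The maximum total is
#' therefore 15 (6 + 6 + 3). Candidates are retained when both boxes reach
#' `min_box_match` matches and the two box scores sum to at least
#' `min_box_sum`; `strict = TRUE` switches both comparisons to strict
#' inequalities.
#'
#' @param min_box_match Per-box match threshold (default 4 of 6).
#' @param min_box_sum Combined box-score threshold (default 8 of 12).
#' @param strict Use strict (`>`) instead of inclusive (`>=`) thresholds.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(min_box_match = 4L, min_box_sum = 8L,
                           strict = FALSE) {
  stopifnot(min_box_match >= 0, min_box_match <= 6,
            min_box_sum >= 0, min_box_sum <= 12)
  structure(list(consensus35 = CONSENSUS_35, consensus10 = CONSENSUS_10,
                 spacer_scores = SPACER_SCORES,
                 min_box_match = as.integer(min_box_match),
                 min_box_sum = as.integer(min_box_sum),
                 strict = isTRUE(strict)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cmp <- if (x$strict) ">" else ">="
  cat(sprintf("<scoring_scheme> -35 %s / -10 %s; spacer bonus 15:1 16:2 17:3 18:2 19:1\n",
              x$consensus35, x$consensus10))
  cat(sprintf("  retain: m35 %s %d AND m10 %s %d AND m35+m10 %s %d\n",
              cmp, x$min_box_match, cmp, x$min_box_match, cmp, x$min_box_sum))
  invisible(x)
}

#' Count matches between a hexamer and a consensus hexamer
#'
#' One point per identical base, zero per mismatch, no gaps; `N` never
#' matches.
#'
#' @param seq6 Hexamer to score.
#' @param consensus Consensus hexamer.
#' @return Integer match count, 0-6.
#' @examples
#' hexamer_match("TTAACG", "TTGACA")  # 4
#' @export
hexamer_match <- function(seq6, consensus) {
  seq6 <- toupper(seq6); consensus <- toupper(consensus)
  if (nchar(seq6) != 6L || nchar(consensus) != 6L)
    stop("hexamer_match requires two length-6 sequences")
  a <- strsplit(seq6, "")[[1L]]
  b <- strsplit(consensus, "")[[1L]]
  sum(a == b & a != "N")
}

#' Spacer-length bonus score
#'
#' @param length Spacer length in bp.
#' @return Integer score: 3 at 17 bp, 2 at 16/18, 1 at 15/19, else 0.
#' @examples
#' spacer_length_score(17)
#' @export
spacer_length_score <- function(length) {
  stopifnot(all(length >= 0))
  out <- SPACER_SCORES[as.character(length)]
  out[is.na(out)] <- 0L
  as.integer(unname(out))
}

# Per-position match-count profile: m[i] = matches of the hexamer starting
# at 1-based index i against the consensus. Vectorized over the sequence.
match_profile <- function(chars, consensus) {
  L <- length(chars)
  if (L < 6L) return(integer(0))
  cvec <- strsplit(consensus, "")[[1L]]
  m <- integer(L - 5L)
  for (j in 1:6) {
    sl <- chars[j:(L - 6L + j)]
    m <- m + as.integer(sl == cvec[j] & sl != "N")
  }
  m
}

scan_one_strand <- function(seq, scheme) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  hits <- vector("list", 5L)
  m35 <- match_profile(chars, scheme$consensus35)
  m10 <- match_profile(chars, scheme$consensus10)
  pass <- if (scheme$strict) {
    function(a, b) a > scheme$min_box_match & b > scheme$min_box_match &
      a + b > scheme$min_box_sum
  } else {
    function(a, b) a >= scheme$min_box_match & b >= scheme$min_box_match &
      a + b >= scheme$min_box_sum
  }
  k <- 0L
  for (sp in 15:19) {
    # -10 box starts 6 + sp after the -35 box start (0-based offsets)
    n <- L - (12L + sp) + 1L
    if (n < 1L) next
    i35 <- seq_len(n)                 # 1-based -35 start
    i10 <- i35 + 6L + sp
    ok <- pass(m35[i35], m10[i10])
    if (!any(ok)) next
    i35 <- i35[ok]; i10 <- i10[ok]
    k <- k + 1L
    hits[[k]] <- data.frame(
      pos35 = i35 - 1L,
      seq35 = substring(seq, i35, i35 + 5L),
      spacer_len = sp,
      seq10 = substring(seq, i10, i10 + 5L),
      m35 = m35[i35], m10 = m10[i10],
      stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(pos35 = integer(), seq35 = character(),
                      spacer_len = integer(), seq10 = character(),
                      m35 = integer(), m10 = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits[seq_len(k)])
}

#' Scan a sequence for consensus promoter hits on one or both strands
#'
#' Enumerates every (-35 start, spacer length in 15..19) pair by sliding
#' 1 bp, scores both hexamers against the consensus, and retains candidates
#' passing the scheme's thresholds. Minus-strand hits are found by scanning
#' the reverse complement and reported in forward coordinates with strand
#' `"-"`: `pos35` is always the 0-based forward-strand start of the
#' -35 hexamer's interval.
#'
#' @param seq Character scalar or [genome_seq].
#' @param scheme A [scoring_scheme()].
#' @param strand_mode `"both"` or `"forward"`.
#' @return A data.frame of promoter hits: `strand`, `pos35`, `seq35`
#'   (as read on the promoter strand), `spacer_len`, `seq10`, `m35`, `m10`,
#'   `spacer_score`, `total`, ordered by `pos35`.
#' @examples
#' scan_sequence(paste0(strrep("C", 10), "TTGACA", strrep("G", 17),
#'                      "TATAAT", strrep("C", 10)))
#' @export
scan_sequence <- function(seq, scheme = scoring_scheme(),
                          strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(seq, "genome_seq")) seq <- seq$seq
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence restricted to alphabet {A,C,G,T,N}")
  L <- nchar(seq)

  fwd <- scan_one_strand(seq, scheme)
  fwd$strand <- rep("+", nrow(fwd))
  if (strand_mode == "both" && L >= 27L) {
    rev <- scan_one_strand(revcomp(seq), scheme)
    if (nrow(rev)) {
      rev$pos35 <- L - rev$pos35 - 6L   # mirror to forward coordinates
      rev$strand <- "-"
    } else rev$strand <- character(0)
    hits <- rbind(fwd, rev)
  } else hits <- fwd

  hits$spacer_score <- spacer_length_score(hits$spacer_len)
  hits$total <- hits$m35 + hits$m10 + hits$spacer_score
  hits <- hits[order(hits$pos35, hits$strand, hits$spacer_len), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("strand", "pos35", "seq35", "spacer_len", "seq10",
           "m35", "m10", "spacer_score", "total")]
}

#' Scan extended spacer regions of a genome
#'
#' Each region is widened by `flank` bp into the flanking genes before
#' scanning, so -35 boxes abutting a gene start are not lost; reported
#' coordinates stay genome-wide.
#'
#' @param genome A [genome_seq].
#' @param regions Data.frame with `start`, `end` (0-based half-open).
#' @param scheme A [scoring_scheme()].
#' @param flank Extension into each flank, bp.
#' @return A data.frame of hits as in [scan_sequence()], with an added
#'   `region` column (row index into `regions`).
#' @export
scan_regions <- function(genome, regions, scheme = scoring_scheme(),
                         flank = 20L) {
  stopifnot(inherits(genome, "genome_seq"))
  out <- vector("list", nrow(regions))
  L <- genome_length(genome)
  for (i in seq_len(nrow(regions))) {
    s <- max(0L, regions$start[i] - flank)
    e <- min(L, regions$end[i] + flank)
    h <- scan_sequence(genome_subseq(genome, s, e), scheme)
    if (nrow(h)) {
      h$pos35 <- h$pos35 + s
      h$region <- i
      out[[i]] <- h
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    h <- scan_sequence(strrep("A", 30), scheme)[0, ]
    h$region <- integer(0)
    return(h)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the best-scoring hit of a region
#'
#' Ties on total score are broken by (1) spacer length closest to 17 bp,
#' (2) larger -10 match count, (3) smaller position.
#'
#' @param hits Data.frame of promoter hits from [scan_sequence()].
#' @return A one-row data.frame, or `NULL` for an empty input.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$total, abs(hits$spacer_len - 17L), -hits$m10, hits$pos35)
  hits[o[1L], , drop = FALSE]
}

#' Score a promoter written in compact `HEXAMER-N-HEXAMER` notation
#'
#' The notation used in the result tables, e.g. `"TTGACA-17-TATAAT"`,
#' gives the -35 box, the spacer length and the -10 box; the total score is
#' the two hexamer match counts plus the spacer bonus.
#'
#' @param compact Character scalar, e.g. `"TTGACA-17-TATAAT"`.
#' @return Integer total score, 0-15.
#' @examples
#' score_promoter_string("TTGACA-17-TATAAT")  # 15
#' @export
score_promoter_string <- function(compact) {
  m <- regmatches(compact,
                  regexec("^([ACGTNacgtn]{6})-([0-9]+)-([ACGTNacgtn]{6})$",
                          compact))[[1L]]
  if (length(m) != 4L)
    stop("malformed promoter string: ", compact,
         " (expected HEXAMER-N-HEXAMER)")
  hexamer_match(m[2L], CONSENSUS_35) + hexamer_match(m[4L], CONSENSUS_10) +
    spacer_length_score(as.integer(m[3L]))
}
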