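#' Conservation cross-tabulation of promoter hits
#'
#' Bins the -35 and -10 match counts of each promoter into
#' `{6, 5, 4, <=3}` and cross-tabulates them. The headline aggregate is
#' the fraction of promoters with at least 4/6 agreement in both boxes —
#' the "high-level conservation" statistic (e.g. 316 of 354 divergent-
#' spacer promoters, 89%).
#'
#' @param hits Data.frame with `m35` and `m10` columns (promoter hits), or
#'   two integer vectors via `m35`/`m10`.
#' @param m35,m10 Optional vectors overriding `hits`.
#' @return List with `counts` (4x4 matrix, rows = -35 bin, cols = -10
#'   bin), `n`, `aggregate_count` (both boxes >= 4) and `aggregate_pct`
#'   (round-half-up integer percent).
#' @export
conservation_crosstab <- function(hits = NULL, m35 = NULL, m10 = NULL) {
  if (is.null(m35) || is.null(m10)) {
    stopifnot(!is.null(hits), all(c("m35", "m10") %in% names(hits)))
    m35 <- hits$m35; m10 <- hits$m10
  }
  if (length(m35) == 0L) stop("no promoters to tabulate")
  stopifnot(length(m35) == length(m10),
            all(m35 >= 0 & m35 <= 6), all(m10 >= 0 & m10 <= 6))
  bins <- c("6", "5", "4", "<=3")
  bin_of <- function(m) factor(ifelse(m >= 4, as.character(m), "<=3"),
                               levels = bins)
  counts <- table(m35 = bin_of(m35), m10 = bin_of(m10))
  agg <- sum(m35 >= 4 & m10 >= 4)
  list(counts = unclass(counts), n = length(m35), aggregate_count = agg,
       aggregate_pct = round_half_up(100 * agg / length(m35)))
}

#' Pooled percentage across promoter groups
#'
#' Sums numerators and denominators before dividing, so groups are
#' weighted by size (e.g. (316 + 226) / (354 + 276) = 86%).
#'
#' @param part_counts,whole_counts Parallel numeric vectors.
#' @return Round-half-up integer percentage.
#' @examples
#' pooled_fraction(c(316, 226), c(354, 276))  # 86
#' @export
pooled_fraction <- function(part_counts, whole_counts) {
  stopifnot(length(part_counts) == length(whole_counts))
  tot <- sum(whole_counts)
  if (tot == 0) stop("zero pooled denominator")
  round_half_up(100 * sum(part_counts) / tot)
}

#' Per-position base frequencies and information content of aligned hexamers
#'
#' Computes, for each of the six positions of an alignment of promoter
#' boxes, the base frequencies over `{A,C,G,T}` (N excluded per position)
#' and the Shannon information content `R(i) = 2 - H(i)` in bits, with
#' `H(i) = -sum f log2 f` — the quantity drawn as total letter height in a
#' sequence logo. Uniform background, no small-sample correction.
#'
#' @param aligned_hexamers Character vector of length-6 sequences.
#' @return Object of class `logo_matrix`: list with `freq` (4x6 matrix,
#'   rows A,C,G,T) and `info` (length-6 numeric, bits).
#' @examples
#' position_information(rep("TATAAT", 10))$info  # 2 bits everywhere
#' @export
position_information <- function(aligned_hexamers) {
  if (length(aligned_hexamers) == 0L) stop("empty alignment")
  if (any(nchar(aligned_hexamers) != 6L))
    stop("all sequences must have length 6")
  mat <- do.call(rbind, strsplit(toupper(aligned_hexamers), ""))
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(6L), function(i) {
    col <- mat[, i]
    col <- col[col %in% bases]
    if (!length(col)) return(rep(NA_real_, 4L))
    as.numeric(table(factor(col, levels = bases))) / length(col)
  }, numeric(4L))
  rownames(freq) <- bases
  info <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 - sum(-f * log2(f))
  })
  structure(list(freq = freq, info = as.numeric(info)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix> information content (bits) per position:\n")
  print(round(x$info, 3))
  invisible(x)
}

#' Does a spacer overlap any silencer binding site?
#'
#' Half-open interval overlap: at least 1 bp shared; abutting intervals do
#' not overlap.
#'
#' @param spacer_start,spacer_end Spacer interval (0-based half-open).
#' @param hns_sites Data.frame of silencer intervals (`start`, `end`).
#' @return Logical scalar.
#' @export
has_hns_overlap <- function(spacer_start, spacer_end, hns_sites) {
  if (is.null(hns_sites) || nrow(hns_sites) == 0L) return(FALSE)
  any(hns_sites$start < spacer_end & hns_sites$end > spacer_start)
}

#' Annotate a spacer table with silencer overlap
#'
#' @param spacers Spacer data.frame (`start`, `end`).
#' @param hns_sites Silencer interval data.frame.
#' @return The spacers with a logical `has_hns` column.
#' @export
annotate_hns <- function(spacers, hns_sites) {
  spacers$has_hns <- vapply(seq_len(nrow(spacers)), function(i)
    has_hns_overlap(spacers$start[i], spacers$end[i], hns_sites), logical(1L))
  spacers
}

#' Promoters potentially silenced by H-NS
#'
#' H-NS spreads cooperatively from its nucleation site, so a single bound
#' site inside a divergent (type-A) spacer can silence both of its
#' promoters; a codirectional (type-B) spacer contributes one. The count
#' is therefore `2 x (#type-A with H-NS) + (#type-B with H-NS)`, reported
#' with its fraction of the maximum constitutive-promoter bound.
#'
#' @param spacers Spacer data.frame with `type` and `has_hns` columns, or
#'   direct counts via `n_a_hns`/`n_b_hns`.
#' @param max_count Maximum constitutive-promoter bound (see
#'   [count_constitutive_bounds()]).
#' @param n_a_hns,n_b_hns Optional direct counts overriding `spacers`.
#' @return List with `count` and `pct` (round-half-up integer percent of
#'   `max_count`).
#' @examples
#' hns_silencing_count(n_a_hns = 63, n_b_hns = 77, max_count = 669)
#' @export
hns_silencing_count <- function(spacers = NULL, max_count,
                                n_a_hns = NULL, n_b_hns = NULL) {
  if (is.null(n_a_hns) || is.null(n_b_hns)) {
    stopifnot(!is.null(spacers), all(c("type", "has_hns") %in% names(spacers)))
    n_a_hns <- sum(spacers$type == "A" & spacers$has_hns)
    n_b_hns <- sum(spacers$type == "B" & spacers$has_hns)
  }
  if (max_count <= 0) stop("max_count must be positive")
  count <- 2L * n_a_hns + n_b_hns
  list(count = as.integer(count),
       pct = round_half_up(100 * count / max_count))
}

#' Essential genes under the control of constitutive promoters
#'
#' @param controlled_genes Character vector of gene identifiers under
#'   constitutive-promoter control.
#' @param essential_list Character vector of essential gene identifiers.
#' @return List with `count` (size of the intersection) and `pct`
#'   (round-half-up integer percent of the essential list).
#' @examples
#' essential_coverage(paste0("g", 1:70), paste0("g", 1:302))
#' @export
essential_coverage <- function(controlled_genes, essential_list) {
  if (length(essential_list) == 0L) stop("empty essential-gene list")
  n <- length(intersect(unique(controlled_genes), unique(essential_list)))
  list(count = n, pct = round_half_up(100 * n / length(unique(essential_list))))
}

#' Read an essential-gene list (one identifier per line)
#'
#' @param path Text file.
#' @return Character vector.
#' @export
read_essential_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
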