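#' Read gene annotation from GFF3
#'
#' Keeps features of type `gene`. Coordinates are converted from GFF3's
#' 1-based closed convention to the package-internal 0-based half-open
#' convention. The optional `operon` attribute is carried through for
#' internal-promoter flagging.
#'
#' @param path GFF3 file.
#' @return Data.frame with columns `id`, `start`, `end`, `strand`,
#'   `operon`, sorted by `start`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0("gene", seq_along(gr))
  operon <- if ("operon" %in% names(mc)) as.character(mc$operon) else
    rep(NA_character_, length(gr))
  df <- data.frame(id = id,
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   operon = operon,
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Write gene annotation to GFF3
#'
#' @param genes Gene data.frame (`id`, `start`, `end`, `strand`, optional
#'   `operon`; 0-based half-open).
#' @param path Output file.
#' @param genome_name Sequence name.
#' @export
write_genes_gff3 <- function(genes, path, genome_name = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = genome_name,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$id
  if ("operon" %in% names(genes)) gr$operon <- genes$operon
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read intervals from BED (0-based half-open, as the format defines)
#'
#' @param path BED file.
#' @return Data.frame with `start`, `end` and, when present, `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- as.character(mc$name)
  if ("score" %in% names(mc)) df$score <- as.numeric(mc$score)
  df
}

#' Write intervals to BED
#'
#' @param intervals Data.frame with `start`, `end` (0-based half-open).
#' @param path Output file.
#' @param genome_name Sequence name.
#' @export
write_bed <- function(intervals, path, genome_name = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = genome_name,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Classify an intergenic spacer by flanking-gene orientation
#'
#' Type A lies between divergently transcribed genes (both read away from
#' the spacer, so it holds promoters for both directions); type B between
#' codirectional genes (upstream of one unit, downstream of the other);
#' type C between convergent genes (downstream of both, so it holds no
#' promoter).
#'
#' @param left_strand,right_strand Strands (`"+"`/`"-"`) of the genes to
#'   the left and right of the spacer. Vectorized.
#' @return Character vector of type codes `"A"`, `"B"` or `"C"`.
#' @examples
#' classify_spacer("-", "+")  # "A"
#' @export
classify_spacer <- function(left_strand, right_strand) {
  ok <- c("+", "-")
  if (!all(left_strand %in% ok) || !all(right_strand %in% ok))
    stop("strand symbols must be '+' or '-'")
  ifelse(left_strand == "-" & right_strand == "+", "A",
         ifelse(left_strand == "+" & right_strand == "-", "C", "B"))
}

#' Extract intergenic spacers from a sorted gene list
#'
#' One spacer per adjacent gene pair with a positive gap; overlapping or
#' abutting pairs yield none. Each spacer is classified by
#' [classify_spacer()] and flagged internal when both flanking genes carry
#' the same operon identifier (an intergenic gap inside one operon can
#' only hold an internal promoter).
#'
#' @param genes Gene data.frame (`id`, `start`, `end`, `strand`, optional
#'   `operon`), 0-based half-open.
#' @return Data.frame of spacers: `left_gene`, `right_gene`, `start`,
#'   `end`, `type`, `internal`.
#' @export
extract_spacers <- function(genes) {
  empty <- data.frame(left_gene = character(), right_gene = character(),
                      start = integer(), end = integer(), type = character(),
                      internal = logical(), stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) < 2L) return(empty)
  genes <- genes[order(genes$start), , drop = FALSE]
  if (!"operon" %in% names(genes)) genes$operon <- NA_character_
  i <- seq_len(nrow(genes) - 1L)
  gap <- genes$start[i + 1L] - genes$end[i]
  keep <- which(gap > 0L)
  if (!length(keep)) return(empty)
  data.frame(
    left_gene = genes$id[keep],
    right_gene = genes$id[keep + 1L],
    start = genes$end[keep],
    end = genes$start[keep + 1L],
    type = classify_spacer(genes$strand[keep], genes$strand[keep + 1L]),
    internal = flag_internal(genes$operon[keep], genes$operon[keep + 1L]),
    stringsAsFactors = FALSE)
}

#' Flag spacers internal to a single operon
#'
#' @param left_operon,right_operon Operon identifiers of the flanking
#'   genes; `NA` for genes without one. Vectorized.
#' @return Logical: `TRUE` iff both identifiers are present and equal
#'   (missing identifiers default conservatively to `FALSE`).
#' @export
flag_internal <- function(left_operon, right_operon) {
  !is.na(left_operon) & !is.na(right_operon) & left_operon == right_operon
}

#' Assign peaks to intergenic spacers or open reading frames
#'
#' Assignment is by summit position: a summit inside a spacer interval goes
#' to that spacer, a summit inside a gene body to that gene. Summits in
#' neither (coordinate gaps left by overlapping genes) are assigned to the
#' nearest feature and flagged.
#'
#' @param peaks Peak data.frame with a `summit` column.
#' @param spacers Spacer data.frame from [extract_spacers()].
#' @param genes Gene data.frame.
#' @return Data.frame with one row per peak: `summit`, `category`
#'   (`"spacer"` or `"orf"`), `container` (spacer row index or gene id),
#'   `nearest` (logical; `TRUE` when assigned by proximity).
#' @export
assign_peaks <- function(peaks, spacers, genes) {
  stopifnot("summit" %in% names(peaks))
  pts <- IRanges::IRanges(start = peaks$summit + 1L, width = 1L)
  sp_r <- IRanges::IRanges(start = spacers$start + 1L,
                           end = pmax(spacers$end, spacers$start + 1L))
  gn_r <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)

  in_sp <- IRanges::findOverlaps(pts, sp_r, select = "first")
  in_gn <- IRanges::findOverlaps(pts, gn_r, select = "first")

  category <- ifelse(!is.na(in_sp), "spacer",
                     ifelse(!is.na(in_gn), "orf", NA_character_))
  container <- ifelse(!is.na(in_sp), as.character(in_sp),
                      ifelse(!is.na(in_gn), genes$id[in_gn], NA_character_))
  nearest <- is.na(category)
  if (any(nearest)) {
    feats <- c(sp_r, gn_r)
    kinds <- c(rep("spacer", length(sp_r)), rep("orf", length(gn_r)))
    ids <- c(as.character(seq_along(sp_r)), genes$id)
    nn <- IRanges::nearest(pts[nearest], feats)
    category[nearest] <- kinds[nn]
    container[nearest] <- ids[nn]
  }
  data.frame(summit = peaks$summit, category = category,
             container = container, nearest = nearest,
             stringsAsFactors = FALSE)
}

#' Summarize a peak assignment
#'
#' @param assignment Output of [assign_peaks()].
#' @return List with counts of spacer- and orf-assigned peaks, the number
#'   of distinct occupied spacers/genes, and the mean peaks per occupied
#'   feature (round-half-up, 2 dp) — e.g. 1,075 peaks over 543 spacers
#'   gives 1.98.
#' @export
assignment_summary <- function(assignment) {
  sp <- assignment[assignment$category == "spacer", ]
  orf <- assignment[assignment$category == "orf", ]
  list(
    n_spacer_peaks = nrow(sp),
    n_orf_peaks = nrow(orf),
    n_spacers = length(unique(sp$container)),
    n_genes = length(unique(orf$container)),
    peaks_per_spacer = if (nrow(sp)) round_half_up(
      nrow(sp) / length(unique(sp$container)), 2) else NA_real_,
    peaks_per_gene = if (nrow(orf)) round_half_up(
      nrow(orf) / length(unique(orf$container)), 2) else NA_real_)
}

#' Bounds on the number of constitutive promoters
#'
#' A peak-bearing divergent (type-A) spacer holds at least one and at most
#' two promoters (one per direction); a codirectional (type-B) spacer holds
#' exactly one; convergent (type-C) spacers hold none. So `min = nA + nB`
#' and `max = 2 nA + nB` over peak-bearing spacers.
#'
#' @param spacers Spacer data.frame with `type` and `n_peaks` columns, or
#'   precomputed counts via `n_a`/`n_b`.
#' @param n_a,n_b Optional direct counts of peak-bearing type-A and type-B
#'   spacers, overriding `spacers`.
#' @return Named integer vector `c(min = , max = )`.
#' @examples
#' count_constitutive_bounds(n_a = 177, n_b = 315)  # 492, 669
#' @export
count_constitutive_bounds <- function(spacers = NULL, n_a = NULL, n_b = NULL) {
  if (is.null(n_a) || is.null(n_b)) {
    stopifnot(!is.null(spacers), all(c("type", "n_peaks") %in% names(spacers)))
    occ <- spacers[spacers$n_peaks >= 1L, , drop = FALSE]
    n_a <- sum(occ$type == "A")
    n_b <- sum(occ$type == "B")
  }
  c(min = as.integer(n_a + n_b), max = as.integer(2L * n_a + n_b))
}

#' Mean number of genes under the control of one promoter
#'
#' @param total_genes Total genes in the operons controlled by the
#'   promoters.
#' @param n_promoters Number of promoters.
#' @return Mean genes per promoter, round-half-up to 2 decimals.
#' @examples
#' genes_per_promoter(271, 154)  # 1.76
#' @export
genes_per_promoter <- function(total_genes, n_promoters) {
  if (n_promoters <= 0) stop("promoter count must be positive")
  round_half_up(total_genes / n_promoters, 2)
}

#' Round half away from zero
#'
#' Matches the printed style of the summary tables (e.g. 89.27% -> 89%,
#' 1.985 -> 1.99), unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Count peaks per spacer
#'
#' Adds an `n_peaks` column to a spacer table from a peak assignment.
#'
#' @param spacers Spacer data.frame.
#' @param assignment Output of [assign_peaks()].
#' @return The spacer data.frame with `n_peaks`.
#' @export
tally_spacer_peaks <- function(spacers, assignment) {
  sp <- assignment[assignment$category == "spacer", ]
  tab <- table(factor(sp$container, levels = as.character(seq_len(nrow(spacers)))))
  spacers$n_peaks <- as.integer(tab)
  spacers
}
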