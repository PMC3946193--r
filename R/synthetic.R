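#' Generate a random genome with a given GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`. Identical `(length, gc_fraction,
#' seed)` triples yield byte-identical sequences.
#'
#' @param length Genome length in bp (>= 1; typical use >= 100).
#' @param gc_fraction Target GC proportion in `[0, 1]`.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param name,circular Passed to [genome_seq()].
#' @return A [genome_seq].
#' @examples
#' g <- generate_genome(1000, 0.5, seed = 1)
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                            name = "synthetic", circular = FALSE) {
  if (!is.numeric(length) || length < 1)
    stop("genome length must be a positive number of bases")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), size = as.integer(length), replace = TRUE, prob = p)
  genome_seq(paste(bases, collapse = ""), name = name, circular = circular)
}

#' Lay out gene pairs realizing requested spacer orientation classes
#'
#' Each layout entry plants one pair of flanking genes around an intergenic
#' spacer of the requested length, with strands chosen so the spacer falls
#' in the requested orientation class: type A lies between divergently
#' transcribed genes (`-`,`+`), type B between codirectional genes
#' (`+`,`+`), and type C between convergent genes (`+`,`-`). Consecutive
#' pairs are separated by `pair_gap` bp of unannotated sequence (which
#' forms incidental spacers of whatever class the abutting strands imply).
#'
#' @param genome A [genome_seq]; only its length is used for bounds checks.
#' @param layout A data.frame with columns `type` (`"A"|"B"|"C"`) and
#'   `spacer_len` (bp), or a list of `c(type, spacer_len)` pairs.
#' @param seed Unused randomness hook kept for interface symmetry.
#' @param gene_length Length of every planted gene body, bp.
#' @param pair_gap Gap between consecutive planted pairs, bp.
#' @return A list with `genes` (data.frame: `id`, `start`, `end`, `strand`,
#'   `operon`; 0-based half-open) and `truth` (data.frame of planted
#'   spacers: `start`, `end`, `type`).
#' @export
plant_gene_layout <- function(genome, layout, seed = NULL,
                              gene_length = 600L, pair_gap = 400L) {
  stopifnot(inherits(genome, "genome_seq"))
  layout <- as_layout_df(layout)
  empty_genes <- data.frame(id = character(), start = integer(),
                            end = integer(), strand = character(),
                            operon = character(), stringsAsFactors = FALSE)
  empty_truth <- data.frame(start = integer(), end = integer(),
                            type = character(), stringsAsFactors = FALSE)
  if (nrow(layout) == 0L)
    return(list(genes = empty_genes, truth = empty_truth))

  strand_for <- list(A = c("-", "+"), B = c("+", "+"), C = c("+", "-"))
  genes <- list(); truth <- list()
  cur <- 0L
  for (i in seq_len(nrow(layout))) {
    type <- toupper(layout$type[i])
    if (!type %in% c("A", "B", "C"))
      stop("unknown spacer type code: ", layout$type[i])
    sp <- as.integer(layout$spacer_len[i])
    s1 <- cur; e1 <- s1 + gene_length
    s2 <- e1 + sp; e2 <- s2 + gene_length
    if (e2 > genome_length(genome))
      stop("layout exceeds genome length (needs ", e2, " bp, genome has ",
           genome_length(genome), ")")
    st <- strand_for[[type]]
    genes[[length(genes) + 1L]] <- data.frame(
      id = paste0("g", 2L * i - 1L), start = s1, end = e1, strand = st[1L],
      operon = NA_character_, stringsAsFactors = FALSE)
    genes[[length(genes) + 1L]] <- data.frame(
      id = paste0("g", 2L * i), start = s2, end = e2, strand = st[2L],
      operon = NA_character_, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      start = e1, end = s2, type = type, stringsAsFactors = FALSE)
    cur <- e2 + pair_gap
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
}

as_layout_df <- function(layout) {
  if (is.data.frame(layout)) {
    stopifnot(all(c("type", "spacer_len") %in% names(layout)))
    return(layout)
  }
  if (is.list(layout)) {
    if (length(layout) == 0L)
      return(data.frame(type = character(), spacer_len = integer()))
    return(data.frame(
      type = vapply(layout, function(x) as.character(x[[1L]]), ""),
      spacer_len = vapply(layout, function(x) as.integer(x[[2L]]), 0L),
      stringsAsFactors = FALSE))
  }
  stop("layout must be a data.frame or a list of (type, spacer_len) pairs")
}

#' Plant a promoter motif with controlled consensus agreement
#'
#' Writes a -35 box with exactly `m35` of 6 bases matching `TTGACA` and a
#' -10 box with exactly `m10` matching `TATAAT`, separated by `spacer_len`
#' random bases. Mismatch positions are drawn uniformly among the six and
#' the substituted base is drawn uniformly from the three non-consensus
#' bases, so the recorded match counts are exact by construction. On the
#' minus strand the reverse complement of the construct is written, so a
#' strand-aware scan recovers the promoter at the mirrored coordinate.
#'
#' @param genome A [genome_seq].
#' @param position 0-based offset of the construct's leftmost base on the
#'   forward strand.
#' @param strand `"+"` or `"-"` (promoter orientation).
#' @param m35,m10 Requested match counts, 0-6.
#' @param spacer_len Spacer length in bp.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list with `genome` (modified) and `truth`, a one-row
#'   data.frame recording `pos35` (forward-coordinate 0-based start of the
#'   -35 hexamer as reported by [scan_sequence()]), `strand`, `m35`, `m10`,
#'   `spacer_len`.
#' @export
plant_promoter <- function(genome, position, strand, m35, m10, spacer_len,
                           seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"), strand %in% c("+", "-"))
  if (m35 < 0 || m35 > 6 || m10 < 0 || m10 > 6)
    stop("match counts must lie in 0..6")
  footprint <- 6L + as.integer(spacer_len) + 6L
  if (position < 0 || position + footprint > genome_length(genome))
    stop("promoter footprint does not fit in the genome at this position")
  if (!is.null(seed)) set.seed(seed)

  box35 <- mutate_box(CONSENSUS_35, m35)
  box10 <- mutate_box(CONSENSUS_10, m10)
  spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
                  collapse = "")
  construct <- paste0(box35, spacer, box10)
  if (strand == "-") construct <- revcomp(construct)

  seq <- genome$seq
  substr(seq, position + 1L, position + footprint) <- construct
  pos35 <- if (strand == "+") position else position + spacer_len + 6L
  list(
    genome = genome_seq(seq, name = genome$name, circular = genome$circular),
    truth = data.frame(pos35 = as.integer(pos35), strand = strand,
                       m35 = as.integer(m35), m10 = as.integer(m10),
                       spacer_len = as.integer(spacer_len),
                       stringsAsFactors = FALSE)
  )
}

mutate_box <- function(consensus, n_match) {
  b <- strsplit(consensus, "")[[1L]]
  n_mm <- 6L - as.integer(n_match)
  if (n_mm == 0L) return(consensus)
  pos <- sample(6L, n_mm)
  for (p in pos) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  }
  paste(b, collapse = "")
}

#' Simulate tiling-array binding signal with planted peaks
#'
#' Probes are placed every `probe_interval` bp starting at position 0,
#' mirroring a tiling design of 60-mer probes at 105-bp spacing. The
#' reference channel (Cy3) sits at a constant baseline; the bound-fraction
#' channel (Cy5) is the baseline times one plus the summed peak kernels,
#' times multiplicative lognormal noise. Each planted peak contributes a
#' triangular kernel of half-width `half_width` bp, reflecting the
#' 200-300 bp fragment size of the selection library, so a genuine peak
#' elevates at least two adjacent probes.
#'
#' @param genome_length Genome length in bp.
#' @param peaks A data.frame with columns `center` and `amplitude` (ratio
#'   units above baseline), or `NULL` for a flat track.
#' @param probe_interval,probe_length Probe spacing and length, bp.
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   noise; 0 gives a deterministic track.
#' @param baseline Cy3 baseline intensity.
#' @param half_width Kernel half-width, bp.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A data.frame with columns `probe_start`, `cy5`, `cy3`, carrying
#'   attributes `probe_interval`, `probe_length` and `genome_length`.
#' @export
simulate_array_signal <- function(genome_length, peaks = NULL,
                                  probe_interval = 105L, probe_length = 60L,
                                  noise_sd = 0, baseline = 1000,
                                  half_width = 150, seed = NULL) {
  stopifnot(probe_interval >= 1, genome_length >= probe_length)
  if (!is.null(seed)) set.seed(seed)
  probe_start <- seq.int(0L, genome_length - probe_length, by = probe_interval)
  n <- length(probe_start)
  enrich <- rep(0, n)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    if (any(peaks$center < 0 | peaks$center > genome_length))
      stop("peak centers must lie within the genome")
    for (i in seq_len(nrow(peaks))) {
      d <- abs(probe_start - peaks$center[i])
      enrich <- enrich + peaks$amplitude[i] * pmax(0, 1 - d / half_width)
    }
  }
  cy3 <- baseline * lognoise(n, noise_sd)
  cy5 <- cy3 * (1 + enrich) * lognoise(n, noise_sd)
  out <- data.frame(probe_start = probe_start, cy5 = cy5, cy3 = cy3)
  attr(out, "probe_interval") <- probe_interval
  attr(out, "probe_length") <- probe_length
  attr(out, "genome_length") <- genome_length
  out
}

lognoise <- function(n, sd) {
  if (sd <= 0) rep(1, n) else exp(stats::rnorm(n, mean = 0, sd = sd))
}

#' Place AT-rich intervals emulating nucleoid-silencer (H-NS) binding sites
#'
#' H-NS nucleates on AT-rich, intrinsically curved DNA. The generator draws
#' candidate windows at random and keeps the `n` most AT-rich, a crude but
#' sufficient stand-in for planting silencer-occupied intervals.
#'
#' @param genome A [genome_seq].
#' @param n Number of sites.
#' @param width Site width, bp.
#' @param n_candidates Candidate windows sampled before AT ranking.
#' @param seed Integer seed.
#' @return A data.frame with `start`, `end` (0-based half-open), sorted by
#'   position.
#' @export
generate_hns_sites <- function(genome, n, width = 120L, n_candidates = 10L * n,
                               seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"), n >= 0)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer()))
  if (!is.null(seed)) set.seed(seed)
  L <- genome_length(genome)
  if (L <= width) stop("genome shorter than site width")
  starts <- sample.int(L - width, n_candidates, replace = TRUE) - 1L
  at <- vapply(starts, function(s) {
    w <- substr(genome$seq, s + 1L, s + width)
    (nchar(w) - nchar(gsub("[AT]", "", w))) / nchar(w)
  }, 0)
  keep <- starts[order(-at)][seq_len(min(n, length(starts)))]
  keep <- sort(unique(keep))[seq_len(min(n, length(unique(keep))))]
  data.frame(start = as.integer(keep), end = as.integer(keep + width))
}

#' Simulate a single-round transcription time course
#'
#' The observable of the standard irreversible open-complex formation model
#' is a saturating exponential, `y(t) = A (1 - exp(-k t))`; multiplicative
#' lognormal noise models band-quantification error. At `noise_sd = 0` the
#' curve is exact.
#'
#' @param amplitude Plateau `A` in relative RNA units (> 0).
#' @param rate_k Opening rate `k` in min^-1 (> 0).
#' @param times Preincubation times in minutes; defaults to the assay grid
#'   0.5, 1.0, 2.5, 5.0, 7.5, 10, 15.
#' @param noise_sd Log-scale sd of the multiplicative noise.
#' @param seed Integer seed.
#' @param template_id Optional label carried through to fitting.
#' @return A data.frame with columns `time`, `signal` and attribute
#'   `template_id`.
#' @export
simulate_time_course <- function(amplitude, rate_k,
                                 times = c(0.5, 1, 2.5, 5, 7.5, 10, 15),
                                 noise_sd = 0, seed = NULL,
                                 template_id = NA_character_) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (rate_k <= 0) stop("rate_k must be positive")
  if (!is.null(seed)) set.seed(seed)
  y <- amplitude * (1 - exp(-rate_k * times)) * lognoise(length(times), noise_sd)
  out <- data.frame(time = times, signal = y)
  attr(out, "template_id") <- template_id
  out
}
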