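# Independent oracles and fixture builders.

# Brute-force promoter scan: explicitly enumerates every (-35 start,
# spacer, -10 start) triple on each strand and scores each candidate
# hexamer by direct byte comparison. Deliberately a different code path
# from the package's sliding match-profile scan.
brute_box_count <- function(hexamers, consensus) {
  cc <- utf8ToInt(consensus)
  nn <- utf8ToInt("N")
  vapply(hexamers, function(h) {
    hh <- utf8ToInt(h)
    sum(hh == cc & hh != nn)
  }, 0L, USE.NAMES = FALSE)
}

brute_scan <- function(seq, min_box = 4L, min_sum = 8L) {
  seq <- toupper(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else conpromo::revcomp(seq)
    L <- nchar(s)
    if (L < 27L) next
    hex <- substring(s, seq_len(L - 5L), seq_len(L - 5L) + 5L)
    c35 <- brute_box_count(hex, "TTGACA")
    c10 <- brute_box_count(hex, "TATAAT")
    for (sp in 15:19) {
      for (i in seq_len(L)) {           # 1-based -35 start on this strand
        j <- i + 6L + sp                 # 1-based -10 start
        if (j + 5L > L) next
        m35 <- c35[i]; m10 <- c10[j]
        if (m35 >= min_box && m10 >= min_box && m35 + m10 >= min_sum) {
          pos35 <- if (strand == "+") i - 1L else L - (i - 1L) - 6L
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, pos35 = pos35, spacer_len = sp,
            m35 = m35, m10 = m10,
            total = m35 + m10 + conpromo::spacer_length_score(sp),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(), pos35 = integer(),
                      spacer_len = integer(), m35 = integer(),
                      m10 = integer(), total = integer()))
  res <- do.call(rbind, out)
  res[order(res$pos35, res$strand, res$spacer_len), , drop = FALSE]
}

# Canonical key for comparing hit sets.
hit_key <- function(h) {
  sort(paste(h$strand, h$pos35, h$spacer_len, h$m35, h$m10, h$total,
             sep = ":"))
}

# Assignment fixture: n_peaks distributed over containers with the given
# per-container counts.
make_assignment <- function(spacer_counts = integer(), orf_counts = integer()) {
  rows <- list()
  if (length(spacer_counts))
    rows$sp <- data.frame(
      summit = seq_len(sum(spacer_counts)),
      category = "spacer",
      container = rep(paste0("s", seq_along(spacer_counts)), spacer_counts),
      nearest = FALSE, stringsAsFactors = FALSE)
  if (length(orf_counts))
    rows$orf <- data.frame(
      summit = seq_len(sum(orf_counts)),
      category = "orf",
      container = rep(paste0("g", seq_along(orf_counts)), orf_counts),
      nearest = FALSE, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# Spacer-table fixture with given counts per (type, n_peaks, has_hns).
make_spacers <- function(n_a = 0, n_b = 0, n_c = 0,
                         n_a_hns = 0, n_b_hns = 0, n_peaks = 1L) {
  type <- c(rep("A", n_a), rep("B", n_b), rep("C", n_c))
  n <- length(type)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), type = character(),
                      n_peaks = integer(), has_hns = logical()))
  has_hns <- logical(n)
  has_hns[which(type == "A")[seq_len(n_a_hns)]] <- TRUE
  has_hns[which(type == "B")[seq_len(n_b_hns)]] <- TRUE
  data.frame(start = seq(0L, by = 1000L, length.out = n),
             end = seq(500L, by = 1000L, length.out = n),
             type = type, n_peaks = n_peaks, has_hns = has_hns,
             stringsAsFactors = FALSE)
}
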