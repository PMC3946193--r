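#' Genome sequence container
#'
#' A lightweight container for a single nucleotide sequence over the
#' alphabet `{A,C,G,T,N}`, carrying a name and a circularity flag. All
#' coordinates used with this object are 0-based, half-open; conversion to
#' 1-based closed happens only at GFF3 boundaries (BED stays 0-based
#' half-open per its standard).
#'
#' @param seq Character scalar, the sequence (upper- or lower-case; stored
#'   upper-case).
#' @param name Sequence identifier used in FASTA/GFF3/BED output.
#' @param circular Logical; whether coordinate arithmetic may wrap around
#'   the origin.
#' @return An object of class `genome_seq` with fields `name`, `seq`,
#'   `circular`.
#' @examples
#' g <- genome_seq("ACGTACGT", name = "toy")
#' genome_length(g)
#' @export
genome_seq <- function(seq, name = "genome", circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop("genome sequence must have length >= 1")
  if (grepl("[^ACGTN]", seq))
    stop("genome sequence restricted to alphabet {A,C,G,T,N}")
  structure(list(name = name, seq = seq, circular = isTRUE(circular)),
            class = "genome_seq")
}

#' @rdname genome_seq
#' @param x A `genome_seq` object.
#' @export
genome_length <- function(x) {
  stopifnot(inherits(x, "genome_seq"))
  nchar(x$seq)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp%s\n", x$name,
              format(genome_length(x), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Extract a subsequence in 0-based half-open coordinates
#'
#' On the minus strand the reverse complement of the interval is returned,
#' i.e. the sequence as read 5'->3' on that strand.
#'
#' @param genome A [genome_seq] object.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_seq"), start >= 0, end >= start,
            end <= genome_length(genome))
  s <- substr(genome$seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over `{A,C,G,T,N}`.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a genome from FASTA
#'
#' The first record of the file becomes the genome; multi-record files are
#' rejected since the pipeline is single-replicon.
#'
#' @param path FASTA file.
#' @param circular Circularity flag to attach (FASTA does not encode it).
#' @return A [genome_seq].
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA, got ", length(ss), " records")
  genome_seq(as.character(ss[[1L]]), name = sub("\\s.*$", "", names(ss)[1L]),
             circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_seq].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
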