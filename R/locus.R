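# Cut-locus model: reference top strand plus cut geometry defining the two
# broken ends and their overhangs. Coordinates are 1-based inclusive on the
# top strand throughout the package.

#' Describe a double-strand break locus
#'
#' A DSB locus is the reference top strand of an amplicon together with the
#' geometry of a staggered endonuclease cut: `cut_pos` is the top-strand
#' position of the most distal base of the left end's overhang region, and
#' `overhang_len` is the overhang length (4 for HO, which leaves 3' overhangs).
#' The single-stranded window always covers top-strand positions
#' `cut_pos - overhang_len + 1 .. cut_pos`; with 3' polarity the left fragment
#' carries the top strand of that window, with 5' polarity the right fragment
#' does. Blunt cuts are `overhang_len = 0`.
#'
#' @param top_strand Character scalar over `A`,`C`,`G`,`T` (uppercase).
#' @param cut_pos Integer, top-strand position of the most distal base of the
#'   left end's overhang.
#' @param overhang_len Integer >= 0, overhang length in bases.
#' @param polarity `"3p"` (default, models HO) or `"5p"`.
#' @param amplicon_window Integer pair `(start, end)`: the top-strand region
#'   covered by the sequencing amplicon. Must span the cut. Defaults to the
#'   whole sequence.
#' @param name Text label.
#' @return An object of class `dsb_locus`.
#' @examples
#' loc <- dsb_locus("AAAACGTACGTTTT", cut_pos = 8, overhang_len = 4)
#' end_sequences(loc)
#' @export
dsb_locus <- function(top_strand, cut_pos, overhang_len,
                      polarity = c("3p", "5p"),
                      amplicon_window = NULL, name = "locus") {
  polarity <- match.arg(polarity)
  stopifnot(is.character(top_strand), length(top_strand) == 1L)
  top_strand <- as.character(top_strand)
  if (grepl("[^ACGT]", top_strand))
    stop("top_strand must contain only uppercase A/C/G/T (no ambiguity codes)")
  n <- nchar(top_strand)
  cut_pos <- as.integer(cut_pos)
  overhang_len <- as.integer(overhang_len)
  if (overhang_len < 0L) stop("overhang_len must be >= 0")
  if (cut_pos < overhang_len || cut_pos > n - overhang_len)
    stop("cut geometry out of bounds: need overhang_len <= cut_pos <= length - overhang_len")
  if (is.null(amplicon_window)) amplicon_window <- c(1L, n)
  amplicon_window <- as.integer(amplicon_window)
  if (length(amplicon_window) != 2L ||
      amplicon_window[1] < 1L || amplicon_window[2] > n ||
      amplicon_window[1] > amplicon_window[2])
    stop("amplicon_window must be within the sequence")
  if (amplicon_window[1] > cut_pos - overhang_len ||
      amplicon_window[2] < cut_pos + 1L)
    stop("amplicon_window must span the cut site")
  structure(list(name = name, top_strand = top_strand, n = n,
                 cut_pos = cut_pos, overhang_len = overhang_len,
                 polarity = polarity, amplicon_window = amplicon_window),
            class = "dsb_locus")
}

#' @export
print.dsb_locus <- function(x, ...) {
  cat(sprintf("<dsb_locus '%s'> %d bp, cut at %d, %d-nt %s overhang, window [%d, %d]\n",
              x$name, x$n, x$cut_pos, x$overhang_len,
              if (x$overhang_len == 0L) "blunt" else x$polarity,
              x$amplicon_window[1], x$amplicon_window[2]))
  invisible(x)
}

#' Load a DSB locus from a single-record FASTA plus a geometry block
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param geometry List (or path to a YAML/JSON file parsing to a list) with
#'   fields `cut_pos`, `overhang_len`, and optionally `polarity`,
#'   `amplicon_window`, `name`.
#' @return A [dsb_locus].
#' @export
load_locus <- function(fasta_path, geometry) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("FASTA must contain exactly one record, found ", length(seqs))
  s <- as.character(seqs[[1]])
  if (grepl("[^ACGT]", s))
    stop("reference sequence contains lowercase or ambiguous bases")
  if (is.character(geometry) && length(geometry) == 1L)
    geometry <- yaml::read_yaml(geometry)
  dsb_locus(top_strand = s,
            cut_pos = geometry$cut_pos,
            overhang_len = geometry$overhang_len,
            polarity = if (is.null(geometry$polarity)) "3p" else geometry$polarity,
            amplicon_window = if (is.null(geometry$amplicon_window)) NULL
                              else unlist(geometry$amplicon_window),
            name = if (is.null(geometry$name)) names(seqs)[1] else geometry$name)
}

#' Sequencing read layout
#'
#' @param index_len Length of the inline sample index at the read start
#'   (6 in the assay emulated here).
#' @param read_len Total read length (100 for HiSeq 100 bp reads).
#' @param primer_len Bases of invariant primer/adapter-proximal sequence
#'   between the index and the first amplicon base counted against
#'   `read_len`; kept for bookkeeping, 0 by default because the amplicon
#'   window start already marks the first sequenced genomic base.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(index_len = 6L, read_len = 100L, primer_len = 0L) {
  index_len <- as.integer(index_len); read_len <- as.integer(read_len)
  primer_len <- as.integer(primer_len)
  if (index_len < 0L || primer_len < 0L) stop("lengths must be non-negative")
  if (index_len + primer_len >= read_len)
    stop("index_len + primer_len must be smaller than read_len")
  structure(list(index_len = index_len, primer_len = primer_len,
                 read_len = read_len), class = "read_layout")
}

#' Broken-end sequences of a cut locus
#'
#' Returns the top-strand extent of the left end, the templated top-strand
#' extent of the right end, and the two single-stranded overhangs written
#' 5' to 3'. For a 3' overhang cut the left end is `top[1..t]` with overhang
#' `top[t-v+1..t]`; the right end templates `top[t-v+1..N]` through its
#' bottom-strand overhang. The two overhangs are reverse complements, which
#' is what allows precise religation.
#'
#' @param locus A [dsb_locus].
#' @return List with `left_end`, `right_end`, and `overhangs` (character
#'   pair, left then right, each read 5' to 3'; empty strings for blunt ends).
#' @export
end_sequences <- function(locus) {
  stopifnot(inherits(locus, "dsb_locus"))
  t <- locus$cut_pos; v <- locus$overhang_len; s <- locus$top_strand
  window <- if (v > 0L) substr(s, t - v + 1L, t) else ""
  if (locus$polarity == "3p") {
    left <- substr(s, 1L, t)
    ovh <- c(left = window, right = revcomp(window))
  } else {
    left <- substr(s, 1L, t - v)
    ovh <- c(left = revcomp(window), right = window)
  }
  right <- substr(s, t - v + 1L, locus$n)
  list(left_end = left, right_end = right, overhangs = ovh)
}

# reverse complement for plain character vectors of A/C/G/T strings
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Bundled synthetic study locus
#'
#' A deterministic synthetic amplicon used throughout tests and simulations:
#' 240 bp, cut at position 110 with a 4-nt 3' overhang whose terminal bases
#' are `CACA`, so that the classic 2-nt fill-in duplication joint ("+CA" in
#' Moore-Haber nomenclature) exists. This is a synthetic stand-in locus; the
#' real promoter sequence of any given assay is supplied via [load_locus()].
#'
#' @param n Sequence length.
#' @param cut_pos Cut position.
#' @param overhang_len Overhang length.
#' @param amplicon_window Window covered by the read, defaults to (50, 190).
#' @return A [dsb_locus].
#' @export
synthetic_locus <- function(n = 240L, cut_pos = 110L, overhang_len = 4L,
                            amplicon_window = c(50L, 190L)) {
  # fixed internal stream so the locus is a constant of the package
  bases <- c("A", "C", "G", "T")
  state <- 104729
  draw <- integer(n)
  for (i in seq_len(n)) {
    state <- (state * 16807) %% 2147483647  # exact in doubles
    draw[i] <- state %% 4 + 1
  }
  s <- bases[draw]
  s[(cut_pos - 3L):cut_pos] <- c("C", "A", "C", "A")
  dsb_locus(paste(s, collapse = ""), cut_pos = cut_pos,
            overhang_len = overhang_len,
            amplicon_window = amplicon_window, name = "synthetic-cs")
}
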