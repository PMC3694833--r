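# Read classification: demultiplex inline-indexed amplicon reads, remove
# contaminant (spike-in control) reads by shared k-mer content, and assign
# each remaining read to a joint template by Hamming distance. Insertion and
# deletion joints are distinct full-length templates, so no gapped alignment
# is needed; the assay's "one mismatched read base" tolerance maps to
# Hamming distance <= 1 against the nearest template.

#' Sample index table
#'
#' @param indexes Character vector of index sequences (all the same length),
#'   or a path to a two-column TSV `index<TAB>sample` (no header needed;
#'   a header line `index\tsample` is tolerated).
#' @param samples Sample labels, parallel to `indexes` (ignored when a path
#'   is given).
#' @return Named character vector mapping index sequence to sample label,
#'   of class `sample_index_table`. Warns when any pair of indexes is within
#'   Hamming distance 1 (a single sequencing error could cross-assign reads).
#' @export
sample_index_table <- function(indexes, samples = NULL) {
  if (is.null(samples) && length(indexes) == 1L && file.exists(indexes)) {
    tab <- utils::read.table(indexes, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
    if (tab[1, 1] == "index") tab <- tab[-1, , drop = FALSE]
    indexes <- tab[[1]]; samples <- tab[[2]]
  }
  indexes <- toupper(as.character(indexes))
  samples <- as.character(samples)
  stopifnot(length(indexes) == length(samples), length(indexes) >= 1L)
  if (anyDuplicated(indexes)) stop("index sequences must be unique")
  if (anyDuplicated(samples)) stop("sample labels must be unique")
  if (length(unique(nchar(indexes))) != 1L)
    stop("all indexes must have the same length")
  if (length(indexes) > 1L) {
    d <- utils::combn(seq_along(indexes), 2, function(p)
      hamming(indexes[p[1]], indexes[p[2]]))
    if (any(d < 2L))
      warning("some index pairs are within Hamming distance 1; ",
              "demultiplexing will be fragile to index sequencing errors")
  }
  structure(stats::setNames(samples, indexes), class = "sample_index_table")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Deterministic well-separated index set
#'
#' Generates up to 64 six-base indexes built from homodimer blocks
#' (`AA`,`CC`,`GG`,`TT`), so any two distinct indexes differ in at least two
#' positions.
#'
#' @param n Number of indexes.
#' @return Character vector of `n` index sequences.
#' @export
default_sample_indexes <- function(n) {
  blocks <- c("AA", "CC", "GG", "TT")
  g <- expand.grid(a = blocks, b = blocks, c = blocks,
                   stringsAsFactors = FALSE)
  codes <- paste0(g$a, g$b, g$c)
  if (n > length(codes)) stop("at most ", length(codes), " indexes available")
  codes[seq_len(n)]
}

#' Demultiplex a read by its inline index
#'
#' The first `index_len` bases are matched exactly against the table; no
#' mismatch is tolerated (6-mers are short and the index set is required to
#' be well separated, so exact matching is the conservative choice).
#'
#' @param read Character scalar read sequence.
#' @param table A [sample_index_table].
#' @param layout A [read_layout].
#' @return The sample label, or `"unassigned_index"`.
#' @export
demultiplex <- function(read, table, layout) {
  if (!nchar(read)) stop("empty read")
  idx <- substr(read, 1L, layout$index_len)
  s <- unname(table[idx])
  if (is.na(s)) "unassigned_index" else s
}

# ---- contaminant filter ----------------------------------------------------

#' Build the k-mer set of a contaminant reference
#'
#' @param contaminant_ref Character scalar reference sequence (both strands
#'   are indexed, so read orientation does not matter).
#' @param k K-mer length (>= 11).
#' @return Character vector of unique k-mers, with `k` as attribute.
#' @export
contaminant_kmers <- function(contaminant_ref, k = 21L) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  if (!nchar(contaminant_ref)) stop("contaminant reference is empty")
  both <- c(contaminant_ref, revcomp(contaminant_ref))
  km <- unlist(lapply(both, function(s) {
    n <- nchar(s)
    if (n < k) character(0)
    else substring(s, 1:(n - k + 1L), k:n)
  }))
  structure(unique(km), k = k)
}

#' Flag a read as contaminant by shared k-mer fraction
#'
#' A read is called contaminant when at least `threshold` of its k-mers occur
#' in the contaminant k-mer set (built over both strands). This self-contained
#' filter stands in for aligner-based spike-in removal; any other predicate
#' with the same signature can be substituted upstream.
#'
#' @param read Character scalar (or vector) of read sequence(s).
#' @param contaminant_ref Reference sequence, or a precomputed set from
#'   [contaminant_kmers()].
#' @param k K-mer length (ignored when a precomputed set is given).
#' @param threshold Fraction of read k-mers that must be shared.
#' @return Logical vector, `TRUE` for contaminant reads.
#' @export
filter_contaminant <- function(read, contaminant_ref, k = 21L,
                               threshold = 0.5) {
  km_set <- if (!is.null(attr(contaminant_ref, "k"))) contaminant_ref
            else contaminant_kmers(contaminant_ref, k)
  k <- attr(km_set, "k")
  n <- nchar(read)
  if (any(n < k)) stop("k (", k, ") larger than a read (", min(n), " bases)")
  nk <- n - k + 1L
  starts <- sequence(nk)
  ridx <- rep.int(seq_along(read), nk)
  kmers <- substring(read[ridx], starts, starts + k - 1L)
  hit <- kmers %in% km_set
  shared <- vapply(split(hit, ridx), sum, numeric(1))
  unname(shared / nk >= threshold)
}

# ---- per-read classification ----------------------------------------------

#' Classify one read against the joint templates
#'
#' The read is compared to every template by Hamming distance over their
#' overlapping length, with the index bases masked. The nearest template
#' wins if its distance is within `max_mismatch` and no other template ties
#' at that distance; a tie at the minimum makes the read `ambiguous`; a
#' minimum above the tolerance makes it `unmatched`. Reads shorter than the
#' layout must still cover the junction plus `junction_flank` bases on each
#' side, otherwise they are `unmatched`.
#'
#' @param read Character scalar read sequence.
#' @param templates A `joint_space` with read templates.
#' @param layout A [read_layout].
#' @param max_mismatch Mismatch tolerance (default 1).
#' @param junction_flank Required junction coverage for short reads.
#' @return List with `category` (`"joint"`, `"ambiguous"`, `"unmatched"`),
#'   `joint_id` (or `NA`), and `mismatches` (or `NA`).
#' @export
classify_read <- function(read, templates, layout, max_mismatch = 1L,
                          junction_flank = 3L) {
  stopifnot(inherits(templates, "joint_space"),
            !is.null(templates$read_template))
  engine <- classify_engine(templates, layout, max_mismatch, junction_flank)
  res <- engine(read)
  list(category = res$category[1], joint_id = res$joint_id[1],
       mismatches = res$mismatches[1])
}

# Precompiled classifier over a fixed template set. Returns a function that
# maps a character vector of reads to a data.frame (category, joint_id,
# mismatches). Exact full-length matches short-circuit through a hash lookup;
# the remaining reads share the mismatch count against the common template
# prefix and only scan the variable suffix per template.
classify_engine <- function(templates, layout, max_mismatch = 1L,
                            junction_flank = 3L) {
  idx_len <- layout$index_len
  body_len <- layout$read_len - idx_len
  bodies <- substr(templates$read_template, idx_len + 1L, layout$read_len)
  stopifnot(all(nchar(bodies) == body_len))
  ids <- templates$joint_id
  dup <- duplicated(bodies) | duplicated(bodies, fromLast = TRUE)
  loc <- attr(templates, "locus")
  a_start <- loc$amplicon_window[1]
  # junction extent in body coordinates (1-based within the post-index body)
  junc_left <- loc$cut_pos - templates$L - a_start + 1L
  junc_right <- junc_left + nchar(templates$I) + 1L

  tmat <- vapply(strsplit(bodies, "", fixed = TRUE), identity,
                 character(body_len))           # body_len x n_templates
  same <- rowSums(tmat != tmat[, 1]) == 0
  prefix_len <- if (all(same)) body_len else min(which(!same)) - 1L
  prefix <- bodies[1]
  suf_mat <- tmat[(prefix_len + 1L):body_len, , drop = FALSE]

  function(reads) {
    n <- length(reads)
    category <- rep("unmatched", n)
    joint_id <- rep(NA_character_, n)
    mism <- rep(NA_integer_, n)
    if (!n) return(data.frame(category = character(0),
                              joint_id = character(0),
                              mismatches = integer(0)))
    rbody <- substr(reads, idx_len + 1L, idx_len + body_len)
    full <- nchar(rbody) == body_len

    # exact path
    ex <- match(rbody, bodies)
    hit <- !is.na(ex) & full
    if (any(hit)) {
      amb <- hit & dup[ifelse(is.na(ex), 1L, ex)]
      category[amb] <- "ambiguous"
      ok <- hit & !amb
      category[ok] <- "joint"
      joint_id[ok] <- ids[ex[ok]]
      mism[ok] <- 0L
    }
    # full-length non-exact reads: template-major vectorised Hamming scan
    # (junction coverage is guaranteed for full-length reads at enumeration)
    rest_full <- which(!hit & full)
    if (length(rest_full)) {
      rmat <- vapply(strsplit(rbody[rest_full], "", fixed = TRUE), identity,
                     character(body_len))
      rmat <- matrix(rmat, nrow = body_len)
      pre_chars <- strsplit(prefix, "", fixed = TRUE)[[1]]
      dpre <- if (prefix_len > 0L)
        colSums(rmat[seq_len(prefix_len), , drop = FALSE] !=
                  pre_chars[seq_len(prefix_len)])
      else rep(0L, length(rest_full))
      rsuf <- rmat[(prefix_len + 1L):body_len, , drop = FALSE]
      nt <- ncol(suf_mat)
      dbest <- rep(Inf, length(rest_full))
      best_t <- integer(length(rest_full))
      tied <- logical(length(rest_full))
      for (tt in seq_len(nt)) {
        d <- dpre + colSums(rsuf != suf_mat[, tt])
        lt <- d < dbest
        eq <- d == dbest
        tied[eq] <- TRUE
        tied[lt] <- FALSE
        dbest[lt] <- d[lt]
        best_t[lt] <- tt
      }
      ok <- dbest <= max_mismatch
      amb2 <- ok & tied
      asg <- ok & !tied
      category[rest_full[amb2]] <- "ambiguous"
      category[rest_full[asg]] <- "joint"
      joint_id[rest_full[asg]] <- ids[best_t[asg]]
      mism[rest_full[asg]] <- as.integer(dbest[asg])
    }

    # short reads: per-read scan with junction-coverage requirement
    for (i in which(!hit & !full)) {
      b <- rbody[i]
      len <- nchar(b)
      if (len < 1L) next                          # stays unmatched
      rchars <- strsplit(b, "", fixed = TRUE)[[1]]
      plen <- min(prefix_len, len)
      dpre <- sum(rchars[seq_len(plen)] !=
                    strsplit(substr(prefix, 1L, plen), "", fixed = TRUE)[[1]])
      if (len > prefix_len) {
        sl <- len - prefix_len
        dsuf <- colSums(suf_mat[seq_len(sl), , drop = FALSE] !=
                          rchars[(prefix_len + 1L):len])
      } else dsuf <- rep(0L, ncol(suf_mat))
      d <- dpre + dsuf
      covered <- (junc_right + junction_flank) <= len &
                 (junc_left - junction_flank) >= 1L
      d[!covered] <- NA_integer_
      if (all(is.na(d))) next
      dmin <- min(d, na.rm = TRUE)
      if (dmin > max_mismatch) next
      best <- which(!is.na(d) & d == dmin)
      if (length(best) > 1L) {
        category[i] <- "ambiguous"
      } else {
        category[i] <- "joint"
        joint_id[i] <- ids[best]
        mism[i] <- dmin
      }
    }
    data.frame(category = category, joint_id = joint_id, mismatches = mism,
               stringsAsFactors = FALSE)
  }
}

# ---- batch classification --------------------------------------------------

#' Classify a FASTQ of indexed amplicon reads
#'
#' Runs the full per-read pipeline in the assay's order: contaminant
#' filtering, index demultiplexing, then joint assignment. Returns the joint
#' count table (rows: joint ids plus `ambiguous` and `unmatched`; columns:
#' samples) and run statistics. Read conservation holds exactly:
#' `sum(counts) + contaminant + unassigned_index + truncated == total`.
#'
#' @param fastq_path Path to a FASTQ file (optionally gzipped).
#' @param templates A `joint_space` with read templates.
#' @param table A [sample_index_table].
#' @param layout A [read_layout].
#' @param contaminant_ref Contaminant reference sequence or precomputed
#'   [contaminant_kmers()] set; `NULL` disables the filter.
#' @param k,threshold Contaminant filter parameters.
#' @param max_mismatch Joint-assignment mismatch tolerance (default 1).
#' @return List of class `nhej_counts` with elements `counts` (integer
#'   matrix) and `stats` (totals per category).
#' @export
classify_batch <- function(fastq_path, templates, table, layout,
                           contaminant_ref = NULL, k = 21L, threshold = 0.5,
                           max_mismatch = 1L) {
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq")),
    error = function(e) stop("unreadable FASTQ '", fastq_path, "': ",
                             conditionMessage(e)))
  samples <- unname(unclass(table))
  special <- c("ambiguous", "unmatched")
  rows <- c(templates$joint_id, special)
  counts <- matrix(0L, nrow = length(rows), ncol = length(samples),
                   dimnames = list(rows, samples))
  stats <- list(total_reads = length(reads), contaminant = 0L,
                unassigned_index = 0L, truncated = 0L)
  if (!length(reads)) {
    return(structure(list(counts = counts, stats = stats),
                     class = "nhej_counts"))
  }

  short <- nchar(reads) < layout$index_len + 1L
  stats$truncated <- sum(short)
  reads <- reads[!short]

  if (!is.null(contaminant_ref) && length(reads)) {
    km <- if (!is.null(attr(contaminant_ref, "k"))) contaminant_ref
          else contaminant_kmers(contaminant_ref, k)
    kk <- attr(km, "k")
    eligible <- which(nchar(reads) >= kk)
    is_cont <- logical(length(reads))
    # scan in blocks to bound the transient k-mer vector
    for (block in split(eligible, ceiling(seq_along(eligible) / 50000)))
      is_cont[block] <- filter_contaminant(reads[block], km,
                                           threshold = threshold)
    stats$contaminant <- sum(is_cont)
    reads <- reads[!is_cont]
  }

  if (length(reads)) {
    idx <- substr(reads, 1L, layout$index_len)
    smp <- unname(table[idx])
    stats$unassigned_index <- sum(is.na(smp))
    reads <- reads[!is.na(smp)]
    smp <- smp[!is.na(smp)]
    if (length(reads)) {
      engine <- classify_engine(templates, layout, max_mismatch)
      res <- engine(reads)
      row_of <- ifelse(res$category == "joint", res$joint_id, res$category)
      tab <- table(factor(row_of, levels = rows),
                   factor(smp, levels = samples))
      counts <- counts + unclass(tab)
    }
  }
  storage.mode(counts) <- "integer"
  stats$assigned <- sum(counts[templates$joint_id, , drop = FALSE])
  stats$ambiguous <- sum(counts["ambiguous", ])
  stats$unmatched <- sum(counts["unmatched", ])
  structure(list(counts = counts, stats = stats), class = "nhej_counts")
}

#' @export
print.nhej_counts <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<nhej_counts> %d reads: %d assigned, %d ambiguous, ",
                     "%d unmatched, %d contaminant, %d unassigned index, ",
                     "%d truncated\n"),
              s$total_reads, s$assigned, s$ambiguous, s$unmatched,
              s$contaminant, s$unassigned_index, s$truncated))
  cat(sprintf("  %d joint rows x %d samples\n",
              nrow(x$counts) - 2L, ncol(x$counts)))
  invisible(x)
}

#' Read / write a joint count table as TSV
#'
#' Rows are joint ids (plus the special `ambiguous` / `unmatched` rows),
#' columns are samples; the first column holds the row names.
#'
#' @param counts Integer matrix (or an `nhej_counts` object).
#' @param path File path.
#' @return `read_count_table`: integer matrix.
#' @export
write_count_table <- function(counts, path) {
  if (inherits(counts, "nhej_counts")) counts <- counts$counts
  df <- data.frame(joint_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
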