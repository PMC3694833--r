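# Demultiplexing, contaminant filtering and joint assignment.

test_that("demultiplexing is exact on the index", {
  tab <- sample_index_table(c("ACGTAC", "TGCATG"), c("wt_0h_r1", "wt_24h_r1"))
  lay <- read_layout()
  expect_equal(demultiplex(paste0("ACGTAC", strrep("A", 94)), tab, lay),
               "wt_0h_r1")
  # one index mismatch is enough to unassign
  expect_equal(demultiplex(paste0("ACGTAG", strrep("A", 94)), tab, lay),
               "unassigned_index")
  expect_equal(demultiplex(paste0("GGGGGG", strrep("A", 94)), tab, lay),
               "unassigned_index")
  expect_error(demultiplex("", tab, lay), "empty")
})

test_that("index tables enforce uniqueness and warn on close pairs", {
  expect_error(sample_index_table(c("ACGTAC", "ACGTAC"), c("a", "b")),
               "unique")
  expect_warning(sample_index_table(c("ACGTAC", "ACGTAT"), c("a", "b")),
                 "Hamming")
  idx <- default_sample_indexes(12)
  expect_silent(tab <- sample_index_table(idx, paste0("s", 1:12)))
  d <- utils::combn(seq_along(idx), 2,
                    function(p) nhejseq:::hamming(idx[p[1]], idx[p[2]]))
  expect_true(all(d >= 2))
})

test_that("contaminant filter matches a brute-force k-mer scan", {
  set.seed(9)
  ref <- synthetic_contaminant(2000, seed = 1)
  bases <- c("A", "C", "G", "T")
  locus_seq <- paste(sample(bases, 200, replace = TRUE), collapse = "")
  k <- 21
  expect_true(filter_contaminant(substr(ref, 101, 200), ref, k))
  expect_false(filter_contaminant(paste(sample(bases, 100, replace = TRUE),
                                        collapse = ""), ref, k))
  # brute-force oracle: scan every k-mer position of the read directly
  brute <- function(read, ref, k, thr) {
    hits <- 0; n <- nchar(read)
    for (i in 1:(n - k + 1)) {
      km <- substr(read, i, i + k - 1)
      found <- grepl(km, ref, fixed = TRUE) ||
        grepl(nhejseq:::revcomp(km), ref, fixed = TRUE)
      hits <- hits + found
    }
    hits / (n - k + 1) >= thr
  }
  reads <- vapply(1:30, function(i) {
    ncont <- sample(0:100, 1)
    s <- sample(nchar(ref) - 100, 1)
    paste0(substr(ref, s, s + ncont - 1),
           substr(locus_seq, 1, 100 - ncont))
  }, character(1))
  expect_equal(filter_contaminant(reads, ref, k, threshold = 0.5),
               vapply(reads, brute, logical(1), ref = ref, k = k, thr = 0.5,
                      USE.NAMES = FALSE))
  expect_error(filter_contaminant("ACGT", ref, k = 21), "larger than a read")
  expect_error(contaminant_kmers(ref, k = 5), ">= 11")
})

test_that("classify_read follows the nearest-template rule", {
  fx <- classer_fixture()
  tp <- fx$templates; lay <- fx$layout
  body <- substr(tp$read_template, 7, 46)
  idx <- "AACCGG"

  # exact read of the precise template
  pr <- which(tp$joint_id == "precise")
  r <- classify_read(paste0(idx, body[pr]), tp, lay)
  expect_equal(r$category, "joint")
  expect_equal(r$joint_id, "precise")
  expect_equal(r$mismatches, 0L)

  # one substituted base still assigns to the nearest template
  chars <- strsplit(body, "", fixed = TRUE)
  dmat <- sapply(chars, function(a)
    vapply(chars, function(b) sum(a != b), integer(1)))
  diag(dmat) <- NA
  safe <- which(apply(dmat, 1, min, na.rm = TRUE) >= 3)[1]
  mut <- body[safe]
  substr(mut, 2, 2) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 2, 2))[1]
  r <- classify_read(paste0(idx, mut), tp, lay)
  expect_equal(r$category, "joint")
  expect_equal(r$joint_id, tp$joint_id[safe])
  expect_equal(r$mismatches, 1L)

  # two mismatches against the nearest template -> unmatched
  mut2 <- body[safe]
  substr(mut2, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(mut2, 2, 2))[1]
  substr(mut2, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(mut2, 4, 4))[1]
  expect_equal(classify_read(paste0(idx, mut2), tp, lay)$category,
               "unmatched")

  # a read equidistant from two templates is ambiguous
  hpair <- which(dmat == 2, arr.ind = TRUE)
  found <- FALSE
  for (row in seq_len(nrow(hpair))) {
    a <- body[hpair[row, 1]]; b <- body[hpair[row, 2]]
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    mid <- a
    substr(mid, pos[1], pos[1]) <- substr(b, pos[1], pos[1])
    midc <- strsplit(mid, "", fixed = TRUE)[[1]]
    dists <- vapply(chars, function(b) sum(midc != b), integer(1))
    if (min(dists) == 1 && sum(dists == 1) >= 2) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(classify_read(paste0(idx, mid), tp, lay)$category, "ambiguous")

  # template order does not matter
  rev_tp <- tp[rev(seq_len(nrow(tp))), ]
  attributes(rev_tp)[c("locus", "layout", "limits", "class")] <-
    attributes(tp)[c("locus", "layout", "limits", "class")]
  r2 <- classify_read(paste0(idx, mut), rev_tp, lay)
  expect_equal(r2[c("category", "joint_id", "mismatches")],
               r[c("category", "joint_id", "mismatches")])
})

test_that("short reads must still cover the junction", {
  fx <- classer_fixture()
  tp <- fx$templates; lay <- fx$layout
  idx <- "AACCGG"
  pr <- which(tp$joint_id == "precise")
  body <- substr(tp$read_template[pr], 7, 46)
  # junction for the precise joint sits at body position 30; 3 flanking
  # bases are required
  long_enough <- paste0(idx, substr(body, 1, 36))
  too_short <- paste0(idx, substr(body, 1, 20))
  expect_equal(classify_read(long_enough, tp, lay)$category, "joint")
  expect_equal(classify_read(too_short, tp, lay)$category, "unmatched")
})

test_that("batch classification conserves reads and recovers planted truth
           exactly without errors", {
  fx <- classer_fixture()
  tp <- fx$templates; lay <- fx$layout
  tab <- sample_index_table(default_sample_indexes(2), c("s1", "s2"))
  sp <- lapply(c(s1 = "wt_24h", s2 = "pre_induction"), make_spectrum,
               templates = tp, seed = 4, reads_per_sample = 5000,
               error_rate = 0, contaminant_frac = 0.04)
  f <- tempfile(fileext = ".fastq")
  sim <- simulate_reads(sp, tp, tab, lay, f, seed = 5)
  cb <- classify_batch(f, tp, tab, lay,
                       contaminant_ref = synthetic_contaminant())
  s <- cb$stats
  expect_equal(s$assigned + s$ambiguous + s$unmatched + s$contaminant +
                 s$unassigned_index + s$truncated, s$total_reads)
  ids <- rownames(sim$truth)
  expect_equal(cb$counts[ids, c("s1", "s2")], sim$truth[ids, c("s1", "s2")])
  expect_true(all(cb$counts[setdiff(tp$joint_id, ids), ] == 0))
  expect_equal(s$contaminant, sum(sim$contaminant))
  expect_equal(s$ambiguous + s$unmatched + s$unassigned_index, 0L)

  # empty FASTQ gives a zero table
  ef <- write_fastq(character(0), tempfile(fileext = ".fastq"))
  cb0 <- classify_batch(ef, tp, tab, lay)
  expect_equal(sum(cb0$counts), 0L)
  expect_equal(cb0$stats$total_reads, 0L)
})

test_that("with sequencing errors, recovered fractions stay within three
           binomial standard errors of truth", {
  fx <- classer_fixture()
  tp <- fx$templates; lay <- fx$layout
  tab <- sample_index_table(default_sample_indexes(1), "s1")
  n_rep <- 100; n_reads <- 1000
  sp <- make_spectrum("wt_24h", tp, seed = 8, reads_per_sample = n_reads,
                      error_rate = 0.01, contaminant_frac = 0)
  # the 3-SE band is a sampling-noise yardstick, so it applies to joints
  # detectable at this depth (>= 1 expected read); the long tail below one
  # expected read is instead bounded by total stray mass
  ids <- names(sp$freqs)[sp$freqs * n_reads >= 1]
  rare <- setdiff(names(sp$freqs), ids)
  within <- matrix(NA, n_rep, length(ids), dimnames = list(NULL, ids))
  stray <- numeric(n_rep)
  f <- tempfile(fileext = ".fastq")
  for (rep in seq_len(n_rep)) {
    sim <- simulate_reads(list(s1 = sp), tp, tab, lay, f, seed = 1000 + rep)
    cb <- classify_batch(f, tp, tab, lay)
    tot <- sum(cb$counts[tp$joint_id, "s1"])
    frac <- cb$counts[ids, "s1"] / tot
    se <- sqrt(sp$freqs[ids] * (1 - sp$freqs[ids]) / tot)
    within[rep, ] <- abs(frac - sp$freqs[ids]) <= 3 * se
    stray[rep] <- sum(pmax(0, cb$counts[rare, "s1"] -
                             sim$truth[rare, "s1"])) / tot
  }
  expect_true(all(colMeans(within) >= 0.95))
  # cross-talk into joints below one expected read stays under 1% of reads
  expect_lt(mean(stray), 0.01)
})

test_that("count tables round-trip through TSV", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("precise", "a", "ambiguous"),
                                         c("s1", "s2")))
  p <- tempfile(fileext = ".tsv")
  write_count_table(m, p)
  expect_identical(read_count_table(p), m)
})
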