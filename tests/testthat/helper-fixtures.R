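# Shared fixtures: small loci built in code, a mid-size locus for classifier
# tests, and independent brute-force oracles.

# 14 bp toy with a 4-nt 3' overhang at positions 5..8 ("CGTA")
toy_locus <- function() dsb_locus("AAAACGTACGTTTT", cut_pos = 8, overhang_len = 4)

# toy whose overhang "CACA" has a terminal 2-base repeat, so the M = 2
# partial-annealing fill-in joint (+CA) is physically valid
repeat_locus <- function()
  dsb_locus(paste0("AAAAG", "CACA", "TTTTTGG"), cut_pos = 9, overhang_len = 4)

# 80 bp locus + short-read layout for classifier tests
classer_fixture <- function() {
  set.seed(424242)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  s <- paste0(substr(s, 1, 26), "CACA", substr(s, 31, 80))  # overhang 27..30
  locus <- dsb_locus(s, cut_pos = 30, overhang_len = 4, name = "classer")
  layout <- read_layout(index_len = 6, read_len = 46)
  templates <- enumerate_joints(locus, layout, L_max = 2, R_max = 2, M_max = 4)
  list(locus = locus, layout = layout, templates = templates)
}

# random valid locus for property tests
random_locus <- function(n = 40, v = NULL) {
  if (is.null(v)) v <- sample(0:6, 1)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  t <- sample(seq(v + 1, n - max(v, 1)), 1)
  dsb_locus(s, cut_pos = t, overhang_len = v)
}

# Independent brute-force product enumeration: joins every retained left
# fragment to every retained right fragment either bluntly (with optional
# non-templated insertion) or by merging a suffix-prefix overlap of m
# identical bases, then deduplicates strings.
oracle_products <- function(locus, L_max, R_max, M_max,
                            ins_alpha = c("A", "C", "G", "T")) {
  s <- locus$top_strand; t <- locus$cut_pos
  v <- locus$overhang_len; n <- nchar(s)
  ins <- c("", ins_alpha, as.vector(outer(ins_alpha, ins_alpha, paste0)))
  out <- character(0)
  for (L in 0:L_max) for (R in 0:R_max) {
    left <- substr(s, 1, t - L)
    right <- substr(s, t - v + R + 1, n)
    for (ii in ins) out <- c(out, paste0(left, ii, right))
    if (M_max > 0) for (m in seq_len(M_max)) {
      if (m <= nchar(left) && m <= nchar(right) &&
          substr(left, nchar(left) - m + 1, nchar(left)) ==
            substr(right, 1, m))
        out <- c(out, paste0(left, substr(right, m + 1, nchar(right))))
    }
  }
  sort(unique(out))
}

# sample a random valid descriptor on a locus within limits
random_descriptor <- function(locus, L_max = 3, R_max = 3, M_max = 6) {
  v <- locus$overhang_len
  repeat {
    L <- sample(0:L_max, 1); R <- sample(0:R_max, 1)
    if (stats::runif(1) < 0.3) {
      M <- 0L
      I <- paste(sample(c("A", "C", "G", "T"), sample(0:2, 1), replace = TRUE),
                 collapse = "")
    } else {
      M <- sample(0:M_max, 1); I <- ""
    }
    if (nhejseq:::descriptor_valid(L, R, M, I, locus))
      return(joint_descriptor(L, R, M, I, v))
  }
}

write_fastq <- function(reads, path) {
  rec <- if (length(reads))
    paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
           strrep("I", nchar(reads))) else character(0)
  writeLines(rec, path)
  path
}
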