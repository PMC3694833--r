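# Synthetic-read generation: seeded joint spectra over an enumerated joint
# space, indexed FASTQ reads with i.i.d. substitution errors and a
# contaminant spike-in, plus NB count tables for the differential stage.
# Every dataset is emitted together with its planted ground truth.

#' Synthetic contaminant reference
#'
#' A deterministic random sequence standing in for a spike-in control
#' library (such as PhiX) so that the contaminant-filter path is testable
#' without any external reference. Clearly synthetic: it shares no k-mers
#' with real genomes by anything but chance.
#'
#' @param length Sequence length (default 5000).
#' @param seed Seed for the draw.
#' @return Character scalar.
#' @export
synthetic_contaminant <- function(length = 5000L, seed = 7L) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Build a joint spectrum for a study condition
#'
#' Spectra encode the repair outcome frequencies the assay produces under
#' prolonged cutting of a chromosomal site:
#' * `pre_induction`: 98.5% precise (intact cut sites dominate before
#'   induction);
#' * `wt_24h` / `k466a_24h`: 60% precise / 40% imprecise after 24 h of
#'   continuous re-cleavage, the imprecise mass spread over the joint space
#'   as a seeded symmetric Dirichlet draw (concentration 0.3) giving the
#'   long-tailed, few-major-joints profile such assays show;
#' * `dnl4del_24h`: 97% precise, 3% imprecise (ligase-null cells retain
#'   mostly uncut alleles).
#'
#' The `k466a_24h` spectrum starts from the same Dirichlet base as `wt_24h`
#' (same `seed`) and plants exact fold changes on major joints: `n_down`
#' decreases on the largest joints and `n_up` increases on a
#' mass-balancing set, so the overall major-joint frequency stays similar
#' between the two strains while individual joints differ — emulating a
#' catalytic-mutant strain whose imprecise joining profile differs
#' joint-by-joint from wild type. Build the wild-type and mutant spectra
#' with the same seed so they share their base profile.
#'
#' @param kind One of `"pre_induction"`, `"wt_24h"`, `"k466a_24h"`,
#'   `"dnl4del_24h"`.
#' @param templates A `joint_space` with read templates.
#' @param seed Mandatory seed.
#' @param reads_per_sample Default read budget carried by the spectrum.
#' @param error_rate Per-base substitution error rate carried by the
#'   spectrum (default 0.002, a typical short-read substitution rate).
#' @param contaminant_frac Fraction of reads drawn from the contaminant
#'   reference (default 0.5, emulating a heavy control spike-in).
#' @param concentration Dirichlet concentration of the imprecise profile.
#' @param n_up,n_down Number of planted increased / decreased joints
#'   (`k466a_24h` only; defaults 15 and 16).
#' @param fold Planted fold change (default 3).
#' @return List of class `joint_spectrum`: `kind`, `freqs` (named,
#'   sums to 1), `reads_per_sample`, `error_rate`, `contaminant_frac`,
#'   `seed`, and for `k466a_24h` the planted `up` / `down` joint ids.
#' @export
make_spectrum <- function(kind = c("pre_induction", "wt_24h", "k466a_24h",
                                   "dnl4del_24h"),
                          templates, seed, reads_per_sample = 100000L,
                          error_rate = 0.002, contaminant_frac = 0.5,
                          concentration = 0.3, n_up = 15L, n_down = 16L,
                          fold = 3) {
  kind <- match.arg(kind)
  stopifnot(inherits(templates, "joint_space"))
  if (missing(seed)) stop("a seed is mandatory")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  precise_frac <- switch(kind, pre_induction = 0.985, wt_24h = 0.60,
                         k466a_24h = 0.60, dnl4del_24h = 0.97)
  # only joints whose read template is unique are usable as planted truth;
  # duplicated templates are inherently ambiguous to the classifier
  body <- templates$read_template
  usable <- !(duplicated(body) | duplicated(body, fromLast = TRUE))
  impr_ids <- templates$joint_id[usable & templates$joint_id != "precise"]
  K <- length(impr_ids)
  if (K < n_up + n_down) stop("joint space too small for the planted design")

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  g <- stats::rgamma(K, shape = concentration)
  g[g <= 0] <- .Machine$double.eps
  base <- g / sum(g)
  impr_mass <- 1 - precise_frac
  w <- base
  up <- down <- character(0)
  if (kind == "k466a_24h") {
    # Decreased joints come from the largest base joints; increased joints
    # are then chosen (greedily, deterministically) so the planted mass
    # gained roughly cancels the mass lost. This keeps the overall major-
    # joint frequency similar between the two strains, mirroring the
    # experiment this emulates, and leaves median-of-ratios size factors
    # undistorted by composition shift.
    ord <- order(base, decreasing = TRUE)
    down_idx <- ord[seq_len(n_down)]
    target_up <- sum(base[down_idx]) * (1 - 1 / fold) / (fold - 1)
    candidates <- ord[-seq_len(n_down)]
    # the window of n_up consecutive ranks whose mass best matches the target
    cs <- cumsum(base[candidates])
    win <- cs[n_up:length(cs)] - c(0, cs)[seq_len(length(cs) - n_up + 1L)]
    best <- which.min(abs(win - target_up))
    up_idx <- candidates[best:(best + n_up - 1L)]
    planted <- c(up_idx, down_idx)
    w[up_idx] <- base[up_idx] * fold
    w[down_idx] <- base[down_idx] / fold
    rest <- setdiff(seq_len(K), planted)
    rest_target <- 1 - sum(w[planted])
    if (rest_target < 0.1 * sum(base[rest]))
      stop("planted fold changes leave too little mass for unplanted joints; ",
           "reduce fold or the number of planted joints")
    w[rest] <- base[rest] * rest_target / sum(base[rest])
    up <- impr_ids[up_idx]; down <- impr_ids[down_idx]
  }
  freqs <- c(precise = precise_frac,
             stats::setNames(w / sum(w) * impr_mass, impr_ids))
  structure(list(kind = kind, freqs = freqs,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 contaminant_frac = contaminant_frac,
                 seed = seed, up = up, down = down),
            class = "joint_spectrum")
}

#' @export
print.joint_spectrum <- function(x, ...) {
  cat(sprintf("<joint_spectrum '%s'> %d joints, precise %.3f, %d planted changes\n",
              x$kind, length(x$freqs), x$freqs[["precise"]],
              length(x$up) + length(x$down)))
  invisible(x)
}

#' Simulate an indexed FASTQ from joint spectra
#'
#' Writes one FASTQ holding all samples: per sample, joint reads are drawn
#' from the spectrum (multinomial), rendered as index + read template, and
#' subjected to i.i.d. substitution errors over the whole read (index
#' included); contaminant reads are random windows of either strand of the
#' contaminant reference. Sequencing indel errors are deliberately not
#' modelled. Returns the exact planted truth.
#'
#' @param spectra Named list of `joint_spectrum` objects, one per sample;
#'   names are the sample labels.
#' @param templates A `joint_space` with read templates.
#' @param table A [sample_index_table] covering all sample labels.
#' @param layout A [read_layout].
#' @param out_fastq Output path (gzipped when it ends in `.gz`).
#' @param seed Mandatory seed; the whole dataset is deterministic given it.
#' @param contaminant_ref Contaminant reference sequence (defaults to
#'   [synthetic_contaminant()]) used when any spectrum has a positive
#'   contaminant fraction.
#' @param reads_per_sample Optional override of each spectrum's read budget.
#' @return List: `truth` (data.frame sample x joint_id planted counts),
#'   `contaminant` (named integer, planted contaminant reads per sample),
#'   `fastq` (the path).
#' @export
simulate_reads <- function(spectra, templates, table, layout, out_fastq,
                           seed, contaminant_ref = NULL,
                           reads_per_sample = NULL) {
  stopifnot(inherits(templates, "joint_space"), inherits(layout, "read_layout"))
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(names(spectra)) || any(!nzchar(names(spectra))))
    stop("spectra must be a named list (names = sample labels)")
  idx_of <- stats::setNames(names(table), unname(unclass(table)))
  if (any(!names(spectra) %in% names(idx_of)))
    stop("every sample needs an index in the sample index table")
  tmpl_body <- stats::setNames(substr(templates$read_template,
                                      layout$index_len + 1L, layout$read_len),
                               templates$joint_id)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)

  need_cont <- any(vapply(spectra, function(s) s$contaminant_frac > 0,
                          logical(1)))
  if (need_cont && is.null(contaminant_ref))
    contaminant_ref <- synthetic_contaminant()

  all_seq <- character(0)
  truth <- list(); cont_counts <- integer(0)
  for (smp in names(spectra)) {
    sp <- spectra[[smp]]
    n <- if (is.null(reads_per_sample)) sp$reads_per_sample
         else as.integer(reads_per_sample)
    n_cont <- as.integer(round(sp$contaminant_frac * n))
    n_joint <- n - n_cont
    ids <- names(sp$freqs)
    missing_ids <- setdiff(ids, names(tmpl_body))
    if (length(missing_ids))
      stop("spectrum joints absent from the template set: ",
           paste(utils::head(missing_ids, 3), collapse = ", "))
    planted <- as.vector(stats::rmultinom(1, n_joint, sp$freqs))
    names(planted) <- ids
    reads <- paste0(idx_of[smp], tmpl_body[rep.int(ids, planted)])
    if (sp$error_rate > 0 && length(reads)) {
      nerr <- stats::rbinom(length(reads), nchar(reads), sp$error_rate)
      mut <- which(nerr > 0L)
      for (i in mut) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(length(ch), nerr[i])
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        reads[i] <- paste(ch, collapse = "")
      }
    }
    if (n_cont > 0L) {
      strands <- c(contaminant_ref, revcomp(contaminant_ref))
      src <- sample.int(2L, n_cont, replace = TRUE)
      start <- sample.int(nchar(contaminant_ref) - layout$read_len + 1L,
                          n_cont, replace = TRUE)
      reads <- c(reads, substring(strands[src], start,
                                  start + layout$read_len - 1L))
    }
    reads <- sample(reads)
    all_seq <- c(all_seq, reads)
    truth[[smp]] <- planted
    cont_counts[smp] <- n_cont
  }
  all_seq <- sample(all_seq)
  con <- if (grepl("\\.gz$", out_fastq)) gzfile(out_fastq, "w")
         else file(out_fastq, "w")
  on.exit(close(con), add = TRUE)
  if (length(all_seq))
    writeLines(paste0("@read_", seq_along(all_seq), "\n", all_seq, "\n+\n",
                      strrep("I", nchar(all_seq))), con)
  truth_df <- do.call(cbind, truth)
  list(truth = truth_df, contaminant = cont_counts, fastq = out_fastq)
}

#' Simulate an NB count table for two conditions
#'
#' Draws joint counts for `r` replicates per condition from negative
#' binomial distributions with per-joint means `frequency x library size`
#' and common dispersion `alpha`; `alpha = 0` gives Poisson counts.
#'
#' @param spectrum_A,spectrum_B `joint_spectrum` objects (or bare named
#'   frequency vectors) for the two conditions.
#' @param library_sizes Numeric vector of length `2 * r`: total expected
#'   joint reads per sample, condition A replicates first.
#' @param dispersion NB dispersion (default 0.002, tight technical
#'   replicates).
#' @param seed Mandatory seed.
#' @param condition_names Labels for the two conditions.
#' @return List: `counts` (integer matrix joints x samples),
#'   `condition_map` (named vector sample -> condition), `truth`
#'   (expected fractions per condition and planted `up` / `down` ids).
#' @export
simulate_count_table <- function(spectrum_A, spectrum_B, library_sizes,
                                 dispersion = 0.002, seed,
                                 condition_names = c("A", "B")) {
  if (missing(seed)) stop("a seed is mandatory")
  fA <- if (inherits(spectrum_A, "joint_spectrum")) spectrum_A$freqs else spectrum_A
  fB <- if (inherits(spectrum_B, "joint_spectrum")) spectrum_B$freqs else spectrum_B
  stopifnot(identical(names(fA), names(fB)))
  r <- length(library_sizes) / 2
  if (r != floor(r) || r < 2) stop("need at least 2 replicates per condition")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  samples <- c(paste0(condition_names[1], "_r", seq_len(r)),
               paste0(condition_names[2], "_r", seq_len(r)))
  cmap <- stats::setNames(rep(condition_names, each = r), samples)
  counts <- matrix(0L, nrow = length(fA), ncol = length(samples),
                   dimnames = list(names(fA), samples))
  for (j in seq_along(samples)) {
    f <- if (cmap[j] == condition_names[1]) fA else fB
    mu <- f * library_sizes[j]
    counts[, j] <- if (dispersion <= 0) stats::rpois(length(mu), mu)
                   else stats::rnbinom(length(mu), size = 1 / dispersion,
                                       mu = mu)
  }
  up <- if (inherits(spectrum_B, "joint_spectrum")) spectrum_B$up else character(0)
  down <- if (inherits(spectrum_B, "joint_spectrum")) spectrum_B$down else character(0)
  list(counts = counts, condition_map = cmap,
       truth = list(freq_A = fA, freq_B = fB, up = up, down = down))
}
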