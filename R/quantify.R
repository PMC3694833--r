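# Summary quantities: per-sample joint fractions, the precise /
# major-imprecise / other categorisation, and the colony-assay arithmetic
# used to score suicide-deletion survivors.

SPECIAL_ROWS <- c("ambiguous", "unmatched", "contaminant", "unassigned_index")

joint_rows <- function(counts) setdiff(rownames(counts), SPECIAL_ROWS)

#' Per-sample joint fractions
#'
#' Each joint's count divided by the sample's total over joint rows only;
#' the special rows (`ambiguous`, `unmatched`, ...) are excluded from the
#' denominator and reported separately as fractions of all reads in the
#' table.
#'
#' @param counts Integer count matrix (joints + special rows x samples) or
#'   an `nhej_counts` object.
#' @return Numeric matrix of fractions over the joint rows (columns sum
#'   to 1), with any special-row fractions in attribute `special`.
#' @export
joint_fractions <- function(counts) {
  if (inherits(counts, "nhej_counts")) counts <- counts$counts
  jr <- joint_rows(counts)
  joints <- counts[jr, , drop = FALSE]
  tot <- colSums(joints)
  if (any(tot == 0))
    stop("zero joint-read total in sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  fr <- sweep(joints, 2, tot, "/")
  sp <- setdiff(rownames(counts), jr)
  if (length(sp))
    attr(fr, "special") <- sweep(counts[sp, , drop = FALSE], 2,
                                 colSums(counts), "/")
  fr
}

#' Categorise joints as precise / major imprecise / other
#'
#' The precise joint is its own category. An imprecise joint is
#' `major_imprecise` when its fraction reaches `threshold` (>=, default
#' 0.1%) in at least one sample; the rest are `other`.
#'
#' @param fractions Fraction matrix from [joint_fractions()].
#' @param threshold Major-joint frequency threshold (default 0.001).
#' @param precise_id Row name of the precise joint.
#' @return Named character vector mapping joint_id to category.
#' @export
categorize_joints <- function(fractions, threshold = 0.001,
                              precise_id = "precise") {
  ids <- rownames(fractions)
  cat <- ifelse(apply(fractions, 1, max) >= threshold, "major_imprecise",
                "other")
  cat[ids == precise_id] <- "precise"
  stats::setNames(cat, ids)
}

#' Per-sample category fractions
#'
#' @param fractions Fraction matrix.
#' @param categories Output of [categorize_joints()].
#' @return Matrix categories x samples; columns sum to 1.
#' @export
category_fractions <- function(fractions, categories) {
  lev <- c("precise", "major_imprecise", "other")
  out <- vapply(lev, function(l)
    colSums(fractions[categories == l, , drop = FALSE]),
    numeric(ncol(fractions)))
  t(matrix(out, ncol = length(lev), dimnames = list(colnames(fractions), lev)))
}

round_half_up <- function(x) floor(x + 0.5)

#' Percent precise joining from re-cleavage counts
#'
#' Survivor colonies whose repaired allele can be re-cleaved by the inducing
#' endonuclease used precise religation; the percentage is the re-cleavable
#' fraction of tested survivors, rounded half-up to an integer.
#'
#' @param recleavable Number of re-cleavable survivors.
#' @param tested_recleavage Number of survivors tested.
#' @return Integer percent.
#' @examples
#' precise_percent(190, 216)  # 88
#' @export
precise_percent <- function(recleavable, tested_recleavage) {
  if (tested_recleavage <= 0) stop("tested_recleavage must be > 0")
  if (recleavable > tested_recleavage)
    stop("recleavable cannot exceed tested_recleavage")
  as.integer(round_half_up(100 * recleavable / tested_recleavage))
}

#' Outcome percentages among marker-loss survivor colonies
#'
#' Survivors that lost the internal cassette marker (`met_minus` of
#' `total_colonies`) are split by a junction-flanking PCR on a tested
#' subsample: PCR-positive colonies carry an imprecise end-joining junction,
#' PCR-negative ones a large deletion. Each class is extrapolated from the
#' tested subsample to all marker-loss colonies and expressed as a half-up
#' rounded integer percent of all colonies analysed; `other` is the
#' marker-retaining remainder. The three percentages sum to 100 +/- 1
#' (rounding).
#'
#' @param met_minus Marker-loss colonies.
#' @param total_colonies All colonies analysed.
#' @param pcr_positive Junction-PCR-positive colonies among those tested.
#' @param pcr_tested Marker-loss colonies tested by PCR.
#' @return Named integer vector `large_deletion_pct`, `imprecise_pct`,
#'   `other_pct`.
#' @examples
#' ade_minus_summary(32, 141, 0, 26)   # 23 / 0 / 77
#' @export
ade_minus_summary <- function(met_minus, total_colonies, pcr_positive,
                              pcr_tested) {
  if (pcr_tested <= 0 || total_colonies <= 0) stop("zero denominator")
  if (!(pcr_positive <= pcr_tested && pcr_tested <= met_minus &&
        met_minus <= total_colonies))
    stop("need pcr_positive <= pcr_tested <= met_minus <= total_colonies")
  met_frac <- met_minus / total_colonies
  c(large_deletion_pct =
      as.integer(round_half_up(100 * (1 - pcr_positive / pcr_tested) * met_frac)),
    imprecise_pct =
      as.integer(round_half_up(100 * (pcr_positive / pcr_tested) * met_frac)),
    other_pct = as.integer(round_half_up(100 * (1 - met_frac))))
}

#' Read colony assay records from TSV
#'
#' Expects a header and a `strain` column; remaining columns are integer
#' counts (`recleavable`, `tested_recleavage` for re-cleavage records;
#' `met_minus`, `total_colonies`, `pcr_positive`, `pcr_tested` for
#' marker-loss records). Missing fields may be absent or NA.
#'
#' @param path TSV path.
#' @return data.frame of colony records.
#' @export
read_colony_records <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
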