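# Two-condition differential joint-frequency testing on raw counts, in the
# classic negative-binomial count-table style: median-of-ratios size factors,
# method-of-moments dispersion with a conservative mean-trend blend, a
# conditional NB exact test per joint, and Bonferroni adjustment.

#' Median-of-ratios size factors
#'
#' For each sample, the median over joints of the ratio of its count to the
#' joint's geometric mean across samples. Joints with a zero count in any
#' sample drop out of the median (their geometric mean is zero).
#'
#' @param counts Integer count matrix (joints x samples); special category
#'   rows are excluded automatically.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "nhej_counts")) counts <- counts$counts
  counts <- counts[joint_rows(counts), , drop = FALSE]
  if (ncol(counts) < 2L) stop("need at least two samples")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no joint has positive counts in every sample")
  apply(counts, 2, function(k) exp(stats::median(log(k[use]) - loggeo[use])))
}

#' Method-of-moments NB dispersion per joint
#'
#' Counts are normalised by the size factors and pooled within condition;
#' per condition, the dispersion is `max(0, (s^2 - mu) / mu^2)` (so that
#' `var = mu + alpha * mu^2`), and the per-joint estimate is the mean over
#' conditions with at least two replicates. With few replicates these
#' estimates are noisy, so the default `"blend"` method also fits a
#' mean-dispersion trend (gamma-family regression of the positive estimates
#' on `1/mu`) and takes, per joint, the maximum of the fitted and the
#' individual value, with a small floor; `"per_joint"` returns the raw
#' clamped estimates (zero for replicates with identical normalised counts).
#' The trend is fitted by least squares of the unclamped per-joint moment
#' estimates on `1/mu` over joints with adequate counts (mean normalised
#' count >= 5): clamping before fitting would bias the trend upward, and
#' low-count joints contribute mostly estimation noise.
#'
#' @param counts Count matrix (joints x samples).
#' @param factors Size factors from [size_factors()].
#' @param condition_map Named character vector sample -> condition (two
#'   conditions).
#' @param method `"blend"` (default) or `"per_joint"`.
#' @param floor Lower bound applied under `"blend"` (default 1e-8).
#' @return Numeric vector of dispersions, one per joint row.
#' @export
estimate_dispersion <- function(counts, factors, condition_map,
                                method = c("blend", "per_joint"),
                                floor = 1e-8) {
  method <- match.arg(method)
  if (inherits(counts, "nhej_counts")) counts <- counts$counts
  counts <- counts[joint_rows(counts), , drop = FALSE]
  cond <- condition_map[colnames(counts)]
  q <- sweep(counts, 2, factors, "/")
  per_cond_raw <- sapply(unique(cond), function(cc) {
    qq <- q[, cond == cc, drop = FALSE]
    if (ncol(qq) < 2L) return(rep(NA_real_, nrow(qq)))
    mu <- rowMeans(qq)
    s2 <- apply(qq, 1, stats::var)
    a <- (s2 - mu) / mu^2
    a[!is.finite(a)] <- NA_real_
    a
  })
  if (is.null(dim(per_cond_raw)))
    per_cond_raw <- matrix(per_cond_raw, nrow = nrow(q))
  raw <- rowMeans(per_cond_raw, na.rm = TRUE)
  raw[is.nan(raw)] <- 0
  alpha <- pmax(raw, 0)
  if (method == "per_joint") return(stats::setNames(alpha, rownames(counts)))

  mu_all <- rowMeans(q)
  use <- is.finite(raw) & mu_all >= 5
  fitted <- rep(0, length(alpha))
  if (sum(use) >= 10L) {
    fit <- tryCatch(stats::lm(raw[use] ~ I(1 / mu_all[use])),
                    error = function(e) NULL)
    co <- if (is.null(fit)) NULL else stats::coef(fit)
    if (!is.null(co) && all(is.finite(co))) {
      fitted[mu_all > 0] <- pmax(co[1] + co[2] / mu_all[mu_all > 0], 0)
    } else {
      fitted <- rep(max(0, stats::median(raw[use])), length(alpha))
    }
  } else if (any(use)) {
    fitted <- rep(max(0, stats::median(raw[use])), length(alpha))
  }
  stats::setNames(pmax(alpha, fitted, floor), rownames(counts))
}

#' Conditional NB exact test for one joint
#'
#' Given the summed counts of the two conditions and the summed size
#' factors, conditions on the total `k = kA + kB`: under the null the
#' common per-unit mean is `k / (sA + sB)`, each margin is negative binomial
#' with its scaled mean and the given dispersion, and the p-value is the
#' probability mass of all splits `a + b = k` no more likely than the
#' observed one, renormalised over all splits. `alpha_disp = 0` degenerates
#' to the Poisson / exact-binomial limit.
#'
#' @param kA,kB Summed counts in each condition.
#' @param sA,sB Summed size factors of each condition.
#' @param alpha_disp NB dispersion (variance = mu + alpha * mu^2).
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(kA, kB, sA = 1, sB = 1, alpha_disp = 0) {
  kA <- as.numeric(kA); kB <- as.numeric(kB)
  if (kA < 0 || kB < 0) stop("counts must be non-negative")
  k <- kA + kB
  if (k == 0) return(1)
  mu <- k / (sA + sB)
  mA <- mu * sA; mB <- mu * sB
  a <- 0:k
  if (alpha_disp <= 0) {
    lp <- stats::dpois(a, mA, log = TRUE) + stats::dpois(k - a, mB, log = TRUE)
  } else {
    sz <- 1 / alpha_disp
    lp <- stats::dnbinom(a, size = sz, mu = mA, log = TRUE) +
          stats::dnbinom(k - a, size = sz, mu = mB, log = TRUE)
  }
  lobs <- lp[kA + 1]
  m <- max(lp)
  w <- exp(lp - m)
  p <- sum(w[lp <= lobs + 1e-7]) / sum(w)
  min(max(p, .Machine$double.xmin), 1)
}

#' Differential joint-frequency table
#'
#' Tests every joint for a frequency difference between two conditions:
#' size factors by median of ratios, dispersion per
#' [estimate_dispersion()], the conditional NB exact test on summed counts
#' per condition, and Bonferroni adjustment over all joints tested. The
#' result also carries MA-plot coordinates (`base_mean`,
#' `log2_fold_change`), a significance direction at `p_adj < alpha`, and a
#' `is_major` flag for joints whose fraction reaches `major_threshold` in
#' at least one sample.
#'
#' @param counts Count matrix (joints + special rows x samples).
#' @param condition_map Named character vector sample -> condition; exactly
#'   two conditions.
#' @param reference Which condition is the reference `A` (fold changes are
#'   `B` vs `A`); defaults to the alphabetically first condition.
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.005).
#' @param major_threshold Major-joint fraction threshold (default 0.001).
#' @param dispersion_method Passed to [estimate_dispersion()].
#' @return data.frame of class `nhej_diff`, one row per joint: `joint_id`,
#'   `base_mean`, `log2_fold_change`, `p_value`, `p_adj`, `direction`
#'   (`increased` / `decreased` / `ns`), `is_major`.
#' @export
nhej_diff <- function(counts, condition_map, alpha = 0.005,
                      major_threshold = 0.001,
                      dispersion_method = c("blend", "per_joint"),
                      reference = NULL) {
  if (inherits(counts, "nhej_counts")) counts <- counts$counts
  counts <- counts[joint_rows(counts), , drop = FALSE]
  condition_map <- condition_map[colnames(counts)]
  if (any(is.na(condition_map)))
    stop("condition_map must cover every sample column")
  conds <- sort(unique(unname(condition_map)))
  if (!is.null(reference)) {
    if (!reference %in% conds) stop("reference is not one of the conditions")
    conds <- c(reference, setdiff(conds, reference))
  }
  if (length(conds) != 2L) stop("exactly two conditions are required")
  tabn <- table(condition_map)
  if (any(tabn == 0)) stop("a condition has zero replicates")
  A <- names(condition_map)[condition_map == conds[1]]
  B <- names(condition_map)[condition_map == conds[2]]

  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, condition_map,
                              method = match.arg(dispersion_method))
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)
  mA <- rowMeans(q[, A, drop = FALSE])
  mB <- rowMeans(q[, B, drop = FALSE])
  l2fc <- log2(mB / mA)
  kA <- rowSums(counts[, A, drop = FALSE])
  kB <- rowSums(counts[, B, drop = FALSE])
  sA <- sum(sf[A]); sB <- sum(sf[B])
  pv <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(kA[i], kB[i], sA, sB, disp[i]), numeric(1))
  padj <- stats::p.adjust(pv, method = "bonferroni")
  fr <- joint_fractions(counts)
  is_major <- apply(fr, 1, max) >= major_threshold
  direction <- ifelse(padj < alpha,
                      ifelse(l2fc > 0, "increased", "decreased"), "ns")
  out <- data.frame(joint_id = rownames(counts), base_mean = base_mean,
                    log2_fold_change = l2fc, p_value = pv, p_adj = padj,
                    direction = direction, is_major = is_major,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "conditions") <- conds
  attr(out, "alpha") <- alpha
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- disp
  class(out) <- c("nhej_diff", "data.frame")
  out
}

#' @export
print.nhej_diff <- function(x, ...) {
  conds <- attr(x, "conditions")
  cat(sprintf("<nhej_diff> %s vs %s: %d joints tested, alpha = %g\n",
              conds[2], conds[1], nrow(x), attr(x, "alpha")))
  cat(sprintf("  increased %d, decreased %d (of which major: %d / %d)\n",
              sum(x$direction == "increased"),
              sum(x$direction == "decreased"),
              sum(x$direction == "increased" & x$is_major),
              sum(x$direction == "decreased" & x$is_major)))
  invisible(x)
}

#' @export
summary.nhej_diff <- function(object, ...) {
  sig <- object[object$direction != "ns", , drop = FALSE]
  sig <- sig[order(sig$p_adj), , drop = FALSE]
  structure(list(conditions = attr(object, "conditions"),
                 alpha = attr(object, "alpha"),
                 n_tested = nrow(object),
                 n_major = sum(object$is_major),
                 increased = sum(object$direction == "increased"),
                 decreased = sum(object$direction == "decreased"),
                 increased_major = sum(object$direction == "increased" &
                                         object$is_major),
                 decreased_major = sum(object$direction == "decreased" &
                                         object$is_major),
                 top = utils::head(as.data.frame(sig), 10)),
            class = "summary.nhej_diff")
}

#' @export
print.summary.nhej_diff <- function(x, ...) {
  cat(sprintf("Differential joint frequency: %s vs %s\n",
              x$conditions[2], x$conditions[1]))
  cat(sprintf("  %d joints tested, %d major (>= threshold in some sample)\n",
              x$n_tested, x$n_major))
  cat(sprintf("  significant at Bonferroni p < %g: %d increased, %d decreased\n",
              x$alpha, x$increased, x$decreased))
  cat(sprintf("  among major joints: %d increased, %d decreased\n",
              x$increased_major, x$decreased_major))
  if (nrow(x$top)) { cat("Top joints:\n"); print(x$top) }
  invisible(x)
}

#' MA plot of a differential result
#'
#' Normalised mean count (log10 x-axis) against log2 fold change;
#' significant joints are highlighted.
#'
#' @param x An `nhej_diff` result.
#' @param highlight Colour for significant joints.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nhej_diff <- function(x, highlight = "red", ...) {
  ok <- is.finite(x$log2_fold_change) & x$base_mean > 0
  graphics::plot(x$base_mean[ok], x$log2_fold_change[ok], log = "x",
                 pch = 20, col = ifelse(x$direction[ok] != "ns",
                                        highlight, "grey40"),
                 xlab = "normalised mean count",
                 ylab = "log2 fold change", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write a differential result as TSV
#'
#' @param x An `nhej_diff` result.
#' @param path File path.
#' @export
write_diff_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
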