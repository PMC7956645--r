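# Differential expression between sterile (S) and fertile (F) libraries at
# one stage: median-of-ratios normalisation, Welch's t-test on
# log2(normalised count + 0.5), Benjamini-Hochberg adjustment. This is a
# deliberately simple, fully documented DE method; externally produced DE
# tables (feature_id, log2fc, padj) are accepted downstream by build_pairs()
# so the integration layer can also run on results from a dedicated NB
# fitter.

#' Median-of-ratios size factors
#'
#' For each library, the median across reference features of the ratio
#' count / geometric mean, where reference features are those with positive
#' counts in every library. Falls back to total-count scaling (library sums
#' normalised to their geometric mean) with a warning when no feature is
#' positive everywhere.
#'
#' @param cm A [count_matrix()] or a plain counts matrix.
#' @return Named positive numeric vector, one factor per library.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  stopifnot(is.matrix(counts))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature positive in all libraries; using total-count scaling")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  ref <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  apply(ref / geo, 2L, stats::median)
}

# Welch two-sample test on a numeric vector split by a 2-level grouping;
# returns the two-sided p-value. Degenerate inputs (zero variance in both
# groups) cannot feed a t statistic: identical groups get p = 1, separated
# constant groups get p ~ 0.
welch_p <- function(x, grp) {
  p <- tryCatch(stats::t.test(x[grp], x[!grp])$p.value, error = function(e) NA)
  if (is.na(p)) {
    p <- if (isTRUE(all.equal(mean(x[grp]), mean(x[!grp])))) 1 else
      .Machine$double.eps
  }
  p
}

#' Per-feature S-vs-F differential expression at one stage
#'
#' Normalises the stage's libraries by [size_factors()], then per feature
#' computes log2fc = log2((mean normalised S + 0.5) / (mean normalised F +
#' 0.5)), a Welch t-test p-value on log2(normalised + 0.5), and BH-adjusted
#' p-values within the stage. Direction is called against the default
#' thresholds (padj < `alpha`, |log2fc| >= `min_abs_log2fc`); use
#' [call_significant()] to re-call at other thresholds.
#'
#' @param cm A [count_matrix()].
#' @param stage 6 or 7.
#' @param alpha,min_abs_log2fc Thresholds used for the `direction` column
#'   (defaults 0.05 and 1, i.e. adjusted p < 0.05 and fold change >= 2).
#' @param pseudocount Added before every log (default 0.5, bounding log2fc on
#'   zero counts).
#' @return Data.frame of DE records: `feature_id`, `stage`, `log2fc` (S over
#'   F), `p`, `padj`, `direction` in `up`/`down`/`ns`.
#' @export
differential_expression <- function(cm, stage, alpha = 0.05,
                                    min_abs_log2fc = 1, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), stage %in% c(6L, 7L))
  sel <- cm$meta$stage == stage
  counts <- cm$counts[, sel, drop = FALSE]
  cond <- cm$meta$condition[sel]
  if (sum(cond == "S") < 2L || sum(cond == "F") < 2L) {
    stop("need >= 2 replicates per condition at stage ", stage)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  is_s <- cond == "S"
  mean_s <- rowMeans(norm[, is_s, drop = FALSE])
  mean_f <- rowMeans(norm[, !is_s, drop = FALSE])
  log2fc <- log2((mean_s + pseudocount) / (mean_f + pseudocount))
  logn <- log2(norm + pseudocount)
  p <- apply(logn, 1L, welch_p, grp = is_s)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = rownames(counts), stage = stage,
                    log2fc = log2fc, p = p, padj = padj,
                    direction = "ns", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  sig <- out$padj < alpha & abs(out$log2fc) >= min_abs_log2fc
  out$direction[sig & out$log2fc > 0] <- "up"
  out$direction[sig & out$log2fc < 0] <- "down"
  out
}

#' Filter DE records at significance thresholds
#'
#' Keeps records with padj < `alpha` and |log2fc| >= `min_abs_log2fc` and
#' (re)assigns their direction.
#'
#' @param derecords Data.frame from [differential_expression()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_abs_log2fc Minimum |log2fc| (default 1, i.e. fold change 2).
#' @return The retained rows with `direction` recomputed.
#' @export
call_significant <- function(derecords, alpha = 0.05, min_abs_log2fc = 1) {
  stopifnot(alpha > 0, alpha <= 1, min_abs_log2fc >= 0)
  keep_p <- if (alpha >= 1) rep(TRUE, nrow(derecords)) else
    derecords$padj < alpha
  keep <- keep_p & abs(derecords$log2fc) >= min_abs_log2fc
  keep[is.na(keep)] <- FALSE
  out <- derecords[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", "ns"))
  rownames(out) <- NULL
  out
}
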