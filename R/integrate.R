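# Integration of DE miRNAs, DE/measured target genes and cleavage-validated
# events into the final pair report, with regulation-pattern labels (miRNA
# direction / target direction, S compared with F) and cross-stage set
# partitions.

#' Join DE miRNAs with cleavage-validated targets
#'
#' One output row per (significant miRNA, cleavage-validated target). The
#' target's DE record is attached; targets without a significant DE call are
#' retained with direction `"ns"` unless `require_target_de` is set. Events
#' whose miRNA is absent from the miRNA DE table are dropped with a warning.
#'
#' @param de_mirnas miRNA DE table (full, with `direction` set by
#'   [differential_expression()], or already filtered by
#'   [call_significant()]); columns `feature_id`, `stage`, `log2fc`,
#'   `direction`. Rows with direction `"ns"` are not paired.
#' @param de_targets Full target DE table (same columns); may also be an
#'   externally produced table restricted to `feature_id`, `stage`,
#'   `log2fc`, `padj`.
#' @param events Cleavage events from [validate_targets()].
#' @param require_target_de Drop rows whose target is not significantly DE
#'   (default `FALSE`: a validated target with modest fold change is still
#'   reported, labelled by its direction or `"ns"`).
#' @param target_alpha,target_min_abs_log2fc Thresholds used to judge target
#'   significance when `require_target_de = TRUE` (defaults 0.05 and 0; the
#'   pair table is deliberately laxer on target effect size than the DEG
#'   screen).
#' @return Data.frame of pair records ordered by (stage, mirna_id,
#'   target_id): `stage`, `mirna_id`, `target_id`, `mirna_log2fc`,
#'   `mirna_direction`, `target_log2fc`, `target_direction`, `align_start`,
#'   `align_end`, `cleavage_site`, `category`, `pattern`
#'   (e.g. `"down/up"`).
#' @export
build_pairs <- function(de_mirnas, de_targets, events,
                        require_target_de = FALSE,
                        target_alpha = 0.05, target_min_abs_log2fc = 0) {
  stopifnot(is.data.frame(de_mirnas), is.data.frame(de_targets),
            is.data.frame(events))
  if (nrow(events) > 0L) {
    known <- unique(de_mirnas$feature_id)
    orphan <- setdiff(unique(events$mirna_id), known)
    if (length(orphan) > 0L) {
      warning("event(s) reference miRNA(s) absent from the DE table, ",
              "dropped: ", paste(orphan, collapse = ", "))
    }
  }
  rows <- list()
  sig_idx <- which(de_mirnas$direction %in% c("up", "down"))
  for (i in sig_idx) {
    mrec <- de_mirnas[i, ]
    ev <- events[events$mirna_id == mrec$feature_id, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      trec <- de_targets[de_targets$feature_id == e$transcript_id &
                           de_targets$stage == mrec$stage, , drop = FALSE]
      if (nrow(trec) == 0L) next
      trec <- trec[1L, ]
      t_dir <- if ("direction" %in% names(trec)) trec$direction else {
        sig <- !is.na(trec$padj) && trec$padj < target_alpha &&
          abs(trec$log2fc) >= target_min_abs_log2fc
        if (!sig) "ns" else if (trec$log2fc > 0) "up" else "down"
      }
      if (require_target_de) {
        sig <- !is.na(trec$padj) && trec$padj < target_alpha &&
          abs(trec$log2fc) >= target_min_abs_log2fc
        if (!sig || t_dir == "ns") next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stage = mrec$stage, mirna_id = mrec$feature_id,
        target_id = e$transcript_id,
        mirna_log2fc = mrec$log2fc, mirna_direction = mrec$direction,
        target_log2fc = trec$log2fc, target_direction = t_dir,
        align_start = e$start, align_end = e$end,
        cleavage_site = e$site, category = e$category,
        pattern = paste(mrec$direction, t_dir, sep = "/"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(stage = integer(), mirna_id = character(),
                      target_id = character(), mirna_log2fc = numeric(),
                      mirna_direction = character(),
                      target_log2fc = numeric(),
                      target_direction = character(), align_start = integer(),
                      align_end = integer(), cleavage_site = integer(),
                      category = integer(), pattern = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$stage, out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a miRNA-target pair table
#'
#' A miRNA is "multi-target" when it appears in two or more rows; "one-to-one"
#' rows are those whose miRNA has exactly one row. A "pair" at the miRNA
#' grain is a distinct miRNA, so multi-target miRNAs and one-to-one rows
#' together partition the miRNA set.
#'
#' @param pairs Pair table from [build_pairs()] (needs `mirna_id`,
#'   `target_id`, `pattern`).
#' @return List: `rows`, `mirnas` (distinct), `targets` (distinct),
#'   `multi_target_mirnas`, `one_to_one_rows`, `pattern_counts` (named
#'   integer vector summing to `rows`).
#' @export
summarize_pairs <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(rows = 0L, mirnas = 0L, targets = 0L,
                multi_target_mirnas = 0L, one_to_one_rows = 0L,
                pattern_counts = integer(0)))
  }
  per_mirna <- table(pairs$mirna_id)
  list(rows = nrow(pairs),
       mirnas = length(per_mirna),
       targets = length(unique(pairs$target_id)),
       multi_target_mirnas = sum(per_mirna >= 2L),
       one_to_one_rows = sum(per_mirna == 1L),
       pattern_counts = c(table(pairs$pattern)))
}

#' Partition two id sets into unique/shared/unique
#'
#' @param set_stage6,set_stage7 Character vectors of feature ids.
#' @return List `unique6`, `shared`, `unique7`: three disjoint sets whose
#'   union is the input union.
#' @export
venn_partition <- function(set_stage6, set_stage7) {
  a <- unique(set_stage6)
  b <- unique(set_stage7)
  list(unique6 = setdiff(a, b), shared = intersect(a, b),
       unique7 = setdiff(b, a))
}

#' Read the bundled published rice PA64S miRNA-target pair table
#'
#' The printed pair report for the rice PTGMS line PA64S (sterile vs fertile
#' anthers): 17 rows of miRNA, target gene, log2 fold changes with
#' directions, duplex alignment range, validated cleavage site and category.
#' Shipped as a plain-text fixture for summary statistics and for
#' worked examples of the cleavage-site geometry.
#'
#' @return Data.frame in [build_pairs()] column layout (without `stage`).
#' @export
rice_pa64s_pairs <- function() {
  path <- system.file("extdata", "rice_pa64s_pairs.tsv", package = "cleavekit")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$pattern <- paste(tab$mirna_direction, tab$target_direction, sep = "/")
  tab
}
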