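#' Run the integrated miRNA-target pipeline
#'
#' Convenience wrapper chaining the full analysis: duplex scanning of every
#' miRNA against every transcript, degradome signature mapping and cleavage
#' validation, per-stage S-vs-F differential expression of miRNAs and target
#' genes, and pair integration.
#'
#' @param mirnas,transcripts Sequence data.frames from [read_fasta()].
#' @param degradome_reads Degradome reads (sequence data.frame or tag table
#'   with `seq`, `count`).
#' @param mirna_counts,gene_counts [count_matrix()] objects (features =
#'   miRNA ids / transcript ids).
#' @param scheme A [scoring_scheme()].
#' @param stages Stages to analyse (default `c(6L, 7L)`).
#' @param alpha,min_abs_log2fc Significance thresholds for the miRNA screen
#'   (defaults 0.05 and 1).
#' @param require_target_de Passed to [build_pairs()].
#' @return List with elements `alignments`, `profiles`, `events`,
#'   `de_mirnas`, `de_genes`, `pairs`, `summary`.
#' @export
run_pipeline <- function(mirnas, transcripts, degradome_reads,
                         mirna_counts, gene_counts,
                         scheme = scoring_scheme(), stages = c(6L, 7L),
                         alpha = 0.05, min_abs_log2fc = 1,
                         require_target_de = FALSE) {
  alignments <- scan_targets(mirnas, transcripts, scheme)
  profiles <- map_signatures(degradome_reads, transcripts)
  events <- validate_targets(alignments, profiles)
  de_mir <- do.call(rbind, lapply(stages, function(st)
    differential_expression(mirna_counts, st, alpha, min_abs_log2fc)))
  de_gene <- do.call(rbind, lapply(stages, function(st)
    differential_expression(gene_counts, st, alpha, min_abs_log2fc)))
  pairs <- build_pairs(de_mir, de_gene, events,
                       require_target_de = require_target_de)
  list(alignments = alignments, profiles = profiles, events = events,
       de_mirnas = de_mir, de_genes = de_gene, pairs = pairs,
       summary = summarize_pairs(pairs))
}
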