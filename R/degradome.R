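# Degradome (PARE) 5'-signature mapping and cleavage-site classification.
# A degradome read marks the 5' end of an uncapped decay fragment; a miRNA
# cleavage event leaves a sharp pile of such 5' ends at the cut position.

#' Map degradome 5' signatures onto transcripts
#'
#' Each read contributes its count at the transcript position of its 5' end,
#' for EVERY transcript location where the read matches exactly (perfect
#' matches only, multi-mapping reads kept at full weight at all matches).
#' Reads shorter than `min_read_len` are discarded before mapping; reads with
#' no perfect match anywhere are tallied as unmapped.
#'
#' @param reads Either a sequence data.frame from [read_fasta()] (each read
#'   weight 1) or a tag table with columns `seq` and `count`.
#' @param transcripts Sequence data.frame from [read_fasta()].
#' @param min_read_len Minimum read length retained (default 15 nt; shorter
#'   reads match near-everywhere and carry no positional signal).
#' @return An object of class `degradome_profiles`: list with `profiles`
#'   (named list, transcript id -> named integer vector of counts keyed by
#'   1-based 5'-end position), `n_unmapped` (total unmapped read mass) and
#'   `n_discarded` (mass removed by the length filter).
#' @export
map_signatures <- function(reads, transcripts, min_read_len = 15L) {
  stopifnot(is.data.frame(reads), is.data.frame(transcripts))
  if ("count" %in% names(reads)) {
    seqs <- chartr("U", "T", normalize_seq(reads$seq))
    wts <- as.integer(reads$count)
  } else {
    seqs <- chartr("U", "T", normalize_seq(reads$seq))
    wts <- rep(1L, length(seqs))
  }
  stopifnot(all(wts >= 0))
  keep <- nchar(seqs) >= min_read_len
  n_discarded <- sum(wts[!keep])
  seqs <- seqs[keep]
  wts <- wts[keep]
  # collapse duplicate read sequences before the (read x transcript) scan
  agg <- tapply(wts, seqs, sum)
  useq <- names(agg)
  uwt <- as.integer(agg)

  profiles <- stats::setNames(
    lapply(transcripts$id, function(i) integer(0)), transcripts$id)
  mapped <- logical(length(useq))
  for (ti in seq_len(nrow(transcripts))) {
    tx <- transcripts$seq[[ti]]
    acc <- new.env(parent = emptyenv())
    for (ri in seq_along(useq)) {
      hit <- gregexpr(useq[[ri]], tx, fixed = TRUE)[[1L]]
      if (hit[[1L]] == -1L) next
      mapped[[ri]] <- TRUE
      for (p in as.integer(hit)) {
        key <- as.character(p)
        acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + uwt[[ri]]
      }
    }
    keys <- ls(acc)
    if (length(keys) > 0L) {
      v <- vapply(keys, function(k) acc[[k]], 0L)
      names(v) <- keys
      profiles[[transcripts$id[[ti]]]] <- v[order(as.integer(keys))]
    }
  }
  structure(list(profiles = profiles,
                 n_unmapped = sum(uwt[!mapped]),
                 n_discarded = n_discarded),
            class = "degradome_profiles")
}

#' @export
print.degradome_profiles <- function(x, ...) {
  covered <- sum(vapply(x$profiles, length, 0L) > 0L)
  cat("degradome_profiles:", length(x$profiles), "transcripts (", covered,
      "with signal ),", x$n_unmapped, "unmapped read(s)\n")
  invisible(x)
}

#' Classify a candidate cleavage position into category 0-4
#'
#' Five-class labelling of a position by its signature abundance relative to
#' the transcript profile:
#' \itemize{
#'   \item 0: more than one raw read at the position, abundance equal to the
#'     transcript maximum, and the maximum attained at only one position;
#'   \item 1: more than one raw read, equal to the maximum, maximum attained
#'     at more than one position;
#'   \item 2: more than one raw read, below the maximum but above the median
#'     for the transcript;
#'   \item 3: more than one raw read, at or below the median;
#'   \item 4: exactly one raw read at the position.
#' }
#' The transcript median is computed over covered positions only (positions
#' with at least one read); including the zero positions of a long transcript
#' would make category 2 nearly universal.
#'
#' @param profile Named integer vector of counts keyed by 1-based position
#'   (one element of the `profiles` field of [map_signatures()]).
#' @param position 1-based transcript position; must carry at least one read.
#' @return Integer category in `0:4`.
#' @export
classify_category <- function(profile, position) {
  stopifnot(length(profile) > 0L)
  key <- as.character(position)
  n <- unname(profile[key])
  if (is.na(n) || n < 1L) stop("position ", position, " has no reads")
  if (n == 1L) return(4L)
  mx <- max(profile)
  med <- stats::median(profile)
  if (n == mx) {
    if (sum(profile == mx) == 1L) 0L else 1L
  } else if (n > med) {
    2L
  } else {
    3L
  }
}

#' Validate miRNA target sites against degradome signal
#'
#' For each retained duplex alignment, the transcript positions paired to
#' miRNA nucleotides 10 and 11 are examined in the degradome profile. With no
#' signal at either position the alignment is dropped; with signal at one it
#' becomes a cleavage event there; with signal at both, the higher-abundance
#' site wins (ties go to nucleotide 10). The event's category is computed
#' with [classify_category()]. When several gap variants of one duplex
#' support the same site, only the best-penalty alignment (ties to the
#' smaller start) is reported, so one (miRNA, transcript, site) triple
#' yields one event.
#'
#' @param alignments Data.frame from [scan_transcript()] / [scan_targets()].
#' @param profiles A `degradome_profiles` object from [map_signatures()].
#' @return Data.frame of cleavage events with columns `mirna_id`,
#'   `transcript_id`, `site`, `coincident_nt` (10 or 11), `abundance`,
#'   `category`, `start`, `end`, `penalty`.
#' @export
validate_targets <- function(alignments, profiles) {
  stopifnot(inherits(profiles, "degradome_profiles"))
  unknown <- setdiff(unique(alignments$transcript_id), names(profiles$profiles))
  if (length(unknown) > 0L) {
    stop("alignment references unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  }
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    prof <- profiles$profiles[[a$transcript_id]]
    if (length(prof) == 0L) next
    n10 <- if (is.na(a$site10)) 0L else unname(prof[as.character(a$site10)])
    n11 <- if (is.na(a$site11)) 0L else unname(prof[as.character(a$site11)])
    n10 <- if (is.na(n10)) 0L else n10
    n11 <- if (is.na(n11)) 0L else n11
    if (n10 == 0L && n11 == 0L) next
    if (n10 >= n11) {
      site <- a$site10; nt <- 10L; ab <- n10
    } else {
      site <- a$site11; nt <- 11L; ab <- n11
    }
    rows[[i]] <- data.frame(
      mirna_id = a$mirna_id, transcript_id = a$transcript_id,
      site = site, coincident_nt = nt, abundance = ab,
      category = classify_category(prof, site),
      start = a$start, end = a$end, penalty = a$penalty,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site = integer(), coincident_nt = integer(),
                      abundance = integer(), category = integer(),
                      start = integer(), end = integer(), penalty = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # overlapping gap variants of one duplex hit the same site: keep the
  # best-penalty alignment per (miRNA, transcript, site)
  ord <- order(out$penalty, out$start)
  out <- out[ord, , drop = FALSE]
  key <- paste(out$mirna_id, out$transcript_id, out$site, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  ord <- order(out$transcript_id, out$site, out$mirna_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' t-plot table for one transcript
#'
#' One row per covered position with its signature count and a flag marking
#' validated cleavage sites, ready for plotting signature abundance along the
#' transcript with cleavage sites highlighted.
#'
#' @param profile Named integer vector (one transcript's degradome profile).
#' @param events Cleavage-event data.frame from [validate_targets()]
#'   (only rows for this transcript are used if `transcript_id` is present).
#' @param transcript_id Optional id used to subset `events`.
#' @return Data.frame with columns `position`, `count`,
#'   `is_validated_site`.
#' @export
tplot_table <- function(profile, events = NULL, transcript_id = NULL) {
  stopifnot(length(profile) > 0L)
  pos <- as.integer(names(profile))
  flagged <- integer(0)
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- events
    if (!is.null(transcript_id) && "transcript_id" %in% names(ev)) {
      ev <- ev[ev$transcript_id == transcript_id, , drop = FALSE]
    }
    flagged <- unique(ev$site)
  }
  out <- data.frame(position = pos, count = unname(as.integer(profile)),
                    is_validated_site = pos %in% flagged)
  out[order(out$position), , drop = FALSE]
}

#' Census of cleavage events by category
#'
#' Counts events, distinct target genes and distinct miRNAs per category.
#' Because an "event" can be read either per (miRNA, site) pair or per site
#' irrespective of the guiding miRNA, both tallies are reported.
#'
#' @param events Cleavage-event data.frame from [validate_targets()].
#' @return Data.frame with one row per category 0-4: `category`, `events`
#'   (rows, i.e. per miRNA-site), `sites` (distinct transcript sites),
#'   `genes`, `mirnas`.
#' @export
category_census <- function(events) {
  out <- data.frame(category = 0:4, events = 0L, sites = 0L, genes = 0L,
                    mirnas = 0L)
  if (is.null(events) || nrow(events) == 0L) return(out)
  for (k in 0:4) {
    ev <- events[events$category == k, , drop = FALSE]
    out$events[[k + 1L]] <- nrow(ev)
    out$sites[[k + 1L]] <- nrow(unique(ev[, c("transcript_id", "site")]))
    out$genes[[k + 1L]] <- length(unique(ev$transcript_id))
    out$mirnas[[k + 1L]] <- length(unique(ev$mirna_id))
  }
  out
}
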