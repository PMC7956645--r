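# Descriptive small-RNA tag profiling: length distribution and first-base
# preference, abundance-weighted (a tag sequenced 100 times counts 100 reads,
# not one distinct sequence).

#' Abundance-weighted sRNA length distribution
#'
#' Per-library read counts and fractions by tag length, over a retained
#' length window. Tags outside the window are excluded and their mass
#' reported per library.
#'
#' @param tags Tag table from [read_tag_counts()] (`seq` + one count column
#'   per library).
#' @param min_len,max_len Retained length window, inclusive (default
#'   18-30 nt; the 20-25 nt band is where canonical plant sRNAs dominate).
#' @return An object of class `length_distribution`: list with `table`
#'   (data.frame `library`, `length`, `count`, `fraction`; fractions sum to 1
#'   per library over retained lengths) and `excluded` (named numeric, mass
#'   outside the window per library).
#' @export
length_distribution <- function(tags, min_len = 18L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  libs <- setdiff(names(tags), "seq")
  if (nrow(tags) == 0L) {
    warning("empty tag table: empty distribution")
    return(structure(list(
      table = data.frame(library = character(), length = integer(),
                         count = numeric(), fraction = numeric()),
      excluded = stats::setNames(numeric(length(libs)), libs)),
      class = "length_distribution"))
  }
  len <- nchar(tags$seq)
  keep <- len >= min_len & len <= max_len
  rows <- list()
  excluded <- stats::setNames(numeric(length(libs)), libs)
  for (lib in libs) {
    cnt <- tags[[lib]]
    excluded[[lib]] <- sum(cnt[!keep])
    tot <- sum(cnt[keep])
    by_len <- tapply(cnt[keep], len[keep], sum)
    if (length(by_len) == 0L) next
    rows[[lib]] <- data.frame(
      library = lib, length = as.integer(names(by_len)),
      count = as.numeric(by_len),
      fraction = if (tot > 0) as.numeric(by_len) / tot else 0,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(library = character(), length = integer(), count = numeric(),
               fraction = numeric())
  rownames(tab) <- NULL
  structure(list(table = tab, excluded = excluded),
            class = "length_distribution")
}

#' First-base composition by tag length
#'
#' Abundance-weighted fraction of tags starting with each base, per length.
#' Reported on the RNA alphabet (U, not T), matching how mature-miRNA
#' first-base preference is conventionally displayed.
#'
#' @param tags Tag table from [read_tag_counts()].
#' @param libraries Optional character vector of library columns to pool
#'   (default: all).
#' @return Data.frame with columns `length`, `base` (`A`, `C`, `G`, `U`) and
#'   `fraction`; fractions sum to 1 within each length that has any tags.
#' @export
first_base_composition <- function(tags, libraries = NULL) {
  libs <- setdiff(names(tags), "seq")
  if (!is.null(libraries)) {
    stopifnot(all(libraries %in% libs))
    libs <- libraries
  }
  if (nrow(tags) == 0L) {
    warning("empty tag table: empty composition")
    return(data.frame(length = integer(), base = character(),
                      fraction = numeric()))
  }
  wt <- rowSums(as.matrix(tags[, libs, drop = FALSE]))
  len <- nchar(tags$seq)
  first <- substr(tags$seq, 1L, 1L)
  first <- chartr("T", "U", first)
  rows <- list()
  for (l in sort(unique(len))) {
    sel <- len == l
    tot <- sum(wt[sel])
    if (tot == 0) next
    by_base <- tapply(wt[sel], first[sel], sum)
    rows[[as.character(l)]] <- data.frame(
      length = l, base = names(by_base),
      fraction = as.numeric(by_base) / tot, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
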