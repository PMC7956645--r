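# Internal alphabet: sequences are stored 5'->3' over {A,C,G,T,N}; U on input
# is normalised to T and the original alphabet (RNA/DNA) is remembered per
# record so writers can restore it.

VALID_BASES <- c("A", "C", "G", "T", "N")

normalize_seq <- function(seq) {
  toupper(chartr("u", "U", seq))
}

#' Read a FASTA file of nucleotide sequences
#'
#' Strict reader for the transcript, miRNA and degradome-read inputs. IDs are
#' the first whitespace-delimited token of each header. U is normalised to T
#' internally; the original alphabet is kept in the `alphabet` column so that
#' [write_fasta()] round-trips exactly.
#'
#' @param path Path to a FASTA file.
#' @param allow_n Logical; permit `N` in sequences (allowed for transcripts,
#'   forbidden for miRNAs where ambiguity would poison duplex scoring).
#' @return A data.frame with columns `id`, `seq` (uppercase, T-internal) and
#'   `alphabet` (`"DNA"` or `"RNA"`).
#' @details Hard errors: duplicate id (named in the message), empty sequence,
#'   and any non-nucleotide character (reported with its line number).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, allow_n = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      alphabet = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[[1L]], ">")) {
    stop("not a FASTA file (first non-blank line must start with '>'): ", path)
  }
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) stop("empty sequence id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  body <- !hdr
  allowed <- VALID_BASES
  if (!allow_n) allowed <- setdiff(allowed, "N")
  line_no <- seq_along(lines)
  for (i in which(body)) {
    chars <- strsplit(toupper(lines[[i]]), "")[[1L]]
    chars[chars == "U"] <- "T"
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("invalid character(s) ", paste(unique(bad), collapse = ""),
           " at line ", line_no[[i]], " of ", path)
    }
  }
  raw_seq <- vapply(split(lines[body], rec[body]), paste0, "", collapse = "")
  seqs <- rep("", length(ids))
  seqs[as.integer(names(raw_seq))] <- toupper(raw_seq)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  alphabet <- ifelse(grepl("U", seqs, fixed = TRUE), "RNA", "DNA")
  data.frame(id = ids, seq = chartr("U", "T", seqs), alphabet = alphabet,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: records whose `alphabet` is `"RNA"` are written
#' back with U.
#'
#' @param records Data.frame with columns `id`, `seq` and optionally
#'   `alphabet` (defaults to DNA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  alphabet <- if ("alphabet" %in% names(records)) records$alphabet else
    rep("DNA", nrow(records))
  out <- character(2L * nrow(records))
  seqs <- ifelse(alphabet == "RNA", chartr("T", "U", records$seq), records$seq)
  if (nrow(records) > 0L) {
    out[c(TRUE, FALSE)] <- paste0(">", records$id)
    out[c(FALSE, TRUE)] <- seqs
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a small-RNA tag-count table
#'
#' Tab-separated, UTF-8, one row per distinct tag sequence, a `seq` column
#' followed by one integer column per library. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the TSV table.
#' @return Data.frame with column `seq` plus one non-negative integer column
#'   per library, in file order.
#' @details Hard errors: ragged rows, negative counts, duplicated tag
#'   sequences, tags with all-zero counts.
#' @export
read_tag_counts <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("tag table has no header row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[[1L]])) {
    stop("ragged row(s) in ", path, " (expected ", nf[[1L]], " fields)")
  }
  header <- fields[[1L]]
  if (header[[1L]] != "seq") stop("first column of a tag table must be 'seq'")
  libs <- header[-1L]
  if (length(libs) == 0L) stop("tag table has no library columns: ", path)
  body <- fields[-1L]
  if (length(body) == 0L) {
    out <- c(list(seq = character()),
             stats::setNames(rep(list(integer()), length(libs)), libs))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  seq <- normalize_seq(vapply(body, `[[`, "", 1L))
  seq <- chartr("U", "T", seq)
  if (anyDuplicated(seq)) {
    stop("duplicated tag sequence(s): ",
         paste(unique(seq[duplicated(seq)]), collapse = ", "))
  }
  counts <- matrix(NA_real_, nrow = length(body), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (j in seq_along(libs)) {
    v <- suppressWarnings(as.numeric(vapply(body, `[[`, "", j + 1L)))
    if (anyNA(v) || any(v != floor(v))) {
      stop("non-integer count in column '", libs[[j]], "' of ", path)
    }
    if (any(v < 0)) stop("negative count in column '", libs[[j]], "' of ", path)
    counts[, j] <- v
  }
  if (any(rowSums(counts) == 0)) stop("tag with all-zero counts in ", path)
  out <- data.frame(seq = seq, stringsAsFactors = FALSE)
  for (j in seq_along(libs)) out[[libs[[j]]]] <- as.integer(counts[, j])
  out
}

#' Write a tag-count table
#' @param tags Data.frame as returned by [read_tag_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_counts <- function(tags, path) {
  stopifnot(is.data.frame(tags), names(tags)[[1L]] == "seq")
  utils::write.table(tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a count matrix with library metadata
#'
#' The container for feature-by-library raw counts in a two-condition
#' (S = sterile, F = fertile), two-stage (6, 7) replicated design.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   libraries in columns (colnames = library ids).
#' @param meta Data.frame with columns `library_id`, `condition` (`"S"` or
#'   `"F"`), `stage` (6 or 7) and `replicate`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta` (meta reordered to match the column order of `counts`).
#' @export
count_matrix <- function(counts, meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate library ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  need <- c("library_id", "condition", "stage", "replicate")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(colnames(counts), meta$library_id)
  if (length(missing_meta) > 0L) {
    stop("library present in counts but not in metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$library_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(meta$condition %in% c("S", "F"))) {
    stop("condition must be 'S' or 'F'")
  }
  if (!all(meta$stage %in% c(6L, 7L))) stop("stage must be 6 or 7")
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "libraries\n")
  cat("libraries:", paste0(x$meta$library_id, " (", x$meta$condition,
                           x$meta$stage, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix and its library metadata
#'
#' @param path TSV with a `feature_id` column followed by one integer column
#'   per library; `#` comment lines ignored.
#' @param metadata_path TSV with columns `library_id`, `condition`, `stage`,
#'   `replicate`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path) {
  stopifnot(file.exists(path), file.exists(metadata_path))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[[1L]] != "feature_id") {
    stop("first column of a count matrix must be 'feature_id'")
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals != floor(vals))) {
    stop("non-integer value in count matrix ", path)
  }
  storage.mode(vals) <- "integer"
  rownames(vals) <- tab$feature_id
  meta <- utils::read.delim(metadata_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  count_matrix(vals, meta)
}

#' Write a count matrix and its metadata
#' @param cm A [count_matrix()].
#' @param path,metadata_path Output TSV paths.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, metadata_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Reverse complement on the internal (T) alphabet.
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "")[[1L]]), collapse = "")
         }, "", USE.NAMES = FALSE))
}
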