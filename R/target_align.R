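# Antiparallel miRNA:transcript duplex scanning under the plant degradome
# scoring convention. miRNA positions are numbered from the 5' end; position 1
# pairs the 3'-most transcript position of the duplex. Penalties accrue in
# 0.5 steps and alignments above the retention ceiling are discarded.

PAIR_STATES <- c("WC", "GU", "MISMATCH", "BULGE_MIRNA", "BULGE_TARGET")
STATE_GLYPH <- c(WC = "|", GU = "o", MISMATCH = "x",
                 BULGE_MIRNA = "m", BULGE_TARGET = "t")

#' Duplex scoring scheme
#'
#' Penalty constants for miRNA:target duplex evaluation. Only the retention
#' ceiling of 4 is fixed by the degradome validation rule; the remaining
#' constants follow the de facto plant-target convention: mismatch 1.0, G:U
#' wobble 0.5, bulge 2.0, all doubled inside the seed-proximal region (miRNA
#' positions 2-13), at most one single-nucleotide bulge per duplex.
#'
#' @param mismatch,gu,bulge Positive per-event penalties.
#' @param seed_start,seed_end miRNA positions (5'-numbered, inclusive) whose
#'   penalties are doubled.
#' @param ceiling Maximum total penalty retained by [scan_transcript()].
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mismatch = 1, gu = 0.5, bulge = 2,
                           seed_start = 2, seed_end = 13, ceiling = 4) {
  stopifnot(mismatch > 0, gu > 0, bulge > 0, ceiling > 0,
            seed_start >= 1, seed_end >= seed_start)
  structure(list(mismatch = mismatch, gu = gu, bulge = bulge,
                 seed_start = seed_start, seed_end = seed_end,
                 ceiling = ceiling),
            class = "scoring_scheme")
}

# Pairing state of one miRNA base against one target (transcript) base,
# both read on the internal T alphabet. N never pairs.
pair_state <- function(mirna_base, target_base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  wc <- comp[mirna_base] == target_base
  gu <- (mirna_base == "G" & target_base == "T") |
        (mirna_base == "T" & target_base == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MISMATCH"))
}

# Per-column penalty under a scheme. `mir_pos` is the miRNA position the
# column is charged at: paired and BULGE_MIRNA columns consume a miRNA
# position; a BULGE_TARGET column is charged at the miRNA position
# immediately 3' of the bulge (the next consumed position).
state_cost <- function(states, mir_pos, scheme) {
  base <- c(WC = 0, GU = scheme$gu, MISMATCH = scheme$mismatch,
            BULGE_MIRNA = scheme$bulge, BULGE_TARGET = scheme$bulge)[states]
  mult <- ifelse(mir_pos >= scheme$seed_start & mir_pos <= scheme$seed_end,
                 2, 1)
  sum(base * mult)
}

# miRNA position each duplex column is charged at, given the column states
# in miRNA 5'->3' order.
column_mir_pos <- function(states) {
  pos <- integer(length(states))
  k <- 1L
  for (i in seq_along(states)) {
    pos[[i]] <- k
    if (states[[i]] != "BULGE_TARGET") k <- k + 1L
  }
  pos
}

#' Score one miRNA:target pairing
#'
#' Computes the duplex penalty from explicit per-column pairing states, or
#' from a target site sequence under the gapless antiparallel convention.
#' Columns are ordered along the miRNA 5'->3'; column penalties are doubled
#' inside the scheme's seed region.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (U or T accepted).
#' @param site_seq Target site sequence, 5'->3' on the transcript strand.
#'   Ignored when `states` is supplied together with a consistency check.
#' @param states Optional character vector of per-column states among
#'   `"WC"`, `"GU"`, `"MISMATCH"`, `"BULGE_MIRNA"`, `"BULGE_TARGET"`.
#' @param scheme A [scoring_scheme()].
#' @return The total penalty (non-negative, multiple of the scheme's
#'   granularity).
#' @details When both `site_seq` and `states` are given, the paired-column
#'   states are checked against the sequences and an inconsistency is a hard
#'   error. At most one bulge column is allowed.
#' @export
score_pairing <- function(mirna_seq, site_seq = NULL, states = NULL,
                          scheme = scoring_scheme()) {
  mir <- strsplit(chartr("U", "T", normalize_seq(mirna_seq)), "")[[1L]]
  m <- length(mir)
  if (is.null(states)) {
    if (is.null(site_seq)) stop("supply site_seq or states")
    site <- strsplit(chartr("U", "T", normalize_seq(site_seq)), "")[[1L]]
    if (length(site) != m) {
      stop("gapless scoring requires equal miRNA and site lengths; ",
           "supply explicit states for bulged duplexes")
    }
    states <- pair_state(mir, rev(site))
  } else {
    states <- match.arg(states, PAIR_STATES, several.ok = TRUE)
    if (sum(states %in% c("BULGE_MIRNA", "BULGE_TARGET")) > 1L) {
      stop("at most one bulge per duplex")
    }
    if (sum(states != "BULGE_TARGET") != m) {
      stop("states consume ", sum(states != "BULGE_TARGET"),
           " miRNA positions but the miRNA has ", m)
    }
    if (!is.null(site_seq)) {
      site <- strsplit(chartr("U", "T", normalize_seq(site_seq)), "")[[1L]]
      if (length(site) != length(states) - sum(states == "BULGE_MIRNA")) {
        stop("site length inconsistent with states")
      }
      chk <- duplex_column_states(mir, site, states)
      if (!identical(chk, states)) {
        stop("states inconsistent with sequences at column(s) ",
             paste(which(chk != states), collapse = ", "))
      }
    }
  }
  state_cost(states, column_mir_pos(states), scheme)
}

# Recompute paired-column states from sequences, keeping the bulge layout of
# `states`; used for the consistency check and by the scanner.
duplex_column_states <- function(mir, site, states) {
  out <- states
  k <- 1L                 # miRNA position consumed next
  p <- length(site)       # site index pairing the current column (3'-most first)
  for (i in seq_along(states)) {
    s <- states[[i]]
    if (s == "BULGE_MIRNA") {
      k <- k + 1L
    } else if (s == "BULGE_TARGET") {
      p <- p - 1L
    } else {
      out[[i]] <- pair_state(mir[[k]], site[[p]])
      k <- k + 1L
      p <- p - 1L
    }
  }
  out
}

#' Construct a duplex alignment record
#'
#' @param mirna_id,transcript_id Identifiers.
#' @param start,end 1-based inclusive transcript positions of the duplex
#'   (`start <= end`; the miRNA 5' end pairs position `end`).
#' @param states Per-column pairing states, miRNA 5'->3' order.
#' @param mirna_len miRNA length in nt.
#' @param scheme [scoring_scheme()] used to compute the penalty.
#' @return An object of class `duplex_alignment`.
#' @export
duplex_alignment <- function(mirna_id, transcript_id, start, end, states,
                             mirna_len = sum(states != "BULGE_TARGET"),
                             scheme = scoring_scheme()) {
  stopifnot(start >= 1, start <= end)
  nb_t <- sum(states == "BULGE_TARGET")
  nb_m <- sum(states == "BULGE_MIRNA")
  if (end - start + 1L != mirna_len + nb_t - nb_m) {
    stop("range width inconsistent with miRNA length and bulges")
  }
  penalty <- state_cost(states, column_mir_pos(states), scheme)
  structure(list(mirna_id = mirna_id, transcript_id = transcript_id,
                 start = as.integer(start), end = as.integer(end),
                 states = states, mirna_len = as.integer(mirna_len),
                 penalty = penalty),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("%s -> %s  %d-%d  penalty %.1f  %s\n", x$mirna_id,
              x$transcript_id, x$start, x$end, x$penalty,
              paste(STATE_GLYPH[x$states], collapse = "")))
  invisible(x)
}

#' Transcript positions paired to miRNA nucleotides 10 and 11
#'
#' miRNA-guided cleavage falls at the transcript position paired to the
#' tenth or eleventh miRNA nucleotide (counted from the miRNA 5' end). For a
#' gapless duplex over transcript range `[s, e]`, nucleotide k pairs position
#' `e - (k - 1)`, so site10 = e - 9 and site11 = e - 10.
#'
#' @param alignment A [duplex_alignment()].
#' @return Named integer vector `c(site10 = , site11 = )`. A site is `NA` if
#'   the corresponding miRNA nucleotide is bulged (unpaired).
#' @export
cleavage_positions <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  if (alignment$mirna_len < 11L) stop("miRNA shorter than 11 nt")
  k <- 1L
  pos <- alignment$end
  sites <- c(site10 = NA_integer_, site11 = NA_integer_)
  for (s in alignment$states) {
    if (s == "BULGE_TARGET") {
      pos <- pos - 1L
    } else if (s == "BULGE_MIRNA") {
      k <- k + 1L
    } else {
      if (k == 10L) sites[["site10"]] <- pos
      if (k == 11L) sites[["site11"]] <- pos
      k <- k + 1L
      pos <- pos - 1L
    }
  }
  sites
}

# Penalty of every gapless window in one vectorised pass: returns a numeric
# vector indexed by window start.
gapless_penalties <- function(mir, tx_chars, scheme) {
  m <- length(mir)
  L <- length(tx_chars)
  n_win <- L - m + 1L
  if (n_win < 1L) return(numeric(0))
  # column k of the duplex (miRNA pos k) reads transcript position s + m - k
  idx <- outer(m:1, seq_len(n_win) - 1L, `+`)     # m x n_win
  tgt <- matrix(tx_chars[idx], nrow = m)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  wc <- tgt == matrix(comp[mir], nrow = m, ncol = n_win)
  gu <- (mir == "G" & tgt == "T") | (mir == "T" & tgt == "G")
  cost <- matrix(scheme$mismatch, nrow = m, ncol = n_win)
  cost[gu] <- scheme$gu
  cost[wc] <- 0
  seed <- seq_len(m) >= scheme$seed_start & seq_len(m) <= scheme$seed_end
  cost[seed, ] <- 2 * cost[seed, , drop = FALSE]
  colSums(cost)
}

#' Scan a transcript for retained miRNA duplexes
#'
#' Scores every gapless window and every single-bulge window of the
#' transcript against the miRNA and returns the alignments whose penalty does
#' not exceed the scheme ceiling. For each `(start, end)` window the
#' best-scoring gap configuration is reported (ties prefer gapless, then the
#' smallest bulge offset). Output is sorted by (penalty, start); overlapping
#' hits are all reported.
#'
#' @param mirna_seq,transcript_seq Sequences 5'->3' (U or T).
#' @param scheme A [scoring_scheme()].
#' @param mirna_id,transcript_id Identifiers carried into the output.
#' @return Data.frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end`, `penalty`, `pairing` (one glyph per column: `|` WC, `o` G:U,
#'   `x` mismatch, `m`/`t` bulge), `site10`, `site11`, plus a `states` list
#'   column of the per-column state vectors.
#' @export
scan_transcript <- function(mirna_seq, transcript_seq,
                            scheme = scoring_scheme(),
                            mirna_id = "mirna", transcript_id = "transcript") {
  mirna_seq <- chartr("U", "T", normalize_seq(mirna_seq))
  transcript_seq <- chartr("U", "T", normalize_seq(transcript_seq))
  mir <- strsplit(mirna_seq, "")[[1L]]
  if (any(mir == "N")) stop("N not allowed in miRNA sequences")
  tx <- strsplit(transcript_seq, "")[[1L]]
  m <- length(mir)
  L <- length(tx)
  if (L < m) stop("transcript shorter than miRNA")

  hits <- list()
  add_hit <- function(s, e, states, penalty) {
    key <- paste0(s, ":", e)
    cur <- hits[[key]]
    if (is.null(cur) || penalty < cur$penalty) {
      hits[[key]] <<- list(s = s, e = e, states = states, penalty = penalty)
    }
  }

  # gapless windows (preferred on ties: inserted first)
  gp <- gapless_penalties(mir, tx, scheme)
  for (s in which(gp <= scheme$ceiling)) {
    e <- s + m - 1L
    site <- tx[s:e]
    states <- pair_state(mir, rev(site))
    add_hit(s, e, states, gp[[s]])
  }

  seed <- function(k) k >= scheme$seed_start & k <= scheme$seed_end
  # vectorised penalty of all windows of one bulge layout: `offsets[k]` is
  # the 0-based transcript offset (from the window start s) of the target
  # base paired to miRNA position paired_k[k]
  layout_penalties <- function(paired_k, offsets, n_win) {
    idx <- outer(offsets, seq_len(n_win), `+`)
    tgt <- matrix(tx[idx], nrow = length(paired_k))
    mirk <- mir[paired_k]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
    wc <- tgt == comp[mirk]
    gu <- (mirk == "G" & tgt == "T") | (mirk == "T" & tgt == "G")
    cost <- matrix(scheme$mismatch, nrow = length(paired_k), ncol = n_win)
    cost[gu] <- scheme$gu
    cost[wc] <- 0
    dbl <- seed(paired_k)
    cost[dbl, ] <- 2 * cost[dbl, , drop = FALSE]
    colSums(cost)
  }
  # one target bulge after miRNA position j: window width m + 1
  if (L >= m + 1L) {
    for (j in seq_len(m - 1L)) {
      bulge_cost <- scheme$bulge * (1 + seed(j + 1L))
      # miRNA pos k pairs e-(k-1) for k<=j, e-k for k>j; e = s + m
      offs <- ifelse(seq_len(m) <= j, m - seq_len(m) + 1L, m - seq_len(m))
      pen <- layout_penalties(seq_len(m), offs, L - m) + bulge_cost
      for (s in which(pen <= scheme$ceiling)) {
        e <- s + m
        tgt <- tx[s + offs]
        st <- pair_state(mir, tgt)
        add_hit(s, e, append(st, "BULGE_TARGET", after = j), pen[[s]])
      }
    }
  }
  # one miRNA bulge at interior position j: window width m - 1
  if (m >= 3L && L >= m - 1L) {
    for (j in 2:(m - 1L)) {
      bulge_cost <- scheme$bulge * (1 + seed(j))
      paired_k <- setdiff(seq_len(m), j)
      # e = s + m - 2; k<j pairs e-(k-1), k>j pairs e-(k-2)
      offs <- ifelse(paired_k < j, m - paired_k - 1L, m - paired_k)
      pen <- layout_penalties(paired_k, offs, L - m + 2L) + bulge_cost
      for (s in which(pen <= scheme$ceiling)) {
        e <- s + m - 2L
        tgt <- tx[s + offs]
        st <- pair_state(mir[paired_k], tgt)
        add_hit(s, e, append(st, "BULGE_MIRNA", after = j - 1L), pen[[s]])
      }
    }
  }

  if (length(hits) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), penalty = numeric(),
                      pairing = character(), site10 = integer(),
                      site11 = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(hits, function(h) {
    aln <- duplex_alignment(mirna_id, transcript_id, h$s, h$e, h$states,
                            mirna_len = m, scheme = scheme)
    cp <- if (m >= 11L) cleavage_positions(aln) else
      c(site10 = NA_integer_, site11 = NA_integer_)
    data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
               start = h$s, end = h$e, penalty = h$penalty,
               pairing = paste(STATE_GLYPH[h$states], collapse = ""),
               site10 = cp[["site10"]], site11 = cp[["site11"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$states <- lapply(hits, `[[`, "states")
  ord <- order(out$penalty, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan all miRNAs against all transcripts
#'
#' @param mirnas,transcripts Sequence data.frames from [read_fasta()].
#' @param scheme A [scoring_scheme()].
#' @return Row-bound [scan_transcript()] results, sorted by
#'   (penalty, start, mirna_id) within each transcript.
#' @export
scan_targets <- function(mirnas, transcripts, scheme = scoring_scheme()) {
  res <- list()
  for (ti in seq_len(nrow(transcripts))) {
    for (mi in seq_len(nrow(mirnas))) {
      if (nchar(transcripts$seq[[ti]]) < nchar(mirnas$seq[[mi]])) next
      res[[length(res) + 1L]] <- scan_transcript(
        mirnas$seq[[mi]], transcripts$seq[[ti]], scheme,
        mirna_id = mirnas$id[[mi]], transcript_id = transcripts$id[[ti]])
    }
  }
  res <- res[vapply(res, nrow, 0L) > 0L]
  if (length(res) == 0L) {
    return(scan_transcript("ACGTACGTACGTACGTACGTA",
                           "TTTTTTTTTTTTTTTTTTTTT")[0L, ])
  }
  out <- do.call(rbind, res)
  ord <- order(out$transcript_id, out$penalty, out$start, out$mirna_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
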