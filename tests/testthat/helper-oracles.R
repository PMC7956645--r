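# Independent oracles, deliberately coded without reference to the package
# internals they check.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Literal restatement of the five category definitions: a sentence each,
# evaluated in order. `profile` is a named count vector over covered
# positions.
oracle_category <- function(profile, position) {
  n <- profile[[as.character(position)]]
  covered <- as.numeric(profile)
  maximum <- max(covered)
  med <- median(covered)
  if (n > 1 && n == maximum && sum(covered == maximum) == 1) return(0L)
  if (n > 1 && n == maximum && sum(covered == maximum) > 1) return(1L)
  if (n > 1 && n < maximum && n > med) return(2L)
  if (n > 1 && n <= med) return(3L)
  if (n == 1) return(4L)
  stop("unclassifiable")
}

# Naive per-window duplex scorer: states for a gapless window, or with one
# bulge laid out explicitly; loops over columns, no vectorisation.
oracle_pair_state <- function(mb, tb) {
  if (COMP[[mb]] == tb) return("WC")
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return("GU")
  "MISMATCH"
}

oracle_score <- function(states, scheme) {
  total <- 0
  k <- 1L
  for (s in states) {
    charge_pos <- k
    cost <- switch(s, WC = 0, GU = scheme$gu, MISMATCH = scheme$mismatch,
                   BULGE_MIRNA = scheme$bulge, BULGE_TARGET = scheme$bulge)
    if (charge_pos >= scheme$seed_start && charge_pos <= scheme$seed_end) {
      cost <- cost * 2
    }
    total <- total + cost
    if (s != "BULGE_TARGET") k <- k + 1L
  }
  total
}

# Brute-force enumeration of every gapless and single-bulge window of a
# transcript, keeping the best configuration per (start, end) and penalties
# at or below the ceiling. Returns data.frame(start, end, penalty). Each
# window is scored from first principles (Watson-Crick / G:U / mismatch per
# paired column, seed doubling at the charged miRNA position, bulge cost),
# with vector operations per window for speed.
oracle_scan <- function(mirna, transcript, scheme) {
  mir <- strsplit(mirna, "")[[1L]]
  tx <- strsplit(transcript, "")[[1L]]
  m <- length(mir)
  L <- length(tx)
  wc_partner <- COMP[mir]
  gu_partner <- c(G = "T", T = "G", A = NA, C = NA)[mir]
  dbl <- ifelse(seq_len(m) >= scheme$seed_start &
                  seq_len(m) <= scheme$seed_end, 2, 1)
  window_cost <- function(paired_k, tgt) {
    per <- ifelse(tgt == wc_partner[paired_k], 0,
                  ifelse(!is.na(gu_partner[paired_k]) &
                           tgt == gu_partner[paired_k],
                         scheme$gu, scheme$mismatch))
    sum(per * dbl[paired_k])
  }
  best <- new.env(parent = emptyenv())
  consider <- function(s, e, p) {
    if (p > scheme$ceiling) return()
    key <- paste(s, e)
    cur <- best[[key]]
    if (is.null(cur) || p < cur[[3L]]) best[[key]] <- c(s, e, p)
  }
  # gapless: miRNA position k reads transcript position e - k + 1
  for (s in seq_len(L - m + 1L)) {
    e <- s + m - 1L
    consider(s, e, window_cost(seq_len(m), tx[e - seq_len(m) + 1L]))
  }
  # one unpaired target nt between miRNA positions j and j+1 (charged at
  # j + 1)
  for (j in seq_len(m - 1L)) {
    bulge <- scheme$bulge * dbl[[j + 1L]]
    for (s in seq_len(max(0L, L - m))) {
      e <- s + m
      tpos <- ifelse(seq_len(m) <= j, e - seq_len(m) + 1L, e - seq_len(m))
      consider(s, e, window_cost(seq_len(m), tx[tpos]) + bulge)
    }
  }
  # one unpaired interior miRNA nt at position j (charged at j)
  if (m >= 3L) {
    for (j in 2:(m - 1L)) {
      bulge <- scheme$bulge * dbl[[j]]
      paired_k <- setdiff(seq_len(m), j)
      for (s in seq_len(L - m + 2L)) {
        e <- s + m - 2L
        tpos <- ifelse(paired_k < j, e - paired_k + 1L, e - paired_k + 2L)
        consider(s, e, window_cost(paired_k, tx[tpos]) + bulge)
      }
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) {
    return(data.frame(start = integer(), end = integer(), penalty = numeric()))
  }
  vals <- t(vapply(keys, function(k) best[[k]], numeric(3)))
  out <- data.frame(start = as.integer(vals[, 1L]),
                    end = as.integer(vals[, 2L]), penalty = vals[, 3L])
  out <- out[order(out$penalty, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_seq <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
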