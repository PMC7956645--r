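# Seeded generators for every input the pipeline consumes, with planted
# ground truth: transcripts carrying miRNA complementary sites of chosen
# penalty, degradome reads piled at chosen cleavage sites with controllable
# category structure and background noise, and negative-binomial count
# matrices with planted fold changes. All generators are pure functions of
# their parameters plus seed.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random transcriptome
#'
#' i.i.d. nucleotides at a target GC fraction; lengths uniform over
#' `length_range`.
#'
#' @param n Number of transcripts (>= 1).
#' @param length_range Integer vector `c(min, max)`, min >= 50.
#' @param gc Target GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return Sequence data.frame (`id`, `seq`, `alphabet`) as from
#'   [read_fasta()].
#' @export
generate_transcriptome <- function(n, length_range = c(500L, 1000L),
                                   gc = 0.5, seed = 1L) {
  stopifnot(n >= 1, length(length_range) == 2L,
            length_range[[1L]] <= length_range[[2L]],
            length_range[[1L]] >= 50L, gc > 0, gc < 1)
  with_seed(seed, {
    lens <- length_range[[1L]] +
      sample.int(length_range[[2L]] - length_range[[1L]] + 1L, n,
                 replace = TRUE) - 1L
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, "")
    data.frame(id = sprintf("TX%04d", seq_len(n)), seq = seqs,
               alphabet = "DNA", stringsAsFactors = FALSE)
  })
}

#' Generate random mature miRNA sequences
#'
#' Uniform random sequences with a 5'-U bias (plant mature miRNAs mostly
#' start with U).
#'
#' @param n Number of miRNAs.
#' @param length miRNA length in nt (default 21).
#' @param u_start_prob Probability that the first base is U (default 0.8).
#' @param seed RNG seed.
#' @return Sequence data.frame with `alphabet = "RNA"`.
#' @export
generate_mirnas <- function(n, length = 21L, u_start_prob = 0.8, seed = 1L) {
  stopifnot(n >= 1, length >= 11L)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      first <- if (stats::runif(1) < u_start_prob) "T" else
        sample(c("A", "C", "G"), 1L)
      paste(c(first, sample(c("A", "C", "G", "T"), length - 1L,
                            replace = TRUE)), collapse = "")
    }, "")
    data.frame(id = sprintf("mir%03d", seq_len(n)), seq = seqs,
               alphabet = "RNA", stringsAsFactors = FALSE)
  })
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")
wobble_partner <- c(G = "T", T = "G", A = NA_character_, C = NA_character_)

# Choose a site base that mismatches miRNA base `mb` (neither Watson-Crick
# nor G:U).
mismatch_base <- function(mb) {
  bad <- c(comp_base[[mb]], wobble_partner[[mb]])
  setdiff(c("A", "C", "G", "T"), bad[!is.na(bad)])[[1L]]
}

# Edit the perfect-complement site of `mir` so the gapless duplex penalty
# equals `target` exactly (multiples of 0.5), using seed mismatches (2.0),
# out-of-seed mismatches (1.0) and one out-of-seed G:U (0.5). Positions 9-11
# are never edited so the cleavage-site region stays paired.
build_site <- function(mir_chars, target, scheme) {
  m <- length(mir_chars)
  site <- rev(comp_base[mir_chars])          # 5'->3' perfect complement
  in_seed <- function(k) k >= scheme$seed_start & k <= scheme$seed_end
  reserved <- 9:11
  seed_pos <- setdiff(which(in_seed(seq_len(m))), reserved)
  out_pos <- setdiff(setdiff(seq_len(m), which(in_seed(seq_len(m)))),
                     reserved)
  remaining <- target
  edit_at <- function(k, kind) {
    j <- m - k + 1L                          # site index paired to miRNA k
    site[[j]] <<- if (kind == "mm") mismatch_base(mir_chars[[k]]) else
      wobble_partner[[mir_chars[[k]]]]
  }
  while (remaining >= 2 * scheme$mismatch && length(seed_pos) > 0L) {
    edit_at(seed_pos[[length(seed_pos)]], "mm")
    seed_pos <- seed_pos[-length(seed_pos)]
    remaining <- remaining - 2 * scheme$mismatch
  }
  while (remaining >= scheme$mismatch && length(out_pos) > 0L) {
    edit_at(out_pos[[length(out_pos)]], "mm")
    out_pos <- out_pos[-length(out_pos)]
    remaining <- remaining - scheme$mismatch
  }
  if (remaining > 0) {
    gu_ok <- out_pos[mir_chars[out_pos] %in% c("G", "T")]
    while (remaining >= scheme$gu && length(gu_ok) > 0L) {
      edit_at(gu_ok[[length(gu_ok)]], "gu")
      gu_ok <- gu_ok[-length(gu_ok)]
      remaining <- remaining - scheme$gu
    }
  }
  if (remaining != 0) {
    stop("penalty target ", target, " not achievable for this miRNA under ",
         "the scheme")
  }
  paste(site, collapse = "")
}

#' Plant miRNA complementary sites into transcripts
#'
#' Each requested site replaces a random (seeded) window of the transcript
#' with a sequence whose gapless duplex penalty against the miRNA equals the
#' requested value exactly (checked with [score_pairing()]); sites on the
#' same transcript never overlap. Targets above the scheme ceiling are only
#' allowed as flagged negative controls.
#'
#' @param transcripts,mirnas Sequence data.frames.
#' @param penalty_targets Data.frame with columns `mirna_id`,
#'   `transcript_id`, `penalty` and optionally logical `control` (permits
#'   penalty above the retention ceiling).
#' @param seed RNG seed.
#' @param scheme A [scoring_scheme()].
#' @return List: `transcripts` (edited) and `truth`, a data.frame with
#'   `mirna_id`, `transcript_id`, `start`, `end`, `penalty`, `site10`,
#'   `site11`, `control`.
#' @export
plant_sites <- function(transcripts, mirnas, penalty_targets, seed = 1L,
                        scheme = scoring_scheme()) {
  stopifnot(all(c("mirna_id", "transcript_id", "penalty") %in%
                  names(penalty_targets)))
  if (!"control" %in% names(penalty_targets)) penalty_targets$control <- FALSE
  over <- penalty_targets$penalty > scheme$ceiling & !penalty_targets$control
  if (any(over)) {
    stop("penalty target above the ceiling must be flagged as control: row(s) ",
         paste(which(over), collapse = ", "))
  }
  with_seed(seed, {
    occupied <- stats::setNames(vector("list", nrow(transcripts)),
                                transcripts$id)
    truth <- list()
    for (i in seq_len(nrow(penalty_targets))) {
      pt <- penalty_targets[i, ]
      mi <- match(pt$mirna_id, mirnas$id)
      ti <- match(pt$transcript_id, transcripts$id)
      if (is.na(mi) || is.na(ti)) stop("unknown id in penalty_targets row ", i)
      mir_chars <- strsplit(mirnas$seq[[mi]], "")[[1L]]
      m <- length(mir_chars)
      site <- build_site(mir_chars, pt$penalty, scheme)
      L <- nchar(transcripts$seq[[ti]])
      ok <- FALSE
      # leave >= 25 nt downstream room so degradome reads from the cleavage
      # site are full length
      s_max <- max(1L, L - m + 1L - 25L)
      for (try in seq_len(200L)) {
        s <- sample.int(s_max, 1L)
        e <- s + m - 1L
        clash <- any(vapply(occupied[[pt$transcript_id]], function(iv) {
          s <= iv[[2L]] && e >= iv[[1L]]
        }, TRUE))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place site without overlap on ",
                    pt$transcript_id)
      occupied[[pt$transcript_id]] <-
        c(occupied[[pt$transcript_id]], list(c(s, e)))
      tx <- transcripts$seq[[ti]]
      transcripts$seq[[ti]] <- paste0(substr(tx, 1L, s - 1L), site,
                                      substr(tx, e + 1L, L))
      realized <- score_pairing(mirnas$seq[[mi]], site, scheme = scheme)
      stopifnot(isTRUE(all.equal(realized, pt$penalty)))
      truth[[i]] <- data.frame(
        mirna_id = pt$mirna_id, transcript_id = pt$transcript_id,
        start = s, end = e, penalty = pt$penalty,
        site10 = e - 9L, site11 = e - 10L, control = pt$control,
        stringsAsFactors = FALSE)
    }
    list(transcripts = transcripts, truth = do.call(rbind, truth))
  })
}

# Companion peaks that force a site of abundance `a` into the intended
# category on its transcript profile.
category_companions <- function(category, a) {
  switch(as.character(category),
         "0" = list(),
         "1" = list(a),                       # one equal co-maximum
         "2" = list(a + max(2L, a), 1L, 1L),  # a dominant peak + low floor
         "3" = list(a + 2L, a + 1L, a + 1L, a + 3L),  # median pulled >= a
         "4" = list(),
         stop("category must be 0-4"))
}

#' Simulate degradome reads for planted cleavage events
#'
#' For each planted (non-control) site, reads of length 20-21 nt are emitted
#' whose 5' ends fall at the chosen cleavage position, with abundance and
#' companion peaks chosen so the realised transcript profile classifies to
#' the intended category; uniform background noise with geometric abundance
#' is layered on top. Intended categories are verified with
#' [classify_category()] on the constructed profiles (with a fresh noise
#' draw on failure) and the realised values recorded in the truth table.
#'
#' @param transcripts Edited transcripts from [plant_sites()].
#' @param truth Truth table from [plant_sites()]; an optional `category`
#'   column gives the intended category per event (default 0), an optional
#'   `coincident_nt` column chooses the cleavage position (10 or 11,
#'   default 10).
#' @param depth Mean signature abundance at a planted site (default 50).
#' @param noise_fraction Fraction of total read mass that is background
#'   noise, in [0, 1) (default 0.1).
#' @param seed RNG seed.
#' @param read_lengths Candidate read lengths (default 20:21).
#' @param max_retries Noise re-draws allowed before giving up (default 5).
#' @return List: `reads` (tag data.frame `seq`, `count`), `truth` (input
#'   truth plus `site`, `coincident_nt`, `abundance`, `category`),
#'   `profiles` (the constructed per-transcript profiles).
#' @export
simulate_degradome <- function(transcripts, truth, depth = 50L,
                               noise_fraction = 0.1, seed = 1L,
                               read_lengths = 20:21, max_retries = 5L) {
  stopifnot(depth >= 1, noise_fraction >= 0, noise_fraction < 1)
  ev <- truth[!truth$control, , drop = FALSE]
  if (!"category" %in% names(ev)) ev$category <- 0L
  if (!"coincident_nt" %in% names(ev)) ev$coincident_nt <- 10L
  stopifnot(all(ev$category %in% 0:4), all(ev$coincident_nt %in% c(10L, 11L)))
  ev$site <- ifelse(ev$coincident_nt == 10L, ev$site10, ev$site11)

  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      profiles <- stats::setNames(
        lapply(transcripts$id, function(i) integer(0)), transcripts$id)
      bump <- function(tx, pos, n) {
        prof <- profiles[[tx]]
        key <- as.character(pos)
        prof[key] <- (if (key %in% names(prof)) prof[[key]] else 0L) + n
        profiles[[tx]] <<- prof
      }
      ev$abundance <- NA_integer_
      for (i in seq_len(nrow(ev))) {
        a <- if (ev$category[[i]] == 4L) 1L else
          max(2L, stats::rpois(1L, depth))
        ev$abundance[[i]] <- a
        bump(ev$transcript_id[[i]], ev$site[[i]], a)
        comp <- category_companions(ev$category[[i]], a)
        if (length(comp) > 0L) {
          L <- nchar(transcripts$seq[[match(ev$transcript_id[[i]],
                                            transcripts$id)]])
          avoid <- c(ev$site[ev$transcript_id == ev$transcript_id[[i]]])
          spots <- setdiff(seq_len(max(1L, L - 25L)), avoid)
          pos <- sample(spots, length(comp))
          for (j in seq_along(comp)) {
            bump(ev$transcript_id[[i]], pos[[j]], comp[[j]])
          }
        }
      }
      planted_mass <- sum(unlist(profiles))
      n_noise <- round(noise_fraction / (1 - noise_fraction) * planted_mass)
      placed <- 0L
      while (placed < n_noise) {
        ti <- sample.int(nrow(transcripts), 1L)
        L <- nchar(transcripts$seq[[ti]])
        pos <- sample.int(max(1L, L - 25L), 1L)
        n <- min(stats::rgeom(1L, 0.7) + 1L, n_noise - placed)
        bump(transcripts$id[[ti]], pos, n)
        placed <- placed + n
      }
      realized <- vapply(seq_len(nrow(ev)), function(i) {
        classify_category(profiles[[ev$transcript_id[[i]]]], ev$site[[i]])
      }, 0L)
      if (all(realized == ev$category)) break
      if (attempt == max_retries) {
        stop("intended categories unrealisable at this depth/noise after ",
             max_retries, " attempts")
      }
    }
    # emit reads from the realised profiles
    reads <- list()
    for (tx in names(profiles)) {
      prof <- profiles[[tx]]
      if (length(prof) == 0L) next
      seq_tx <- transcripts$seq[[match(tx, transcripts$id)]]
      L <- nchar(seq_tx)
      for (k in seq_along(prof)) {
        pos <- as.integer(names(prof)[[k]])
        len <- sample(read_lengths, 1L)
        len <- min(len, L - pos + 1L)
        reads[[length(reads) + 1L]] <- data.frame(
          seq = substr(seq_tx, pos, pos + len - 1L),
          count = unname(prof[[k]]), stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, reads)
    agg <- stats::aggregate(count ~ seq, reads, sum)
    ev$category <- vapply(seq_len(nrow(ev)), function(i) {
      classify_category(profiles[[ev$transcript_id[[i]]]], ev$site[[i]])
    }, 0L)
    list(reads = agg, truth = ev, profiles = profiles)
  })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Two conditions (S, F) at two stages (6, 7) with `replicates` libraries
#' each. A feature with planted effect `log2fc` at a stage has NB means
#' `mu * 2^(log2fc/2)` in S and `mu * 2^(-log2fc/2)` in F at that stage
#' (so the S/F log2 ratio is `log2fc`), variance `mu + dispersion * mu^2`.
#'
#' @param n_features Number of features.
#' @param effects Data.frame with columns `feature` (index or id), `stage`,
#'   `log2fc`; features not listed have effect 0. `NULL` for a global null.
#' @param replicates Libraries per condition per stage (default 3).
#' @param dispersion NB dispersion alpha (default 0.05).
#' @param mean_log_mu,sd_log_mu Log-normal baseline mean parameters
#'   (defaults log(200) and 1).
#' @param lib_size_range Uniform range of per-library scale factors
#'   (default c(0.7, 1.3)).
#' @param seed RNG seed.
#' @return List: `cm` (a [count_matrix()]) and `truth` (data.frame
#'   `feature_id`, `stage`, `true_log2fc`).
#' @export
simulate_counts <- function(n_features, effects = NULL, replicates = 3L,
                            dispersion = 0.05, mean_log_mu = log(200),
                            sd_log_mu = 1, lib_size_range = c(0.7, 1.3),
                            seed = 1L) {
  stopifnot(n_features >= 1, replicates >= 2L, dispersion > 0)
  with_seed(seed, {
    feats <- sprintf("G%05d", seq_len(n_features))
    delta <- matrix(0, nrow = n_features, ncol = 2L,
                    dimnames = list(feats, c("6", "7")))
    if (!is.null(effects) && nrow(effects) > 0L) {
      fidx <- if (is.numeric(effects$feature)) effects$feature else
        match(effects$feature, feats)
      stopifnot(!anyNA(fidx), all(effects$stage %in% c(6L, 7L)))
      delta[cbind(fidx, match(effects$stage, c(6L, 7L)))] <- effects$log2fc
    }
    mu <- stats::rlnorm(n_features, mean_log_mu, sd_log_mu)
    meta <- expand.grid(replicate = seq_len(replicates),
                        condition = c("S", "F"), stage = c(6L, 7L),
                        stringsAsFactors = FALSE)
    meta$library_id <- paste0(meta$condition, meta$stage, "_",
                              meta$replicate)
    meta <- meta[, c("library_id", "condition", "stage", "replicate")]
    lib_fac <- stats::runif(nrow(meta), lib_size_range[[1L]],
                            lib_size_range[[2L]])
    counts <- matrix(0L, nrow = n_features, ncol = nrow(meta),
                     dimnames = list(feats, meta$library_id))
    for (j in seq_len(nrow(meta))) {
      sgn <- if (meta$condition[[j]] == "S") 1 else -1
      m_j <- mu * 2^(sgn * delta[, as.character(meta$stage[[j]])] / 2) *
        lib_fac[[j]]
      counts[, j] <- stats::rnbinom(n_features, mu = m_j,
                                    size = 1 / dispersion)
    }
    storage.mode(counts) <- "integer"
    truth <- data.frame(
      feature_id = rep(feats, 2L),
      stage = rep(c(6L, 7L), each = n_features),
      true_log2fc = c(delta[, "6"], delta[, "7"]),
      stringsAsFactors = FALSE)
    list(cm = count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate a small-RNA tag table
#'
#' Tags with a planted modal length and first-base preference, for testing
#' the profiling operations.
#'
#' @param n_tags Number of distinct tags.
#' @param libraries Library names (default `c("S6", "F6")`).
#' @param length_probs Named numeric: probability of each tag length
#'   (default 40% 24-nt mode over 20-25).
#' @param u_first_prob Probability that a 21-nt tag starts with U
#'   (default 0.6); other lengths draw the first base uniformly.
#' @param mean_count Mean per-library abundance (geometric-ish, >= 1).
#' @param seed RNG seed.
#' @return Tag data.frame (`seq` + one column per library).
#' @export
simulate_tags <- function(n_tags, libraries = c("S6", "F6"),
                          length_probs = c("20" = 0.1, "21" = 0.2,
                                           "22" = 0.1, "23" = 0.1,
                                           "24" = 0.4, "25" = 0.1),
                          u_first_prob = 0.6, mean_count = 10, seed = 1L) {
  stopifnot(n_tags >= 1, abs(sum(length_probs) - 1) < 1e-9)
  with_seed(seed, {
    lens <- as.integer(sample(names(length_probs), n_tags, replace = TRUE,
                              prob = length_probs))
    seqs <- vapply(lens, function(L) {
      first <- if (L == 21L) {
        if (stats::runif(1) < u_first_prob) "T" else sample(c("A", "C", "G"), 1L)
      } else sample(c("A", "C", "G", "T"), 1L)
      paste(c(first, sample(c("A", "C", "G", "T"), L - 1L, replace = TRUE)),
            collapse = "")
    }, "")
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]
    out <- data.frame(seq = seqs, stringsAsFactors = FALSE)
    for (lib in libraries) {
      out[[lib]] <- stats::rpois(length(seqs), mean_count) + 1L
    }
    out
  })
}
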