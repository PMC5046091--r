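#' Extract a promoter window around a TSS
#'
#' Returns the promoter window used for motif scanning: by default the
#' 2 kb sequence from 1.5 kb upstream of the transcription start site to
#' 0.5 kb downstream, in transcript orientation. On the plus strand this is
#' the half-open interval [tss - upstream, tss + downstream) of the source
#' sequence; on the minus strand it is [tss - downstream, tss + upstream)
#' reverse-complemented, so that window position 0 is always -upstream
#' relative to the TSS in transcript orientation. Positions beyond the ends
#' of the source sequence are padded with N (with a warning).
#'
#' @param seq_source a single sequence string (e.g. a chromosome).
#' @param tss 0-based TSS position in `seq_source`.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window extent in bases.
#' @return A `PromoterWindow` list: `tss`, `strand`, `sequence` (length
#'   upstream + downstream), `upstream`, `downstream`.
#' @export
extract_promoter <- function(seq_source, tss, strand = "+",
                             upstream = 1500L, downstream = 500L) {
  stopifnot(strand %in% c("+", "-"))
  len <- nchar(seq_source)
  if (strand == "+") {
    from <- tss - upstream; to <- tss + downstream  # [from, to)
  } else {
    from <- tss - downstream; to <- tss + upstream
  }
  lo <- max(from, 0L); hi <- min(to, len)
  core <- if (hi > lo) substr(seq_source, lo + 1L, hi) else ""
  n_left <- lo - from; n_right <- to - hi
  if (n_left > 0 || n_right > 0)
    warning("promoter window at tss=", tss,
            " extends past the sequence; N-padded", call. = FALSE)
  seq <- paste0(strrep("N", n_left), core, strrep("N", n_right))
  if (strand == "-") seq <- revcomp(seq)
  structure(list(tss = tss, strand = strand, sequence = seq,
                 upstream = upstream, downstream = downstream),
            class = "PromoterWindow")
}

# reverse complement preserving case and N
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a log-odds score model from a position probability matrix
#'
#' Adds a pseudocount to the motif probabilities (renormalizing each
#' position), takes log2 odds against the background, and fixes the score
#' discretization step used for the exact p-value table:
#' granularity = (max attainable score - min attainable score) / 1000.
#'
#' @param ppm L x 4 position probability matrix (columns A, C, G, T).
#' @param background probability vector over A, C, G, T.
#' @param pseudocount probability added to each motif entry before log-odds.
#' @return A `ScoreModel` list: `log_odds` (L x 4, bits), `int_scores`
#'   (L x 4 integer-scaled scores), `granularity`, `background`.
#' @export
score_model <- function(ppm, background = c(A = .25, C = .25, G = .25,
                                            T = .25),
                        pseudocount = 1e-3) {
  stopifnot(ncol(ppm) == 4, abs(sum(background) - 1) < 1e-6)
  p <- (ppm + pseudocount) / (1 + 4 * pseudocount)
  lo <- log2(sweep(p, 2, background, "/"))
  range <- sum(apply(lo, 1, max)) - sum(apply(lo, 1, min))
  if (range <= 0) range <- 1  # uninformative motif; any granularity works
  g <- range / 1000
  ints <- round(lo / g)
  storage.mode(ints) <- "integer"
  structure(list(log_odds = lo, int_scores = ints, granularity = g,
                 background = background),
            class = "ScoreModel")
}

#' Exact tail distribution of a PWM match score under the background
#'
#' Computes, by position-wise convolution over the integer-discretized
#' per-position scores, the exact distribution of the total log-odds score
#' of a random background string of motif length, and returns the tail
#' P(score >= s). Scores are discretized once (in [score_model()]) and both
#' the table and the scanner operate on the same integer scores, so lookups
#' are exact for the discretized score.
#'
#' @param model a [score_model()].
#' @return A `ScorePvalueTable` list: `offset` (minimum attainable integer
#'   score), `tail` (numeric vector; `tail[s - offset + 1]` =
#'   P(int score >= s)), `granularity`.
#' @export
exact_score_pvalue_table <- function(model) {
  ints <- model$int_scores
  bg <- model$background
  lo_min <- sum(apply(ints, 1, min))
  lo_max <- sum(apply(ints, 1, max))
  nbin <- lo_max - lo_min + 1L
  if (nbin < 100L)
    warning("score granularity is coarse (", nbin,
            " bins); p-values may be lumpy", call. = FALSE)
  # pmf over integer total scores, indexed score - lo_min + 1
  pmf <- numeric(nbin)
  # running support after i positions: [run_min, run_max]
  run_min <- 0L; run_max <- 0L
  pmf[1] <- 1  # before any position: score 0 with prob 1 (temporary origin)
  cur <- c(1, numeric(nbin - 1L))
  for (i in seq_len(nrow(ints))) {
    nxt <- numeric(nbin)
    smin <- min(ints[i, ]); smax <- max(ints[i, ])
    new_min <- run_min + smin
    sup <- which(cur > 0)
    for (b in 1:4) {
      s <- ints[i, b]
      # shift: previous support offset run_min maps to new offset new_min
      shift <- (run_min + s) - new_min
      idx <- sup + shift
      nxt[idx] <- nxt[idx] + cur[sup] * bg[b]
    }
    cur <- nxt
    run_min <- new_min
    run_max <- run_max + smax
  }
  tail <- rev(cumsum(rev(cur)))
  structure(list(offset = run_min, tail = tail,
                 granularity = model$granularity),
            class = "ScorePvalueTable")
}

# P(int score >= s) for integer score s
lookup_tail <- function(table, s) {
  i <- s - table$offset + 1L
  n <- length(table$tail)
  out <- numeric(length(s))
  out[i <= 1L] <- 1
  mid <- i > 1L & i <= n
  out[mid] <- table$tail[i[mid]]
  out[i > n] <- 0
  out
}

# integer match score of a motif at every offset of a character-vector
# sequence; NA where the footprint contains an unscannable base
slide_scores <- function(chars, ints) {
  L <- nrow(ints)
  W <- length(chars)
  if (W < L) return(integer(0))
  base_idx <- match(chars, c("A", "C", "G", "T"))
  n_off <- W - L + 1L
  scores <- integer(n_off)
  ok <- !is.na(base_idx)
  good <- rep(TRUE, n_off)
  for (i in seq_len(L)) {
    idx <- base_idx[i:(i + n_off - 1L)]
    bad <- is.na(idx)
    good <- good & !bad
    idx[bad] <- 1L
    scores <- scores + ints[i, idx]
  }
  scores[!good] <- NA_integer_
  scores
}

#' Scan promoter windows with a motif set
#'
#' Slides each motif over every offset of every window, on the forward
#' strand and (by default) the reverse strand, scoring with the
#' discretized log-odds model and converting scores to exact match p-values
#' via [exact_score_pvalue_table()]. Match footprints containing N or
#' lowercase (repeat-masked) bases are skipped. Hits with p <= `p_threshold`
#' are returned. Minus-strand hits are reported at the forward-coordinate
#' offset of the leftmost base of the site.
#'
#' @param windows named list of window sequences (strings) or
#'   `PromoterWindow` objects; names are the target identifiers.
#' @param motifs a `MotifSet` (see [read_motifs_meme()]).
#' @param p_threshold per-match p-value cutoff.
#' @param both_strands logical; also scan the reverse strand.
#' @param pseudocount passed to [score_model()].
#' @return data.frame of `MotifHit`s: `tf`, `target`, `offset`, `strand`,
#'   `score`, `p_value`.
#' @export
scan_promoters <- function(windows, motifs, p_threshold = 0.05,
                           both_strands = TRUE, pseudocount = 1e-3) {
  seqs <- lapply(windows, function(w)
    if (inherits(w, "PromoterWindow")) w$sequence else w)
  hits <- list()
  for (tf in names(motifs$motifs)) {
    mod <- score_model(motifs$motifs[[tf]], motifs$background,
                       pseudocount = pseudocount)
    tab <- exact_score_pvalue_table(mod)
    # reverse-strand scores: scan with the reverse-complement matrix so
    # offsets stay in forward coordinates
    rc_ints <- mod$int_scores[rev(seq_len(nrow(mod$int_scores))),
                              c(4, 3, 2, 1), drop = FALSE]
    for (target in names(seqs)) {
      chars <- strsplit(seqs[[target]], "")[[1]]  # lowercase = masked
      fwd <- slide_scores(chars, mod$int_scores)
      strands <- list(`+` = fwd)
      if (both_strands) strands$`-` <- slide_scores(chars, rc_ints)
      for (st in names(strands)) {
        sc <- strands[[st]]
        off <- which(!is.na(sc))
        if (!length(off)) next
        p <- lookup_tail(tab, sc[off])
        keep <- p <= p_threshold
        if (!any(keep)) next
        hits[[length(hits) + 1L]] <- data.frame(
          tf = tf, target = target, offset = off[keep] - 1L, strand = st,
          score = sc[off[keep]] * mod$granularity, p_value = p[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(tf = character(), target = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Reduce hits to unique pairs and keep the top fraction
#'
#' Reduces motif hits to one record per (tf, target) pair keeping the
#' smallest p-value, sorts ascending by p (ties broken lexicographically by
#' tf then target), and retains the top `ceiling(top_fraction * n_pairs)`
#' pairs.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param top_fraction fraction of unique pairs to retain.
#' @return data.frame `tf`, `target`, `p_value`, best hit per pair, top
#'   fraction only.
#' @export
rank_and_truncate <- function(hits, top_fraction = 0.01) {
  if (!nrow(hits))
    return(data.frame(tf = character(), target = character(),
                      p_value = numeric()))
  key <- paste(hits$tf, hits$target, sep = "\r")
  best <- tapply(hits$p_value, key, min)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  pairs <- data.frame(tf = vapply(parts, `[`, "", 1),
                      target = vapply(parts, `[`, "", 2),
                      p_value = as.numeric(best),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p_value, pairs$tf, pairs$target), , drop = FALSE]
  n_keep <- ceiling(top_fraction * nrow(pairs))
  out <- pairs[seq_len(n_keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
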