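test_that("promoter windows use the strand-oriented 1.5kb/0.5kb frame", {
  src <- paste(rep("A", 3000), collapse = "")
  w <- extract_promoter(src, tss = 1500, strand = "+")
  expect_equal(nchar(w$sequence), 2000L)
  expect_equal(w$sequence, substr(src, 1, 2000))
  # near the sequence start the missing upstream part is N-padded
  expect_warning(w2 <- extract_promoter(src, tss = 100, strand = "+"),
                 "N-padded")
  expect_equal(substr(w2$sequence, 1, 1400), strrep("N", 1400))
  expect_equal(substr(w2$sequence, 1401, 2000), strrep("A", 600))
  # minus strand: a unique marker lands reverse-complemented at the
  # mirrored offset. Marker G at source position 2000 (0-based); window
  # [tss-500, tss+1500) = [1000, 3000) reverse-complemented, so the
  # marker sits at window position (3000 - 1) - 2000 = 999 as C.
  src3 <- paste0(strrep("A", 2000), "G", strrep("A", 999))
  w3 <- extract_promoter(src3, tss = 1500, strand = "-")
  expect_equal(nchar(w3$sequence), 2000L)
  expect_equal(substr(w3$sequence, 1000, 1000), "C")
  expect_equal(gsub("C", "", w3$sequence), strrep("T", 1999))
})

test_that("single-position score tails equal base probabilities", {
  # near-degenerate A column: only A attains the maximum score, so
  # P(score >= max) is the background probability of A
  ppm <- matrix(c(1, 0, 0, 0), 1, dimnames = list(NULL, c("A", "C", "G", "T")))
  mod <- score_model(ppm)
  tab <- exact_score_pvalue_table(mod)
  expect_equal(mirnetcons:::lookup_tail(tab, max(mod$int_scores)), 0.25)
  # minimum attainable score has full tail mass
  expect_equal(mirnetcons:::lookup_tail(tab, min(mod$int_scores)), 1)
})

test_that("DP tail probabilities equal exhaustive enumeration (L <= 6)", {
  set.seed(14)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (L in 2:6) {
    ppm <- t(vapply(seq_len(L), function(i) {
      x <- rgamma(4, 1); x / sum(x)
    }, numeric(4)))
    colnames(ppm) <- c("A", "C", "G", "T")
    mod <- score_model(ppm, background = bg)
    tab <- exact_score_pvalue_table(mod)
    # enumerate all 4^L strings with their background probabilities
    grids <- do.call(expand.grid, rep(list(1:4), L))
    scores <- as.matrix(grids)
    int_s <- vapply(seq_len(nrow(scores)), function(r)
      sum(mod$int_scores[cbind(seq_len(L), scores[r, ])]), integer(1))
    probs <- apply(scores, 1, function(r) prod(bg[r]))
    for (s in sort(unique(int_s)))
      expect_equal(mirnetcons:::lookup_tail(tab, s),
                   sum(probs[int_s >= s]), tolerance = 1e-12)
  }
})

test_that("scanning finds planted consensus sites at their exact offsets", {
  motifs <- test_motifs()
  prom <- simulate_promoters(motifs, n_promoters = 10, plant_fraction = 0.6,
                             seed = 31)
  hits <- scan_promoters(prom$sequences, motifs, p_threshold = 1e-4)
  for (i in seq_len(nrow(prom$sites))) {
    s <- prom$sites[i, ]
    match <- hits[hits$tf == s$tf & hits$target == s$promoter &
                  hits$offset == s$offset & hits$strand == s$strand, ]
    expect_equal(nrow(match), 1L,
                 info = paste("site", s$tf, s$promoter, s$offset, s$strand))
    # the planted consensus attains the motif's minimum attainable p
    mod <- score_model(motifs$motifs[[s$tf]], motifs$background)
    expect_equal(match$score, sum(apply(mod$int_scores, 1, max)) *
                   mod$granularity)
  }
})

test_that("unscannable bases are skipped", {
  motifs <- test_motifs()
  allN <- list(pN = strrep("N", 2000))
  expect_equal(nrow(scan_promoters(allN, motifs, p_threshold = 1)), 0L)
  # lowercase (repeat-masked) footprints are skipped too
  masked <- list(pm = paste0(strrep("a", 100), strrep("A", 100)))
  h <- scan_promoters(masked, motifs, p_threshold = 1, both_strands = FALSE)
  L <- nrow(motifs$motifs$TFA)
  expect_true(all(h$offset >= 100))
})

test_that("offset count and strand symmetry behave as expected", {
  ppm <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ppm[cbind(1:4, c(1, 2, 3, 4))] <- 0.7
  ppm <- ppm / rowSums(ppm)
  ms <- structure(list(motifs = list(M = ppm),
                       background = c(A = .25, C = .25, G = .25, T = .25)),
                  class = "MotifSet")
  # 10-base window, 4-base motif, single strand, p_threshold 1: 7 offsets
  h <- scan_promoters(list(w = "ACGTACGTAC"), ms, p_threshold = 1,
                      both_strands = FALSE)
  expect_equal(nrow(h), 7L)
  expect_setequal(h$offset, 0:6)
  # scanning the reverse complement yields the mirrored hit set
  w <- "ACGGTTACGTGCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
  h1 <- scan_promoters(list(w = w), ms, p_threshold = 1)
  h2 <- scan_promoters(list(w = rc), ms, p_threshold = 1)
  L <- 4; W <- nchar(w)
  mirror <- function(h) {
    h$offset <- W - L - h$offset
    h$strand <- ifelse(h$strand == "+", "-", "+")
    h[order(h$strand, h$offset), c("offset", "strand", "score", "p_value")]
  }
  expect_equal(mirror(h2),
               h1[order(h1$strand, h1$offset),
                  c("offset", "strand", "score", "p_value")],
               ignore_attr = TRUE)
})

test_that("threshold and truncation monotonicity hold", {
  motifs <- test_motifs()
  prom <- simulate_promoters(motifs, n_promoters = 5, plant_fraction = 0.4,
                             seed = 8)
  loose <- scan_promoters(prom$sequences, motifs, p_threshold = 0.05)
  tight <- scan_promoters(prom$sequences, motifs, p_threshold = 0.001)
  keys <- function(h) paste(h$tf, h$target, h$offset, h$strand)
  expect_true(all(keys(tight) %in% keys(loose)))
  r1 <- rank_and_truncate(loose, 0.1)
  r2 <- rank_and_truncate(loose, 0.3)
  expect_true(all(paste(r1$tf, r1$target) %in% paste(r2$tf, r2$target)))
})

test_that("rank_and_truncate keeps the best hit per pair and the top slice", {
  hits <- data.frame(
    tf = c("T1", "T1", "T2"), target = c("g", "g", "g"),
    offset = c(1L, 5L, 2L), strand = "+", score = c(5, 4, 3),
    p_value = c(0.04, 0.01, 0.02), stringsAsFactors = FALSE)
  out <- rank_and_truncate(hits, top_fraction = 1)
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_value[out$tf == "T1"], 0.01)
  # ceil(0.01 * 300) = 3 pairs retained
  big <- data.frame(tf = paste0("T", 1:300), target = "g", offset = 0L,
                    strand = "+", score = 1,
                    p_value = seq(0.001, 0.3, length.out = 300),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(rank_and_truncate(big, 0.01)), 3L)
  # random fixture equals the naive sort-and-slice oracle
  set.seed(3)
  rnd <- data.frame(tf = sample(paste0("T", 1:20), 200, TRUE),
                    target = sample(paste0("g", 1:10), 200, TRUE),
                    offset = 0L, strand = "+", score = 0,
                    p_value = runif(200), stringsAsFactors = FALSE)
  out <- rank_and_truncate(rnd, 0.2)
  agg <- aggregate(p_value ~ tf + target, rnd, min)
  agg <- agg[order(agg$p_value, agg$tf, agg$target), ]
  expected <- head(agg, ceiling(0.2 * nrow(agg)))
  expect_equal(out$p_value, expected$p_value)
  expect_equal(paste(out$tf, out$target),
               paste(expected$tf, expected$target))
  expect_equal(nrow(rank_and_truncate(rnd[0, ], 0.01)), 0L)
})
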