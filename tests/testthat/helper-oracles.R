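# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles never call the implementation paths they check.

# tiny ExpressionDataset from case/control value matrices
make_ds <- function(case, ctrl, features = NULL, id = "ds") {
  case <- as.matrix(case); ctrl <- as.matrix(ctrl)
  if (is.null(features)) features <- paste0("f", seq_len(nrow(case)))
  vals <- cbind(case, ctrl)
  colnames(vals) <- c(paste0("case_", seq_len(ncol(case))),
                      paste0("ctrl_", seq_len(ncol(ctrl))))
  rownames(vals) <- features
  groups <- setNames(rep(c("case", "control"), c(ncol(case), ncol(ctrl))),
                     colnames(vals))
  expression_dataset(vals, groups, dataset_id = id)
}

# random signed directed graph as an edge data.frame (single category so
# role constraints cannot bite)
random_signed_digraph <- function(n = 12, p = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(src = nodes, dst = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  keep <- runif(nrow(pairs)) < p
  ed <- pairs[keep, , drop = FALSE]
  ed$sign <- sample(c(1L, -1L), nrow(ed), replace = TRUE)
  ed$category <- "tf_gene"
  ed$evidence <- "predicted"
  rownames(ed) <- NULL
  ed
}

# O(n^3) feed-forward loop oracle over an edge data.frame
oracle_ffl <- function(edges) {
  key <- paste(edges$src, edges$dst)
  sgn <- setNames(edges$sign, key)
  nodes <- unique(c(edges$src, edges$dst))
  out <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x == y || y == z || x == z) next
    kxy <- paste(x, y); kyz <- paste(y, z); kxz <- paste(x, z)
    if (kxy %in% key && kyz %in% key && kxz %in% key) {
      out[[length(out) + 1]] <- data.frame(
        x = x, y = y, z = z,
        coherent = sgn[kxz] == sgn[kxy] * sgn[kyz],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(x = character(), y = character(), z = character(),
                      coherent = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$x, res$y, res$z), ]
}

# brute-force simple directed cycles of length <= max_len, canonicalized
# so each cycle is one row (rotated to start at its smallest node)
oracle_cycles <- function(edges, max_len = 2) {
  key <- paste(edges$src, edges$dst)
  sgn <- setNames(edges$sign, key)
  nodes <- sort(unique(c(edges$src, edges$dst)))
  found <- new.env()
  res <- list()
  try_cycle <- function(path) {
    ks <- paste(path, c(path[-1], path[1]))
    if (!all(ks %in% key)) return()
    rot <- which(path == min(path))[1]
    canon <- paste(c(path[rot:length(path)], path[seq_len(rot - 1)]),
                   collapse = "|")
    if (!is.null(found[[canon]])) return()
    found[[canon]] <- TRUE
    nrep <- sum(sgn[ks] < 0)
    res[[length(res) + 1]] <<- data.frame(
      cycle = canon, length = length(path), n_repression = nrep,
      sign = if (nrep %% 2 == 0) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  if (max_len >= 2)
    for (a in nodes) for (b in nodes) if (a < b) try_cycle(c(a, b))
  if (max_len >= 3)
    for (a in nodes) for (b in nodes) for (c in nodes)
      if (a != b && b != c && a != c) try_cycle(c(a, b, c))
  if (!length(res))
    return(data.frame(cycle = character(), length = integer(),
                      n_repression = integer(), sign = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$cycle), ]
}

# exhaustive expectation of the consensus-count statistic: all datasets
# draw a subset of the given size from their universe; returns E[T] where
# T = #features present in >= k_min subsets. Enumerates every combination.
oracle_perm_expectation <- function(universe_size, subset_sizes, k_min) {
  subsets <- combn(universe_size, subset_sizes[1])
  masks <- t(apply(subsets, 2, function(s) {
    m <- integer(universe_size); m[s] <- 1L; m
  }))  # n_subsets x universe_size
  stopifnot(length(unique(subset_sizes)) == 1)  # equal sizes suffice here
  ns <- nrow(masks)
  # accumulate counts over dataset pairs to limit memory
  idx2 <- expand.grid(seq_len(ns), seq_len(ns))
  p2 <- masks[idx2[[1]], ] + masks[idx2[[2]], ]  # ns^2 x U
  total <- 0
  for (i in seq_len(nrow(p2))) {
    counts <- sweep(p2, 2, p2[i, ], "+")
    total <- total + sum(counts >= k_min)
  }
  total / (nrow(p2)^2)
}

# small sharp test motif set
test_motifs <- function() mirnetcons:::builtin_motifs()
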