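#' Consensus configuration
#'
#' Parameters of the cross-dataset consensus call: the per-dataset
#' significance threshold `alpha` (raw t-test p-value, no per-dataset
#' multiple-testing correction — the consensus and permutation tests are the
#' error control), the minimum number of supporting datasets `k_min`, and
#' whether the supporting datasets must agree in direction.
#'
#' @param alpha per-dataset significance threshold, in (0, 1).
#' @param k_min minimum number of datasets with p <= alpha.
#' @param require_direction logical; require a consistent direction of
#'   change across all supporting datasets.
#' @return A `ConsensusConfig` list.
#' @export
consensus_config <- function(alpha = 0.05, k_min = 3L,
                             require_direction = TRUE) {
  stopifnot(alpha > 0, alpha < 1, k_min >= 1)
  structure(list(alpha = alpha, k_min = as.integer(k_min),
                 require_direction = isTRUE(require_direction)),
            class = "ConsensusConfig")
}

#' Per-dataset differential expression
#'
#' For every feature, a two-sided two-sample t-test between case and control
#' samples (Welch's unequal-variance form by default, Student's pooled form
#' via `var_equal = TRUE`), the fold-change defined as the ratio of the mean
#' case intensity to the mean control intensity, and the direction of
#' change: up if the ratio exceeds 1, down if below 1, unchanged if exactly
#' 1. A feature whose values are identical in both groups with zero
#' variance gets p = 1 and fold-change 1. Features with a zero control mean
#' have no finite fold-change; they are excluded from the returned table and
#' reported in the `excluded` attribute with a warning.
#'
#' @param ds an `ExpressionDataset`.
#' @param var_equal logical; TRUE selects the pooled-variance Student test.
#' @return A data.frame with columns `feature`, `p_value`, `fold_change`,
#'   `direction` (attribute `excluded`: features dropped for zero control
#'   mean).
#' @export
differential_expression <- function(ds, var_equal = FALSE) {
  case <- ds$values[, ds$groups == "case", drop = FALSE]
  ctrl <- ds$values[, ds$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate features: no variance anywhere
  flat <- se == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- 0
  fc <- m1 / m2
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "unchanged"))
  res <- data.frame(feature = rownames(ds$values), p_value = p,
                    fold_change = fc, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  drop <- m2 == 0
  if (any(drop)) {
    warning(sum(drop), " feature(s) with zero control mean excluded in ",
            ds$dataset_id, call. = FALSE)
    res <- res[!drop, , drop = FALSE]
  }
  attr(res, "excluded") <- rownames(ds$values)[drop]
  res
}

#' Cross-dataset consensus calls
#'
#' Combines per-dataset differential-expression tables into one call per
#' feature. A feature's supporting datasets are those in which it was
#' measured and significant (p <= alpha). `passes_overlap` requires at
#' least `k_min` supporting datasets; `passes_direction` additionally
#' requires all supporting datasets to agree on a non-"unchanged" direction.
#' Features absent from a platform simply lack that dataset's vote.
#'
#' @param de_tables named list of data.frames from
#'   [differential_expression()], one per dataset.
#' @param cfg a [consensus_config()].
#' @return A data.frame with one row per feature seen in any table:
#'   `feature`, `n_significant`, `supporting_datasets` (comma-joined),
#'   `consensus_direction` (the agreed direction or NA), `passes_overlap`,
#'   `passes_direction`.
#' @export
consensus_select <- function(de_tables, cfg = consensus_config()) {
  stopifnot(length(de_tables) >= cfg$k_min)
  if (is.null(names(de_tables)))
    names(de_tables) <- paste0("dataset", seq_along(de_tables))
  features <- sort(unique(unlist(lapply(de_tables, `[[`, "feature"))))
  sig <- vapply(de_tables, function(tab) {
    out <- rep(FALSE, length(features))
    out[match(tab$feature, features)] <- tab$p_value <= cfg$alpha
    out
  }, logical(length(features)))
  dirs <- vapply(de_tables, function(tab) {
    out <- rep(NA_character_, length(features))
    out[match(tab$feature, features)] <- tab$direction
    out
  }, character(length(features)))
  dim(sig) <- dim(dirs) <- c(length(features), length(de_tables))
  n_sig <- rowSums(sig)
  passes_overlap <- n_sig >= cfg$k_min
  passes_direction <- vapply(seq_along(features), function(i) {
    if (!passes_overlap[i]) return(FALSE)
    d <- dirs[i, sig[i, ]]
    length(unique(d)) == 1L && d[1] != "unchanged"
  }, logical(1))
  consensus_direction <- ifelse(passes_direction,
                                vapply(seq_along(features), function(i)
                                  dirs[i, which(sig[i, ])[1]], character(1)),
                                NA_character_)
  supporting <- vapply(seq_along(features), function(i)
    paste(names(de_tables)[sig[i, ]], collapse = ","), character(1))
  data.frame(feature = features, n_significant = n_sig,
             supporting_datasets = supporting,
             consensus_direction = consensus_direction,
             passes_overlap = passes_overlap,
             passes_direction = passes_direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# observed consensus count for a set of per-dataset selections
count_consensus <- function(selected, k_min, directions = NULL) {
  feats <- unlist(selected, use.names = FALSE)
  tab <- table(feats)
  hit <- names(tab)[tab >= k_min]
  if (is.null(directions)) return(length(hit))
  sum(vapply(hit, function(f) {
    d <- vapply(seq_along(selected), function(j) {
      if (f %in% selected[[j]]) directions[[j]][[f]] else NA_character_
    }, character(1))
    d <- d[!is.na(d)]
    length(unique(d)) == 1L && d[1] != "unchanged"
  }, logical(1)))
}

#' Permutation test of the consensus count
#'
#' Assesses whether the observed number of consensus features could arise by
#' chance given the per-dataset platform universes and the observed numbers
#' of significant features. Each of `B` replicates draws, for every dataset,
#' a uniform random subset of that dataset's universe of the same size as
#' its observed significant set, and counts features selected in at least
#' `k_min` datasets. With `require_direction`, a sampled feature inherits
#' the direction of its observed fold-change in that dataset (directions are
#' a fixed per-dataset labeling; only set membership is randomized), and the
#' count is restricted to features whose selecting datasets agree on a
#' non-"unchanged" direction; with `direction_mode = "random_sign"`,
#' directions are instead assigned i.i.d. up/down.
#'
#' The reported p-value is r/B where r is the number of replicates with a
#' null count at least the observed count; when r = 0 the resolution bound
#' 1/B is reported and flagged (`p_is_bound`). `conservative = TRUE`
#' switches to (r+1)/(B+1).
#'
#' @param universes named list of character vectors: each dataset's measured
#'   feature universe.
#' @param de_sets named list of character vectors: each dataset's observed
#'   significant features (subset of its universe).
#' @param cfg a [consensus_config()]; `k_min` and `require_direction` are
#'   used.
#' @param B number of permutation replicates.
#' @param seed integer seed.
#' @param directions named list (parallel to `universes`) of named direction
#'   vectors ("up"/"down"/"unchanged") covering at least each universe's
#'   features; required when `cfg$require_direction` is TRUE with the
#'   default `direction_mode`.
#' @param direction_mode `"observed"` (inherit per-dataset labels) or
#'   `"random_sign"`.
#' @param conservative logical; use the (r+1)/(B+1) estimator.
#' @return A `PermutationResult` list: `observed`, `null_counts`,
#'   `exceedances`, `B`, `p_report`, `p_is_bound`, `seed`.
#' @export
permutation_consensus_test <- function(universes, de_sets,
                                       cfg = consensus_config(),
                                       B = 5000L, seed = 1L,
                                       directions = NULL,
                                       direction_mode = c("observed",
                                                          "random_sign"),
                                       conservative = FALSE) {
  direction_mode <- match.arg(direction_mode)
  if (B <= 0) stop("B must be positive", call. = FALSE)
  stopifnot(length(universes) == length(de_sets))
  for (j in seq_along(universes)) {
    if (length(de_sets[[j]]) > length(universes[[j]]))
      stop("dataset ", j, ": more significant features than universe",
           call. = FALSE)
  }
  use_dir <- cfg$require_direction
  if (use_dir && direction_mode == "observed" && is.null(directions))
    stop("directions required when require_direction = TRUE", call. = FALSE)
  obs_dirs <- if (use_dir) {
    if (direction_mode == "observed") directions else
      # observed statistic still uses the real directions if given
      directions
  } else NULL
  observed <- count_consensus(de_sets, cfg$k_min, obs_dirs)
  sizes <- lengths(de_sets)
  set.seed(seed)
  null_counts <- integer(B)
  n_feat_total <- length(unique(unlist(universes)))
  feat_index <- stats::setNames(seq_len(n_feat_total),
                                unique(unlist(universes)))
  uni_idx <- lapply(universes, function(u) unname(feat_index[u]))
  dir_idx <- if (use_dir && direction_mode == "observed") {
    lapply(seq_along(universes), function(j) {
      d <- directions[[j]][universes[[j]]]
      unname(match(d, c("up", "down", "unchanged")))
    })
  } else NULL
  k_min <- cfg$k_min
  n_ds <- length(universes)
  for (b in seq_len(B)) {
    picks <- lapply(seq_len(n_ds), function(j)
      sample(length(uni_idx[[j]]), sizes[j]))
    sel <- unlist(lapply(seq_len(n_ds), function(j)
      uni_idx[[j]][picks[[j]]]), use.names = FALSE)
    cnt <- tabulate(sel, nbins = n_feat_total)
    if (!use_dir) {
      null_counts[b] <- sum(cnt >= k_min)
    } else {
      hit <- which(cnt >= k_min)
      if (!length(hit)) { null_counts[b] <- 0L; next }
      # per selected feature, the multiset of direction labels it carries
      dirs_sel <- if (direction_mode == "observed") {
        unlist(lapply(seq_len(n_ds), function(j)
          dir_idx[[j]][picks[[j]]]), use.names = FALSE)
      } else {
        sample(1:2, length(sel), replace = TRUE)
      }
      up <- tabulate(sel[dirs_sel == 1L], nbins = n_feat_total)
      dn <- tabulate(sel[dirs_sel == 2L], nbins = n_feat_total)
      null_counts[b] <- sum((up[hit] == cnt[hit] | dn[hit] == cnt[hit]))
    }
  }
  r <- sum(null_counts >= observed)
  p_is_bound <- !conservative && r == 0L
  p_report <- if (conservative) (r + 1) / (B + 1)
  else if (r == 0L) 1 / B else r / B
  structure(list(observed = observed, null_counts = null_counts,
                 exceedances = r, B = as.integer(B), p_report = p_report,
                 p_is_bound = p_is_bound, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Permutation consensus test: observed = %d, B = %d, r = %d, p %s %g\n",
              x$observed, x$B, x$exceedances,
              if (x$p_is_bound) "<" else "=", x$p_report))
  invisible(x)
}

#' Arithmetic mean of per-dataset fold-changes
#'
#' Summary used for reporting a single fold-change per consensus feature:
#' the arithmetic mean of its per-dataset fold-changes (over datasets where
#' the feature was measured). Labelled as an arithmetic mean because
#' fold-changes are ratios and other summaries (geometric mean) exist.
#'
#' @param de_tables named list of [differential_expression()] tables.
#' @param features character vector of features to summarize.
#' @return Named numeric vector of mean fold-changes.
#' @export
mean_fold_change <- function(de_tables, features) {
  vapply(features, function(f) {
    fcs <- unlist(lapply(de_tables, function(tab)
      tab$fold_change[tab$feature == f]))
    mean(fcs)
  }, numeric(1))
}
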