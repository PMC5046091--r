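#' Filter validated miRNA-target records
#'
#' Keeps only interactions with causal experimental support: TarBase-style
#' records pass iff the validation method is exactly "reporter gene assay"
#' (case-insensitive) — correlation-only methods such as microarray or
#' sequencing are discarded — and miRTarBase-style records pass unless the
#' support type is classified "weak" (case-insensitive; any other value,
#' including missing, counts as non-weak). The result is the deduplicated
#' union of passing (miRNA, gene) pairs.
#'
#' @param records data.frame with columns `mirna`, `gene`, `database`
#'   (tarbase/mirtarbase), `method`, `support`.
#' @return data.frame of unique pairs: `mirna`, `gene`.
#' @export
filter_validated <- function(records) {
  if (!nrow(records)) return(data.frame(mirna = character(),
                                        gene = character()))
  db <- tolower(records$database)
  unknown <- setdiff(unique(db), c("tarbase", "mirtarbase"))
  if (length(unknown))
    stop("unknown validated-target database tag(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- ifelse(db == "tarbase",
                 tolower(trimws(records$method)) == "reporter gene assay",
                 !(tolower(trimws(records$support)) %in% "weak"))
  keep[is.na(keep)] <- FALSE
  pairs <- unique(data.frame(mirna = records$mirna[keep],
                             gene = toupper(records$gene[keep]),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

#' Filter and intersect predicted miRNA-target records
#'
#' Applies each prediction database's score cutoff (all boundaries
#' inclusive): TargetScan context score <= -0.19, microT-CDS miTG score
#' >= 0.993, miRDB score >= 84. Only pairs passing the cutoff in all three
#' databases are returned.
#'
#' @param records data.frame with columns `mirna`, `gene`, `database`
#'   (targetscan/mirdb/microt_cds), `score`.
#' @param cutoffs named numeric vector of per-database cutoffs.
#' @return data.frame of unique pairs `mirna`, `gene` present above cutoff
#'   in all three databases.
#' @export
filter_predicted <- function(records,
                             cutoffs = c(targetscan = -0.19,
                                         microt_cds = 0.993, mirdb = 84)) {
  empty <- data.frame(mirna = character(), gene = character())
  if (!nrow(records)) return(empty)
  db <- tolower(records$database)
  unknown <- setdiff(unique(db), names(cutoffs))
  if (length(unknown))
    stop("unknown predicted-target database tag(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pass <- ifelse(db == "targetscan",
                 records$score <= cutoffs["targetscan"],
                 records$score >= cutoffs[db])
  key <- function(i) paste(records$mirna[i], toupper(records$gene[i]),
                           sep = "\r")
  pass_sets <- lapply(names(cutoffs), function(d)
    unique(key(which(pass & db == d))))
  common <- Reduce(intersect, pass_sets)
  if (!length(common)) return(empty)
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out[order(out$mirna, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Merge validated and predicted target pairs into an edge list
#'
#' Deduplicated union of the two pair sets. Every edge is a miRNA-target
#' interaction, sign repression by default (overridable later by explicit
#' curated records), with evidence "validated", "predicted" or "both".
#'
#' @param validated,predicted data.frames of pairs (`mirna`, `gene`).
#' @return Edge data.frame: `src`, `dst`, `sign`, `category`, `evidence`.
#' @export
merge_target_edges <- function(validated, predicted) {
  vkey <- paste(validated$mirna, validated$gene, sep = "\r")
  pkey <- paste(predicted$mirna, predicted$gene, sep = "\r")
  all_key <- union(vkey, pkey)
  if (!length(all_key))
    return(data.frame(src = character(), dst = character(),
                      sign = integer(), category = character(),
                      evidence = character()))
  parts <- strsplit(all_key, "\r", fixed = TRUE)
  evid <- ifelse(all_key %in% vkey & all_key %in% pkey, "both",
                 ifelse(all_key %in% vkey, "validated", "predicted"))
  data.frame(src = vapply(parts, `[`, "", 1),
             dst = vapply(parts, `[`, "", 2),
             sign = -1L, category = "mirna_target", evidence = evid,
             stringsAsFactors = FALSE)
}

#' Materialize reciprocal miRNA-to-TF edges from feedback-flagged records
#'
#' For every curated TF-miRNA regulation record flagged as a feedback pair
#' (a reciprocal repression of the TF by the miRNA exists), emits the
#' miRNA -> TF edge as a miRNA-target interaction (sign repression) and
#' unions it into the existing target edge list with deduplication, so a
#' pair already present in the target set is not double-counted.
#'
#' @param tfregs data.frame with columns `tf`, `mirna`, `sign`, `feedback`
#'   (logical).
#' @param target_edges edge data.frame from [merge_target_edges()].
#' @return The augmented edge data.frame.
#' @export
feedback_partner_edges <- function(tfregs, target_edges) {
  fb <- tfregs[isTRUE_vec(tfregs$feedback), , drop = FALSE]
  if (!nrow(fb)) return(target_edges)
  new <- unique(data.frame(src = fb$mirna, dst = toupper(fb$tf),
                           sign = -1L, category = "mirna_target",
                           evidence = "validated",
                           stringsAsFactors = FALSE))
  have <- paste(target_edges$src, target_edges$dst, sep = "\r")
  add <- new[!paste(new$src, new$dst, sep = "\r") %in% have, , drop = FALSE]
  out <- rbind(target_edges, add)
  rownames(out) <- NULL
  out
}

# TRUE for TRUE / "TRUE" / "true" / "x" / 1; FALSE otherwise (incl. NA)
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  v <- tolower(trimws(as.character(x)))
  !is.na(v) & v %in% c("true", "x", "1", "yes")
}
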