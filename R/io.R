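#' Read an expression matrix and its group file
#'
#' Reads a tab-separated expression table (first column feature names, header
#' row sample identifiers) together with a two-column tab-separated group
#' file (`sample<TAB>group`, group in case/control) and returns an
#' [expression_dataset()].
#'
#' Values are treated as linear-scale normalized intensities, because
#' fold-change is later computed as a ratio of group means. Matrices stored
#' on the log2 scale can be exponentiated on read with `log2_input = TRUE`.
#' An optional `include_samples` vector restricts the dataset to a subset of
#' samples, which covers longitudinal designs where only one sample per
#' subject enters the analysis.
#'
#' @param path path to the tab-separated expression matrix.
#' @param groups_path path to the tab-separated group file.
#' @param log2_input logical; if TRUE, values are 2^x-transformed on read.
#' @param include_samples optional character vector of sample ids to keep.
#' @param dataset_id dataset identifier; defaults to the file name.
#' @return An `ExpressionDataset`.
#' @export
read_expression_matrix <- function(path, groups_path, log2_input = FALSE,
                                   include_samples = NULL,
                                   dataset_id = basename(path)) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": expected feature column + samples",
         call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = c("character", rep("numeric",
                                                           length(header) - 1L)),
                           row.names = NULL)
  feats <- tab[[1]]
  dup <- duplicated(feats)
  if (any(dup))
    stop("duplicated feature row name(s) in ", path, ": ",
         paste(unique(feats[dup]), collapse = ", "),
         " (resolve via map_feature_ids(), not on read)", call. = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- feats
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at feature '", feats[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'", call. = FALSE)
  }
  grp <- utils::read.table(groups_path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "",
                           colClasses = "character")
  if (ncol(grp) < 2L)
    stop("malformed group file ", groups_path, call. = FALSE)
  groups <- stats::setNames(grp[[2]], grp[[1]])
  if (!is.null(include_samples)) {
    keep <- intersect(colnames(values), include_samples)
    values <- values[, keep, drop = FALSE]
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) in matrix absent from group file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (log2_input) values <- 2^values
  expression_dataset(values, groups, dataset_id = dataset_id)
}

#' Write an ExpressionDataset to a matrix + group file pair
#'
#' Inverse of [read_expression_matrix()]; used by the synthetic-data
#' generator to emit study fixtures.
#'
#' @param ds an `ExpressionDataset`.
#' @param path,groups_path output paths (tab-separated).
#' @return `ds`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, groups_path) {
  tab <- data.frame(feature = rownames(ds$values), ds$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(names(ds$groups), unname(ds$groups)),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ds)
}

#' Average technical replicate arrays
#'
#' Collapses columns belonging to the same replicate group to their
#' arithmetic mean, one output column per replicate group. All members of a
#' replicate group must carry the same case/control label.
#'
#' @param ds an `ExpressionDataset`.
#' @param replicate_groups named character vector mapping each sample to a
#'   replicate-group id. Samples not listed form singleton groups.
#' @return An `ExpressionDataset` with one column per replicate group (named
#'   by the group id, or the sample name for singletons).
#' @export
collapse_replicates <- function(ds, replicate_groups) {
  samples <- colnames(ds$values)
  rg <- replicate_groups[samples]
  rg[is.na(rg)] <- samples[is.na(rg)]
  out_ids <- unique(rg)
  values <- vapply(out_ids, function(g) {
    rowMeans(ds$values[, rg == g, drop = FALSE])
  }, numeric(nrow(ds$values)))
  dim(values) <- c(nrow(ds$values), length(out_ids))
  dimnames(values) <- list(rownames(ds$values), out_ids)
  groups <- vapply(out_ids, function(g) {
    lab <- unique(ds$groups[samples[rg == g]])
    if (length(lab) != 1L)
      stop("replicate group '", g, "' spans case and control", call. = FALSE)
    lab
  }, character(1))
  expression_dataset(values, groups, dataset_id = ds$dataset_id)
}

#' A feature identifier map
#'
#' Maps platform assay identifiers to canonical names: current miRBase miRNA
#' names (case-sensitive) or official gene symbols (uppercased).
#'
#' @param entries named character vector: names are assay ids, values
#'   canonical names.
#' @param namespace `"mirna"` or `"gene"`.
#' @return A `FeatureIdMap` object.
#' @export
feature_id_map <- function(entries, namespace = c("mirna", "gene")) {
  namespace <- match.arg(namespace)
  if (anyDuplicated(names(entries)))
    stop("duplicate assay identifiers in id map", call. = FALSE)
  if (namespace == "gene") entries <- toupper(entries)
  structure(list(entries = entries, namespace = namespace),
            class = "FeatureIdMap")
}

#' Map assay identifiers to canonical feature names
#'
#' Applies the identifier-mapping policy appropriate to the molecule type.
#' For miRNA datasets only assay identifiers with a one-to-one relationship
#' to miRNA names (unique in both directions within the map) are retained
#' and renamed; everything else is dropped. For gene datasets, unmapped
#' identifiers are dropped, identifiers are renamed to gene symbols, and
#' rows assigned to the same symbol are averaged per sample.
#'
#' @param ds an `ExpressionDataset`.
#' @param idmap a [feature_id_map()] whose namespace matches the dataset.
#' @return An `ExpressionDataset` on canonical names.
#' @export
map_feature_ids <- function(ds, idmap) {
  stopifnot(inherits(idmap, "FeatureIdMap"))
  entries <- idmap$entries
  feats <- rownames(ds$values)
  if (idmap$namespace == "mirna") {
    # one-to-one in both directions: assay ids unique by construction;
    # drop any id whose target name is shared with another id
    multi <- names(entries)[entries %in% entries[duplicated(entries)]]
    ok <- feats[feats %in% setdiff(names(entries), multi)]
    if (!length(ok)) stop("no mappable features", call. = FALSE)
    values <- ds$values[ok, , drop = FALSE]
    rownames(values) <- unname(entries[ok])
  } else {
    ok <- feats[feats %in% names(entries)]
    if (!length(ok)) stop("no mappable features", call. = FALSE)
    sym <- unname(entries[ok])
    sub <- ds$values[ok, , drop = FALSE]
    out_sym <- unique(sym)
    values <- t(vapply(out_sym, function(s) {
      colMeans(sub[sym == s, , drop = FALSE])
    }, numeric(ncol(sub))))
    dim(values) <- c(length(out_sym), ncol(sub))
    dimnames(values) <- list(out_sym, colnames(sub))
  }
  expression_dataset(values, ds$groups, dataset_id = ds$dataset_id)
}

#' Read a MEME minimal-format motif file
#'
#' Parses the MEME minimal motif format: a version line, optional ALPHABET
#' and strand lines, optional background letter frequencies, then one or
#' more `MOTIF` blocks each with a `letter-probability matrix:` header and
#' per-position rows of probabilities over A, C, G, T.
#'
#' @param path path to the motif file.
#' @return A `MotifSet`: list with `motifs` (named list of L x 4 probability
#'   matrices, columns A,C,G,T) and `background` (probability vector over
#'   A,C,G,T).
#' @export
read_motifs_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    if (length(toks) < 8L)
      stop("malformed background line at line ", bg_at[1] + 1L, call. = FALSE)
    vals <- as.numeric(toks[seq(2, 8, by = 2)])
    bg <- stats::setNames(vals, toks[seq(1, 7, by = 2)])[c("A", "C", "G", "T")]
    if (abs(sum(bg) - 1) > 1e-6)
      stop("background frequencies do not sum to 1 (line ",
           bg_at[1] + 1L, ")", call. = FALSE)
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path, call. = FALSE)
  motifs <- list()
  for (m in motif_at) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr <- m + which(grepl("^letter-probability matrix",
                           lines[(m + 1):length(lines)]))[1]
    if (is.na(hdr))
      stop("MOTIF '", name, "' lacks a letter-probability matrix header",
           call. = FALSE)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1L)
      stop("cannot parse motif width at line ", hdr, call. = FALSE)
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(seq_along(rows), function(i) {
      v <- as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]])
      if (length(v) != 4L || anyNA(v))
        stop("malformed matrix row at line ", hdr + i, call. = FALSE)
      v
    }, numeric(4)))
    colnames(mat) <- c("A", "C", "G", "T")
    bad <- abs(rowSums(mat) - 1) > 1e-6
    if (any(bad))
      stop("motif '", name, "': position(s) ",
           paste(which(bad), collapse = ", "),
           " do not sum to 1 (line ", hdr + which(bad)[1], ")", call. = FALSE)
    motifs[[name]] <- mat
  }
  structure(list(motifs = motifs, background = bg), class = "MotifSet")
}

#' Write motifs in MEME minimal format
#'
#' @param motifset a `MotifSet` as returned by [read_motifs_meme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs_meme <- function(motifset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies"), con)
  bg <- motifset$background
  writeLines(paste(sprintf("%s %.6f", names(bg), bg), collapse = " "), con)
  for (name in names(motifset$motifs)) {
    mat <- motifset$motifs[[name]]
    writeLines(c("", paste("MOTIF", name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         nrow(mat))), con)
    writeLines(apply(mat, 1, function(r) paste(sprintf("%.6f", r),
                                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each tab-separated line is `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#' Gene symbols are uppercased; empty sets are rejected.
#'
#' @param path path to the GMT file.
#' @return A `GeneSetCollection`: named list of lists with `name` and
#'   `genes` (character vector, unique, uppercase).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(toks) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields (empty gene set?)",
           call. = FALSE)
    genes <- unique(toupper(toks[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT line ", i, ": empty gene set", call. = FALSE)
    sets[[toks[1]]] <- list(name = toks[2], genes = genes)
  }
  structure(sets, class = "GeneSetCollection")
}

#' Read a FASTA file as a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a tab-separated edge/interaction table
#'
#' Generic reader for the normalized interaction tables used throughout the
#' pipeline (validated targets, predicted targets, TF-miRNA regulations,
#' network edge tables). The header row defines the columns.
#'
#' @param path path to a TSV file with a header row.
#' @return A data.frame; character columns are read as-is.
#' @export
read_edge_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a regulatory network to a directory
#'
#' Emits `network.sif` (`src<TAB>sign<TAB>dst`), `edges.tsv`
#' (src, dst, sign, category, evidence) and `nodes.tsv` (id, roles,
#' comma-joined). `edges.tsv` is re-readable by [read_edge_table()] and
#' reassembles to the same network.
#'
#' @param net a `RegNetwork` (see [assemble_network()]).
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- net$edges
  utils::write.table(ed[, c("src", "dst", "sign", "category", "evidence")],
                     file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sif <- data.frame(src = ed$src,
                    sign = ifelse(ed$sign > 0, "activation", "repression"),
                    dst = ed$dst)
  utils::write.table(sif, file.path(dir, "network.sif"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  nodes <- data.frame(
    id = names(net$nodes),
    roles = vapply(net$nodes, paste, character(1), collapse = ","))
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
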