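#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: for sorted p-values p_(1) <=
#' ... <= p_(m), q_(i) = min_{j >= i} min(1, p_(j) * m / j), returned in
#' the input order. Delegates to [stats::p.adjust()] (method "BH"), which
#' implements exactly this definition.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query set against a
#' background: with N background genes, K of them in the term, and a query
#' of n background genes of which k are in the term, the p-value is the
#' upper hypergeometric tail P(X >= k). Query and term sets are first
#' intersected with the background; terms with no overlap with the query
#' (k = 0) are skipped. All tested terms are BH-adjusted together and rows
#' with q <= `fdr` are flagged enriched.
#'
#' Only gene symbols are matched: miRNA nodes of a network should be
#' excluded from the query upstream (annotation databases operate on
#' genes); miRNAs associate with terms via subnetwork adjacency instead
#' (see [extract_subnetwork()]).
#'
#' @param query character vector of gene symbols.
#' @param sets a `GeneSetCollection` (see [read_gene_sets_gmt()]).
#' @param background character vector of gene symbols; defaults to the
#'   union of all genes in `sets`.
#' @param fdr enrichment flag threshold on the BH-adjusted value.
#' @return data.frame: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `enriched`, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, sets, background = NULL,
                                      fdr = 0.05) {
  if (is.null(background))
    background <- unique(unlist(lapply(sets, `[[`, "genes")))
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- intersect(unique(toupper(query)), background)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    genes <- intersect(sets[[id]]$genes, background)
    K <- length(genes)
    k <- length(intersect(genes, query))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = sets[[id]]$name,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), enriched = logical()))
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$enriched <- res$q_value <= fdr
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the subnetwork around a term's genes
#'
#' Given an assembled network and the genes annotated to a term, the seed
#' is the intersection of the term genes with the network's nodes; the
#' subnetwork consists of the seed plus all its in- and out-neighbors, and
#' (by default) only the edges incident to at least one seed node. With
#' `include_neighbor_edges = TRUE`, all network edges among the selected
#' nodes are retained instead (the induced subgraph).
#'
#' @param net a `RegNetwork`.
#' @param term_genes character vector of gene symbols.
#' @param include_neighbor_edges logical; include neighbor-neighbor edges.
#' @return A `Subnetwork` list: `seed_genes`, `nodes`, `edges` (data.frame),
#'   `mirnas_present`.
#' @export
extract_subnetwork <- function(net, term_genes,
                               include_neighbor_edges = FALSE) {
  seed <- intersect(toupper(term_genes), names(net$nodes))
  edges <- net$edges
  if (!length(seed)) {
    warning("no term genes present in the network; empty subnetwork",
            call. = FALSE)
    return(structure(list(seed_genes = character(), nodes = character(),
                          edges = edges[0, , drop = FALSE],
                          mirnas_present = character()),
                     class = "Subnetwork"))
  }
  incident <- edges$src %in% seed | edges$dst %in% seed
  nodes <- sort(unique(c(seed, edges$src[incident], edges$dst[incident])))
  sub_edges <- if (include_neighbor_edges)
    edges[edges$src %in% nodes & edges$dst %in% nodes, , drop = FALSE]
  else edges[incident, , drop = FALSE]
  rownames(sub_edges) <- NULL
  mirnas <- nodes[vapply(nodes, function(id)
    "mirna" %in% net$nodes[[id]], logical(1))]
  structure(list(seed_genes = sort(seed), nodes = nodes, edges = sub_edges,
                 mirnas_present = mirnas),
            class = "Subnetwork")
}

#' miRNA-by-term presence matrix
#'
#' For each term's subnetwork, marks which miRNAs of the full network
#' appear among its nodes, yielding the term x miRNA presence table that
#' associates differentially expressed miRNAs with enriched terms.
#'
#' @param subnetworks named list of `Subnetwork` objects (names = term
#'   ids).
#' @param mirnas optional character vector fixing the column order;
#'   defaults to the union of miRNAs present in any subnetwork.
#' @return logical matrix, terms x miRNAs.
#' @export
mirna_term_matrix <- function(subnetworks, mirnas = NULL) {
  if (is.null(mirnas))
    mirnas <- sort(unique(unlist(lapply(subnetworks,
                                        `[[`, "mirnas_present"))))
  mat <- t(vapply(subnetworks, function(sn) mirnas %in% sn$mirnas_present,
                  logical(length(mirnas))))
  dim(mat) <- c(length(subnetworks), length(mirnas))
  dimnames(mat) <- list(names(subnetworks), mirnas)
  mat
}
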