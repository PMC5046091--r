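#' Assemble the signed directed regulatory network
#'
#' Combines edge lists (miRNA-target, TF-miRNA, TF-gene) into a single
#' network under the standard sign conventions: miRNAs repress their
#' targets (sign -1) and TFs activate theirs (sign +1), unless a curated
#' override record states otherwise. Duplicate (src, dst) pairs from the
#' same category merge, keeping the strongest evidence
#' (validated + predicted -> "both"); the same ordered pair arriving under
#' two different categories is an error, as are contradictory explicit
#' signs. Node roles (mirna / tf / target) are derived from the categories
#' of incident edges.
#'
#' @param edge_sets list of edge data.frames, each with columns `src`,
#'   `dst`, `category` (mirna_target / tf_mirna / tf_gene), optional `sign`
#'   and `evidence`.
#' @param overrides optional data.frame of curated signs: columns `src`,
#'   `dst`, `sign` (+1/-1 or "activation"/"repression").
#' @return A `RegNetwork`: list with `nodes` (named list id -> role
#'   character vector) and `edges` (data.frame src, dst, sign, category,
#'   evidence).
#' @export
assemble_network <- function(edge_sets, overrides = NULL) {
  default_sign <- c(mirna_target = -1L, tf_mirna = 1L, tf_gene = 1L)
  edges <- do.call(rbind, lapply(edge_sets, function(ed) {
    if (!nrow(ed)) return(NULL)
    stopifnot(all(c("src", "dst", "category") %in% names(ed)))
    bad <- !ed$category %in% names(default_sign)
    if (any(bad))
      stop("unknown edge category: ",
           paste(unique(ed$category[bad]), collapse = ", "), call. = FALSE)
    data.frame(src = ed$src, dst = ed$dst,
               sign = if ("sign" %in% names(ed)) as.integer(ed$sign)
                      else unname(default_sign[ed$category]),
               category = ed$category,
               evidence = if ("evidence" %in% names(ed)) ed$evidence
                          else "validated",
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(src = character(), dst = character(),
                        sign = integer(), category = character(),
                        evidence = character())
  if (any(edges$src == edges$dst))
    stop("self-loop edge(s): ",
         paste(unique(edges$src[edges$src == edges$dst]), collapse = ", "),
         call. = FALSE)
  # merge duplicates per ordered pair
  if (nrow(edges)) {
    key <- paste(edges$src, edges$dst, sep = "\r")
    merged <- lapply(split(seq_len(nrow(edges)), key), function(i) {
      e <- edges[i, , drop = FALSE]
      if (length(unique(e$category)) > 1L)
        stop("pair (", e$src[1], ", ", e$dst[1],
             ") arrives under multiple categories", call. = FALSE)
      ev <- unique(e$evidence)
      evidence <- if ("both" %in% ev ||
                      all(c("validated", "predicted") %in% ev)) "both"
                  else ev[1]
      data.frame(src = e$src[1], dst = e$dst[1], sign = e$sign[1],
                 category = e$category[1], evidence = evidence,
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, merged)
  }
  if (!is.null(overrides) && nrow(overrides)) {
    sgn <- normalize_sign(overrides$sign)
    okey <- paste(overrides$src, overrides$dst, sep = "\r")
    contradictory <- tapply(sgn, okey, function(s) length(unique(s)) > 1L)
    if (any(contradictory))
      stop("contradictory explicit signs for pair(s): ",
           paste(gsub("\r", " -> ", names(contradictory)[contradictory]),
                 collapse = ", "), call. = FALSE)
    m <- match(paste(edges$src, edges$dst, sep = "\r"), okey)
    edges$sign[!is.na(m)] <- sgn[m[!is.na(m)]]
  }
  rownames(edges) <- NULL
  structure(list(nodes = derive_roles(edges), edges = edges),
            class = "RegNetwork")
}

normalize_sign <- function(x) {
  if (is.numeric(x)) return(as.integer(sign(x)))
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("activation", "+1", "+", "1"), 1L,
                ifelse(v %in% c("repression", "-1", "-"), -1L, NA_integer_))
  if (anyNA(out)) stop("unparseable sign value(s)", call. = FALSE)
  out
}

derive_roles <- function(edges) {
  roles <- list()
  add <- function(roles, ids, role) {
    for (id in unique(ids)) roles[[id]] <- union(roles[[id]], role)
    roles
  }
  mt <- edges$category == "mirna_target"
  tm <- edges$category == "tf_mirna"
  tg <- edges$category == "tf_gene"
  roles <- add(roles, edges$src[mt], "mirna")
  roles <- add(roles, edges$dst[mt], "target")
  roles <- add(roles, edges$src[tm | tg], "tf")
  roles <- add(roles, edges$dst[tm], "mirna")
  roles <- add(roles, edges$dst[tg], "target")
  if (length(roles)) roles[order(names(roles))] else roles
}

#' @export
print.RegNetwork <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("RegNetwork: %d nodes, %d edges (%s)\n", s$n_nodes, s$n_edges,
              paste(names(s$edges_by_category), s$edges_by_category,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Summarize a regulatory network
#'
#' Node and edge tallies: total nodes, nodes per role (a dual-role node is
#' counted under each of its roles but once in the total), dual-role node
#' count, total edges and edges per category.
#'
#' @param net a `RegNetwork`.
#' @return A list: `n_nodes`, `nodes_by_role`, `n_dual_role`, `n_edges`,
#'   `edges_by_category`.
#' @export
network_summary <- function(net) {
  role_tab <- table(unlist(net$nodes))
  list(n_nodes = length(net$nodes),
       nodes_by_role = as.list(role_tab),
       n_dual_role = sum(lengths(net$nodes) > 1L),
       n_edges = nrow(net$edges),
       edges_by_category = as.list(table(net$edges$category)))
}

#' Enumerate feedback loops (simple directed cycles)
#'
#' Finds all simple directed cycles of length at most `max_len` and
#' classifies each by sign parity: a loop is positive iff it contains an
#' even number of repression edges, negative otherwise. The default
#' `max_len = 2` captures mutual-regulation loops (TF activates/represses a
#' miRNA which represses the TF back); longer cycles are found by a bounded
#' depth-first enumeration that only starts cycles at their smallest node,
#' so each cycle is reported once (rotation-free).
#'
#' @param net a `RegNetwork`.
#' @param max_len maximum cycle length.
#' @return data.frame with columns `cycle` (node ids joined by "->"),
#'   `length`, `n_repression`, `sign` ("positive"/"negative").
#' @export
find_feedback_loops <- function(net, max_len = 2L) {
  edges <- net$edges
  empty <- data.frame(cycle = character(), length = integer(),
                      n_repression = integer(), sign = character())
  if (!nrow(edges)) return(empty)
  ids <- sort(names(net$nodes))
  idx <- stats::setNames(seq_along(ids), ids)
  esrc <- idx[edges$src]; edst <- idx[edges$dst]
  adj <- split(data.frame(to = edst, sign = edges$sign), esrc)
  out <- list()
  emit <- function(path, signs) {
    nrep <- sum(signs < 0)
    out[[length(out) + 1L]] <<- data.frame(
      cycle = paste(ids[path], collapse = "->"),
      length = length(path), n_repression = nrep,
      sign = if (nrep %% 2L == 0L) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  dfs <- function(start, v, path, signs) {
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      w <- nb$to[k]
      if (w == start) {
        emit(path, c(signs, nb$sign[k]))
      } else if (w > start && !(w %in% path) &&
                 length(path) < max_len) {
        dfs(start, w, c(path, w), c(signs, nb$sign[k]))
      }
    }
  }
  for (s in seq_along(ids)) dfs(s, s, s, integer(0))
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate feed-forward loops
#'
#' Finds every ordered triple (X, Y, Z) of distinct nodes with edges
#' X -> Y, Y -> Z and X -> Z, classifies coherence (coherent iff the sign
#' of the direct edge X -> Z equals the product of the signs along the
#' indirect path X -> Y -> Z), and flags triples containing a miRNA node.
#'
#' @param net a `RegNetwork`.
#' @return data.frame with columns `x`, `y`, `z`, `coherent` (logical),
#'   `contains_mirna` (logical).
#' @export
find_feedforward_loops <- function(net) {
  edges <- net$edges
  empty <- data.frame(x = character(), y = character(), z = character(),
                      coherent = logical(), contains_mirna = logical())
  if (!nrow(edges)) return(empty)
  key <- paste(edges$src, edges$dst, sep = "\r")
  sign_of <- stats::setNames(edges$sign, key)
  succ <- split(edges$dst, edges$src)
  ssign <- split(edges$sign, edges$src)
  is_mirna <- vapply(net$nodes, function(r) "mirna" %in% r, logical(1))
  out <- list()
  for (x in names(succ)) {
    ys <- succ[[x]]
    xs <- ssign[[x]]
    for (i in seq_along(ys)) {
      y <- ys[i]
      zs <- succ[[y]]
      if (is.null(zs)) next
      zsg <- ssign[[y]]
      for (j in seq_along(zs)) {
        z <- zs[j]
        if (z == x || z == y) next
        direct <- sign_of[paste(x, z, sep = "\r")]
        if (is.na(direct)) next
        out[[length(out) + 1L]] <- data.frame(
          x = x, y = y, z = z,
          coherent = unname(direct) == xs[i] * zsg[j],
          contains_mirna = any(is_mirna[c(x, y, z)], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
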