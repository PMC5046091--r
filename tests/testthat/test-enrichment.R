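test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)                      # m = 1: q = p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # monotone along the sorted p-values, never above 1
  set.seed(4)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("hypergeometric tail matches the closed form and PMF summation", {
  sets <- structure(list(T1 = list(name = "term one",
                                   genes = paste0("G", 1:5))),
                    class = "GeneSetCollection")
  background <- paste0("G", 1:10)
  res <- hypergeometric_enrichment(paste0("G", 1:4), sets, background)
  # N=10, K=5, n=4, k=4: C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(res$p_value, 5 / 210)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 4L, K = 5L, n = 4L, N = 10L),
               ignore_attr = TRUE)
  # tail equals explicit PMF summation
  pmf_sum <- sum(vapply(4:4, function(i)
    choose(5, i) * choose(5, 4 - i) / choose(10, 4), numeric(1)))
  expect_equal(res$p_value, pmf_sum, tolerance = 1e-12)
  # disjoint term (k = 0) is skipped
  sets2 <- structure(list(T1 = list(name = "t", genes = paste0("G", 6:9))),
                     class = "GeneSetCollection")
  expect_equal(nrow(hypergeometric_enrichment(paste0("G", 1:3), sets2,
                                              background)), 0L)
  expect_error(hypergeometric_enrichment("G1", sets, character(0)),
               "background")
})

test_that("random enrichment fixtures match manual phyper computation", {
  set.seed(19)
  background <- paste0("G", 1:200)
  sets <- simulate_gene_sets(background, n_sets = 12, seed = 5)
  query <- sample(background, 30)
  res <- hypergeometric_enrichment(query, sets, background)
  for (i in seq_len(nrow(res))) {
    genes <- sets[[res$term_id[i]]]$genes
    k <- length(intersect(intersect(genes, background), query))
    expect_equal(res$k[i], k)
    expect_equal(res$p_value[i],
                 phyper(k - 1, length(intersect(genes, background)),
                        200 - length(intersect(genes, background)), 30,
                        lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_equal(res$q_value, bh_adjust(res$p_value), tolerance = 1e-12)
  # rows with q <= 0.05 and only those carry the enriched flag
  expect_equal(res$enriched, res$q_value <= 0.05)
})

test_that("subnetworks take seed, neighbors, and seed-incident edges", {
  ed <- data.frame(src = c("A", "B"), dst = c("B", "C"),
                   category = "tf_gene", sign = 1L)
  net <- assemble_network(list(ed))
  sn <- extract_subnetwork(net, "B")
  expect_setequal(sn$nodes, c("A", "B", "C"))
  expect_equal(nrow(sn$edges), 2L)
  # isolated seed: just the node (B only connected to A, C)
  sn2 <- extract_subnetwork(net, "A")
  expect_setequal(sn2$nodes, c("A", "B"))
  expect_equal(nrow(sn2$edges), 1L)
  # empty seed warns and returns an empty subnetwork
  expect_warning(sn3 <- extract_subnetwork(net, "ZZZ"), "empty")
  expect_equal(length(sn3$nodes), 0L)
  # seeding with every node returns the full node set
  sn4 <- extract_subnetwork(net, names(net$nodes))
  expect_setequal(sn4$nodes, names(net$nodes))
  expect_equal(nrow(sn4$edges), nrow(net$edges))
})

test_that("subnetwork extraction equals a naive edge-filter oracle", {
  set.seed(6)
  for (rep in 1:5) {
    ed <- random_signed_digraph(n = 15, p = 0.15, seed = rep + 50)
    ed$src <- toupper(ed$src); ed$dst <- toupper(ed$dst)
    net <- assemble_network(list(ed))
    seed_genes <- sample(names(net$nodes), 4)
    sn <- extract_subnetwork(net, seed_genes)
    seed_in <- intersect(toupper(seed_genes), names(net$nodes))
    incident <- ed$src %in% seed_in | ed$dst %in% seed_in
    expect_equal(nrow(sn$edges), sum(incident))
    expect_setequal(sn$nodes, unique(c(seed_in, ed$src[incident],
                                       ed$dst[incident])))
    # subnetwork edges are always a subset of network edges
    expect_true(all(paste(sn$edges$src, sn$edges$dst) %in%
                      paste(net$edges$src, net$edges$dst)))
  }
})

test_that("neighbor-neighbor edges appear only with the induced-flag", {
  ed <- data.frame(src = c("S", "A"), dst = c("A", "B"),
                   category = "tf_gene", sign = 1L)
  net <- assemble_network(list(ed))
  sn <- extract_subnetwork(net, "S")
  expect_equal(nrow(sn$edges), 1L)          # only the seed-incident edge
  expect_setequal(sn$nodes, c("S", "A"))
  sn_ind <- extract_subnetwork(net, "S", include_neighbor_edges = TRUE)
  expect_equal(nrow(sn_ind$edges), 1L)      # A->B leaves the node set
})

test_that("miRNA-term matrix equals direct membership rechecks", {
  ed <- list(
    data.frame(src = "miR-1", dst = "G1", category = "mirna_target"),
    data.frame(src = "miR-2", dst = "G2", category = "mirna_target"),
    data.frame(src = "TF1", dst = "G1", category = "tf_gene"))
  net <- assemble_network(ed)
  subs <- list(termA = extract_subnetwork(net, "G1"),
               termB = extract_subnetwork(net, "G2"),
               termC = extract_subnetwork(net, c("G1", "G2")))
  mat <- mirna_term_matrix(subs)
  for (term in rownames(mat)) for (m in colnames(mat))
    expect_equal(unname(mat[term, m]), m %in% subs[[term]]$nodes)
  expect_true(mat["termA", "miR-1"])
  expect_false(mat["termA", "miR-2"])
  # a miRNA absent from every subnetwork yields a blank column
  mat2 <- mirna_term_matrix(subs, mirnas = c("miR-1", "miR-2", "miR-99"))
  expect_true(all(!mat2[, "miR-99"]))
})
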