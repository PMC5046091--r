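test_that("assembly applies default signs and curated overrides", {
  targets <- data.frame(src = c("miR-221-3p", "let-7b-5p"),
                        dst = c("SRSF1", "LIN28A"),
                        category = "mirna_target", evidence = "validated",
                        sign = -1L, stringsAsFactors = FALSE)
  tf <- data.frame(src = c("ESR1", "E2F1"), dst = c("miR-221-3p",
                                                    "miR-19b-3p"),
                   category = "tf_mirna", stringsAsFactors = FALSE)
  net <- assemble_network(list(targets, tf))
  e <- net$edges
  expect_equal(e$sign[e$src == "ESR1"], 1L)   # TF default: activation
  expect_equal(e$sign[e$src == "miR-221-3p"], -1L)  # miRNA default
  # curated repression record overrides the TF default
  net2 <- assemble_network(
    list(targets, tf),
    overrides = data.frame(src = "ESR1", dst = "miR-221-3p",
                           sign = "repression"))
  expect_equal(net2$edges$sign[net2$edges$src == "ESR1"], -1L)
  # roles derive from incident edge categories
  expect_true("mirna" %in% net$nodes[["miR-221-3p"]])
  expect_true("tf" %in% net$nodes[["ESR1"]])
  expect_true("target" %in% net$nodes[["LIN28A"]])
  # empty input: empty network
  empty <- assemble_network(list())
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("assembly rejects malformed edge combinations", {
  expect_error(assemble_network(list(data.frame(
    src = "A", dst = "A", category = "tf_gene"))), "self-loop")
  expect_error(assemble_network(list(
    data.frame(src = "A", dst = "B", category = "tf_gene"),
    data.frame(src = "A", dst = "B", category = "mirna_target"))),
    "multiple categories")
  expect_error(assemble_network(
    list(data.frame(src = "A", dst = "B", category = "tf_gene")),
    overrides = data.frame(src = c("A", "A"), dst = c("B", "B"),
                           sign = c("activation", "repression"))),
    "contradictory")
})

test_that("validated+predicted duplicates merge to evidence 'both'", {
  ed <- rbind(
    data.frame(src = "miR-1", dst = "G1", category = "mirna_target",
               evidence = "validated", sign = -1L),
    data.frame(src = "miR-1", dst = "G1", category = "mirna_target",
               evidence = "predicted", sign = -1L))
  net <- assemble_network(list(ed))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$evidence, "both")
})

test_that("network summary equals a naive recount", {
  for (seed in 1:5) {
    ed <- random_signed_digraph(n = 10, p = 0.25, seed = seed)
    net <- assemble_network(list(ed))
    s <- network_summary(net)
    expect_equal(s$n_edges, nrow(ed))
    expect_equal(s$n_nodes, length(unique(c(ed$src, ed$dst))))
    expect_equal(s$edges_by_category$tf_gene, nrow(ed))
  }
  # single edge: 2 nodes
  one <- assemble_network(list(data.frame(src = "A", dst = "B",
                                          category = "tf_gene")))
  expect_equal(network_summary(one)$n_nodes, 2L)
})

test_that("mutual-regulation loops classify by repression parity", {
  # TF activates the miRNA, the miRNA represses the TF back: negative
  ed <- list(
    data.frame(src = "SRSF1", dst = "miR-221-3p", category = "tf_mirna",
               sign = 1L),
    data.frame(src = "miR-221-3p", dst = "SRSF1",
               category = "mirna_target", sign = -1L))
  fbl <- find_feedback_loops(assemble_network(ed))
  expect_equal(nrow(fbl), 1L)
  expect_equal(fbl$sign, "negative")
  # mutual repression: two repressions, even parity, positive
  ed2 <- list(
    data.frame(src = "LIN28A", dst = "let-7b-5p", category = "tf_mirna",
               sign = -1L),
    data.frame(src = "let-7b-5p", dst = "LIN28A",
               category = "mirna_target", sign = -1L))
  fbl2 <- find_feedback_loops(assemble_network(ed2))
  expect_equal(fbl2$sign, "positive")
  # flipping exactly one edge sign flips the classification
  ed3 <- ed2
  ed3[[1]]$sign <- 1L
  expect_equal(find_feedback_loops(assemble_network(ed3))$sign, "negative")
  # acyclic network: no loops
  chain <- data.frame(src = c("A", "B"), dst = c("B", "C"),
                      category = "tf_gene")
  expect_equal(nrow(find_feedback_loops(assemble_network(list(chain)))), 0L)
})

test_that("feed-forward loops classify coherence by sign product", {
  ffl_of <- function(s_xy, s_yz, s_xz) {
    ed <- data.frame(src = c("X", "Y", "X"), dst = c("Y", "Z", "Z"),
                     category = "tf_gene", sign = c(s_xy, s_yz, s_xz))
    find_feedforward_loops(assemble_network(list(ed)))
  }
  expect_true(ffl_of(1, 1, 1)$coherent)       # all activation
  expect_false(ffl_of(1, -1, 1)$coherent)     # +1 != +1 * -1
  expect_true(ffl_of(-1, -1, 1)$coherent)     # two repressions cancel
  expect_false(ffl_of(-1, 1, 1)$coherent)
})

test_that("loop enumeration matches brute-force oracles on random graphs", {
  for (seed in 1:100) {
    ed <- random_signed_digraph(n = 12, p = 0.3, seed = seed)
    net <- assemble_network(list(ed))
    ffl <- find_feedforward_loops(net)
    oracle <- oracle_ffl(ed)
    expect_equal(nrow(ffl), nrow(oracle))
    if (nrow(ffl)) {
      got <- ffl[order(ffl$x, ffl$y, ffl$z), ]
      expect_equal(paste(got$x, got$y, got$z),
                   paste(oracle$x, oracle$y, oracle$z))
      expect_equal(got$coherent, oracle$coherent, ignore_attr = TRUE)
      expect_equal(sum(got$coherent) + sum(!got$coherent), nrow(got))
    }
    fbl <- find_feedback_loops(net, max_len = 2)
    expect_equal(sort(fbl$cycle),
                 sort(gsub("\\|", "->", oracle_cycles(ed, 2)$cycle)))
  }
  # longer cycles against the exhaustive triple enumeration
  for (seed in 1:10) {
    ed <- random_signed_digraph(n = 8, p = 0.3, seed = seed)
    net <- assemble_network(list(ed))
    fbl3 <- find_feedback_loops(net, max_len = 3)
    oracle3 <- oracle_cycles(ed, 3)
    expect_equal(sort(fbl3$cycle), sort(gsub("\\|", "->", oracle3$cycle)))
    m1 <- setNames(fbl3$sign, fbl3$cycle)
    m2 <- setNames(oracle3$sign, gsub("\\|", "->", oracle3$cycle))
    expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  }
})

test_that("feed-forward loops flag miRNA participation", {
  ed <- list(
    data.frame(src = "TF1", dst = "miR-9", category = "tf_mirna", sign = 1L),
    data.frame(src = "miR-9", dst = "G1", category = "mirna_target",
               sign = -1L),
    data.frame(src = "TF1", dst = "G1", category = "tf_gene", sign = 1L))
  ffl <- find_feedforward_loops(assemble_network(ed))
  expect_equal(nrow(ffl), 1L)
  expect_true(ffl$contains_mirna)
  expect_false(ffl$coherent)  # +1 != (+1)(-1)
})
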