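test_that("canonical labels are isomorphism-invariant and separate motif classes", {
  ffl_a <- canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("x", "x", "y"), target = c("y", "g", "g"), sign = 1))
  ffl_b <- canonical_label(
    data.frame(id = c("p", "q", "r"), type = c("TF", "gene", "TF")),
    data.frame(source = c("r", "r", "p"), target = c("p", "q", "q"), sign = 1))
  expect_equal(ffl_a, ffl_b)
  cascade <- canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("x", "y"), target = c("y", "g"), sign = 1))
  expect_false(ffl_a == cascade)
  # signed mode distinguishes coherent type-1 FFL from a mixed-sign variant
  coh <- canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("x", "x", "y"), target = c("y", "g", "g"),
               sign = c(1, 1, 1)), signed = TRUE)
  mix <- canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("x", "x", "y"), target = c("y", "g", "g"),
               sign = c(1, 1, -1)), signed = TRUE)
  expect_false(coh == mix)
  # unsigned mode collapses them
  expect_equal(canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("x", "x", "y"), target = c("y", "g", "g"),
               sign = c(1, 1, -1)), signed = FALSE), ffl_a)
  expect_error(canonical_label(
    data.frame(id = c("x", "y", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = "x", target = "y", sign = 1)), "not connected")
})

test_that("a minimal network censuses to exactly its planted instances", {
  ffl <- make_net(
    list(list("t1", "t2", "TF->TF", 1L), list("t1", "g1", "TF->gene", 1L),
         list("t2", "g1", "TF->gene", 1L)),
    c(t1 = "TF", t2 = "TF", g1 = "gene"))
  cs <- census(ffl, 3)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$count, 1L)
  expect_equal(cs$label, canonical_label(
    data.frame(id = c("a", "b", "c"), type = c("TF", "TF", "gene")),
    data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"), sign = 1)))
  # 2-node census of the same network: the two connected pairs
  cs2 <- census(ffl, 2)
  expect_equal(sum(cs2$count), 3)
  expect_error(census(ffl, 4), "size")
})

test_that("node-disjoint planted FFLs and cascades are all found", {
  k <- 4
  edges <- list(); types <- c()
  for (i in 1:k) {
    a <- sprintf("fa%d", i); b <- sprintf("fb%d", i); g <- sprintf("fg%d", i)
    edges <- c(edges, list(list(a, b, "TF->TF", 1L), list(a, g, "TF->gene", 1L),
                           list(b, g, "TF->gene", 1L)))
    types[c(a, b)] <- "TF"; types[g] <- "gene"
    a2 <- sprintf("ca%d", i); b2 <- sprintf("cb%d", i); g2 <- sprintf("cg%d", i)
    edges <- c(edges, list(list(a2, b2, "TF->TF", 1L), list(b2, g2, "TF->gene", 1L)))
    types[c(a2, b2)] <- "TF"; types[g2] <- "gene"
  }
  net <- make_net(edges, types)
  cs <- census(net, 3)
  ffl_label <- canonical_label(
    data.frame(id = c("a", "b", "c"), type = c("TF", "TF", "gene")),
    data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"), sign = 1))
  casc_label <- canonical_label(
    data.frame(id = c("a", "b", "c"), type = c("TF", "TF", "gene")),
    data.frame(source = c("a", "b"), target = c("b", "c"), sign = 1))
  expect_gte(cs$count[cs$label == ffl_label], k)
  expect_gte(cs$count[cs$label == casc_label], k)
})

test_that("the exact census matches the brute-force all-triples oracle", {
  set.seed(2024)
  for (i in 1:12) {
    net <- random_typed_network(sample(10:40, 1), sample(20:80, 1),
                                signed = i %% 2 == 0)
    if (is.null(net)) next
    signed <- i %% 2 == 0
    cs <- census(net, 3, signed = signed)
    oc <- oracle_census3(net, signed = signed)
    expect_equal(sum(cs$count), sum(oc), label = sprintf("total, graph %d", i))
    expect_equal(nrow(cs), length(oc), label = sprintf("classes, graph %d", i))
    expect_equal(sort(as.integer(cs$count)), sort(as.integer(oc)),
                 label = sprintf("count multiset, graph %d", i))
  }
})

test_that("specific motif classes agree between census and oracle via representatives", {
  set.seed(77)
  net <- random_typed_network(25, 60)
  cs <- census(net, 3)
  reps <- list(
    ffl = list(nodes = data.frame(id = c("a", "b", "c"),
                                  type = c("TF", "TF", "gene")),
               edges = data.frame(source = c("a", "a", "b"),
                                  target = c("b", "c", "c"), sign = c(1, 1, 1))),
    fanout = list(nodes = data.frame(id = c("a", "b", "c"),
                                     type = c("TF", "gene", "gene")),
                  edges = data.frame(source = c("a", "a"),
                                     target = c("b", "c"), sign = c(1, 1))),
    mirna_pair = list(nodes = data.frame(id = c("a", "b", "c"),
                                         type = c("miRNA", "TF", "gene")),
                      edges = data.frame(source = c("a", "a", "b"),
                                         target = c("b", "c", "c"),
                                         sign = c(-1, -1, 1))))
  for (nm in names(reps)) {
    r <- reps[[nm]]
    impl_label <- canonical_label(r$nodes, r$edges)
    mini <- integrated_network(
      r$nodes,
      data.frame(source = r$edges$source, target = r$edges$target,
                 type = ifelse(r$nodes$type[match(r$edges$source, r$nodes$id)] == "miRNA",
                               ifelse(r$nodes$type[match(r$edges$target, r$nodes$id)] == "TF",
                                      "miRNA->TF", "miRNA->gene"),
                               ifelse(r$nodes$type[match(r$edges$target, r$nodes$id)] == "TF",
                                      "TF->TF",
                                      ifelse(r$nodes$type[match(r$edges$target, r$nodes$id)] == "miRNA",
                                             "TF->miRNA", "TF->gene"))),
                 sign = r$edges$sign, stringsAsFactors = FALSE))
    oracle_label <- names(oracle_census3(mini))
    oc <- oracle_census3(net)
    n_impl <- if (impl_label %in% cs$label) cs$count[cs$label == impl_label] else 0L
    n_orac <- if (oracle_label %in% names(oc)) as.integer(oc[[oracle_label]]) else 0L
    expect_equal(n_impl, n_orac, label = nm)
  }
})

test_that("stratified rewiring preserves per-stratum degrees exactly and is seeded", {
  sim <- small_sim(seed = 51)
  suppressMessages(net <- assemble_network(
    call_tf_targets(sim$peaksets, sim$annotation),
    filter_conserved_sites(sim$sites, sim$annotation),
    sim$ppi, sim$annotation))
  net <- assign_edge_signs(
    net, data.frame(tf_id = sim$tf_ids,
                    class = ifelse(sim$tf_signs > 0, "positive", "negative")))
  degs <- function(n, signed) {
    e <- n$edges
    strat <- if (signed) paste(e$type, e$sign) else e$type
    list(out = table(paste(strat, e$source)), inn = table(paste(strat, e$target)))
  }
  for (signed in c(FALSE, TRUE)) {
    before <- degs(net, signed)
    set.seed(42)
    rn <- rewire_null(net, q = 20, signed = signed)
    after <- degs(rn, signed)
    expect_equal(after$out, before$out)
    expect_equal(after$inn, before$inn)
    # no duplicates within a type, no new self-loops
    expect_false(any(duplicated(paste(rn$edges$type, rn$edges$source,
                                      rn$edges$target))))
    new_self <- rn$edges$source == rn$edges$target & rn$edges$type != "TF->TF"
    expect_false(any(new_self))
    # determinism under the same seed
    set.seed(42)
    rn2 <- rewire_null(net, q = 20, signed = signed)
    expect_identical(rn$edges, rn2$edges)
  }
})

test_that("edge overlap with the original decays with rewiring intensity", {
  sim <- small_sim(seed = 52)
  suppressMessages(net <- assemble_network(
    call_tf_targets(sim$peaksets, sim$annotation),
    filter_conserved_sites(sim$sites, sim$annotation),
    NULL, sim$annotation))
  orig <- paste(net$edges$type, net$edges$source, net$edges$target)
  mean_overlap <- function(q, reps = 15) {
    mean(vapply(seq_len(reps), function(i) {
      rn <- rewire_null(net, q = q)
      mean(paste(rn$edges$type, rn$edges$source, rn$edges$target) %in% orig)
    }, numeric(1)))
  }
  set.seed(77)
  o1 <- mean_overlap(1)
  o10 <- mean_overlap(10)
  expect_lt(o10, o1)
  expect_lt(o1, 1)
})

test_that("planted FFL enrichment is detected against a degree-matched null", {
  set.seed(303)
  base <- random_typed_network(40, 90)
  # plant FFLs over the existing node set
  tfs <- base$nodes$id[base$nodes$type == "TF"]
  genes <- base$nodes$id[base$nodes$type == "gene"]
  k <- 12
  add <- list()
  for (i in seq_len(k)) {
    ab <- sample(tfs, 2)
    g <- sample(genes, 1)
    add <- c(add, list(
      data.frame(source = ab[1], target = ab[2], type = "TF->TF", sign = 0L),
      data.frame(source = ab[1], target = g, type = "TF->gene", sign = 0L),
      data.frame(source = ab[2], target = g, type = "TF->gene", sign = 0L)))
  }
  edges <- unique(rbind(base$edges, do.call(rbind, add)))
  net <- integrated_network(base$nodes, edges)
  enr <- motif_enrichment(net, size = 3, signed = FALSE, n_null = 100,
                          q = 30, seed = 5)
  ffl_label <- canonical_label(
    data.frame(id = c("a", "b", "c"), type = c("TF", "TF", "gene")),
    data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"), sign = 1))
  row <- enr[enr$label == ffl_label, ]
  expect_gt(row$z, 2)
  expect_lte(row$p_emp, 0.05)
  # add-one correction: no empirical p is ever 0
  expect_true(all(enr$p_emp > 0))
  expect_true(all(enr$p_emp <= 1))
})

test_that("a degree-determined star network shows no spurious enrichment", {
  hub <- "t1"
  leaves <- sprintf("g%02d", 1:12)
  edges <- lapply(leaves, function(g) list(hub, g, "TF->gene", 1L))
  net <- make_net(edges, c(setNames(rep("gene", 12), leaves), t1 = "TF"))
  enr <- motif_enrichment(net, n_null = 50, q = 10, seed = 3)
  # the star is fully determined by its degrees: null sd is 0, z undefined,
  # and the empirical p is 1
  expect_true(all(is.na(enr$z)))
  expect_true(all(enr$p_emp == 1))
})

test_that("composite motif counts follow their definitions", {
  net <- make_net(
    list(list("t1", "m1", "TF->miRNA", 1L), list("m1", "t1", "miRNA->TF", -1L),
         list("t2", "m2", "TF->miRNA", 1L),        # no reciprocal edge
         list("m1", "g1", "miRNA->gene", -1L), list("m1", "g2", "miRNA->gene", -1L),
         list("m2", "g2", "miRNA->gene", -1L),
         list("t1", "t1", "TF->TF", -1L), list("t2", "t2", "TF->TF", 1L)),
    c(t1 = "TF", t2 = "TF", m1 = "miRNA", m2 = "miRNA",
      g1 = "gene", g2 = "gene"),
    ppi = data.frame(a = "g1", b = "g2", stringsAsFactors = FALSE))
  res <- composite_ppi_motifs(net, n_null = 20, seed = 1)
  expect_equal(res$co_mirna_ppi$count, 1L)       # m1 hits both PPI partners
  expect_equal(res$feedback_loops$count, 1L)     # only t1<->m1
  expect_equal(res$autoregulation$count, 2L)
  expect_equal(res$autoregulation$par, 1L)
  expect_equal(res$autoregulation$nar, 1L)
  expect_true(res$co_mirna_ppi$p_emp > 0 && res$co_mirna_ppi$p_emp <= 1)
  # without PPI edges the composite test is skipped and flagged
  net2 <- make_net(list(list("t1", "m1", "TF->miRNA", 1L)),
                   c(t1 = "TF", m1 = "miRNA"))
  res2 <- composite_ppi_motifs(net2, n_null = 5, seed = 1)
  expect_true(isTRUE(res2$co_mirna_ppi$skipped))
})

test_that("the sampling census is unbiased and degenerates to the exact one", {
  set.seed(888)
  net <- random_typed_network(40, 100)
  exact <- census(net, 3)
  # sampling more triples than exist is the exact census
  all_of_it <- census(net, 3, sample_triples = 1e6)
  expect_equal(all_of_it$count, exact$count)
  expect_equal(all_of_it$label, exact$label)
  # Horvitz-Thompson scale-up conserves the total exactly and approximates
  # individual classes
  set.seed(1)
  half <- census(net, 3, sample_triples = ceiling(attr(exact, "n_subgraphs") / 2))
  expect_equal(sum(half$count), sum(exact$count), tolerance = 1e-9)
  top <- exact$label[1]
  expect_lt(abs(half$count[half$label == top] - exact$count[exact$label == top]),
            0.5 * exact$count[exact$label == top])
})
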