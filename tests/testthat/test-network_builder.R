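test_that("conservation filtering applies the species-set rules at gene level", {
  ann <- tiny_annotation()
  site <- function(mirna, tx, e, b, r, br = FALSE, j = FALSE) {
    data.frame(mirna_id = mirna, transcript_id = tx, chrom = "chrI",
               start = 15850L, end = 15857L,
               `C.elegans` = e, `C.briggsae` = b, `C.remanei` = r,
               `C.brenneri` = br, `C.japonica` = j,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  sites <- rbind(
    site("mir-i", "gA.t1", TRUE, TRUE, TRUE, TRUE, TRUE),   # all 5
    site("mir-x", "gA.t1", TRUE, TRUE, FALSE),              # 2 species only
    site("mir-x", "gB.t1", TRUE, TRUE, TRUE))               # 3-way only
  e3 <- filter_conserved_sites(sites, ann, 3)
  expect_setequal(paste(e3$mirna_id, e3$gene_id),
                  c("mir-i gA", "mir-x gB"))
  e5 <- filter_conserved_sites(sites, ann, 5)
  expect_equal(paste(e5$mirna_id, e5$gene_id), "mir-i gA")
  expect_error(filter_conserved_sites(sites, ann, 4), "3 or 5")
})

test_that("a site on any transcript of a gene creates the gene-level edge", {
  ann <- tiny_annotation()
  # add a second transcript to gA via a fresh annotation
  genes <- ann$genes
  tr <- rbind(ann$transcripts,
              data.frame(transcript_id = "gA.t2", gene_id = "gA",
                         chrom = "chrI", start = 10200L, end = 16000L,
                         strand = "+", tss = 10200L, stringsAsFactors = FALSE))
  ann2 <- genome_annotation(genes, tr[, setdiff(names(tr), "tss")],
                            ann$exons, ann$utr3, ann$mirnas)
  sites <- data.frame(mirna_id = "mir-x", transcript_id = "gA.t2",
                      chrom = "chrI", start = 15850L, end = 15857L,
                      `C.elegans` = TRUE, `C.briggsae` = TRUE,
                      `C.remanei` = TRUE, `C.brenneri` = FALSE,
                      `C.japonica` = FALSE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  e <- filter_conserved_sites(sites, ann2, 3)
  expect_equal(e$gene_id, "gA")
})

test_that("network assembly enforces the both-inputs gene universe", {
  # gC has a TSS but no 3'UTR: excluded, and its edges dropped
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chrI",
                      start = c(1000L, 20000L, 40000L),
                      end = c(5000L, 25000L, 44000L),
                      strand = "+", is_tf = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  tr <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                   gene_id = genes$gene_id, chrom = "chrI",
                   start = genes$start, end = genes$end, strand = "+",
                   stringsAsFactors = FALSE)
  empty <- data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  utr3 <- data.frame(transcript_id = c("gA.t1", "gB.t1"), chrom = "chrI",
                     start = c(4800L, 24800L), end = c(5000L, 25000L),
                     stringsAsFactors = FALSE)
  mir <- data.frame(mirna_id = "m1", chrom = "chrI", start = 60000L,
                    end = 60100L, strand = "+", stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, tr, empty, utr3, mir)
  tf_edges <- data.frame(tf_id = "gA", target_id = c("gA", "gB", "gC", "m1"),
                         target_type = c("gene", "gene", "gene", "mirna"),
                         stringsAsFactors = FALSE)
  mirna_edges <- data.frame(mirna_id = "m1", gene_id = c("gB", "gC"),
                            stringsAsFactors = FALSE)
  expect_message(
    net <- assemble_network(tf_edges, mirna_edges, NULL, ann),
    "dropped")
  expect_false("gC" %in% net$nodes$id)
  expect_setequal(net$edges$type[net$edges$target == "gB"],
                  c("TF->gene", "miRNA->gene"))
  # the TF self-target survives as a TF->TF self-loop
  self <- net$edges[net$edges$source == "gA" & net$edges$target == "gA", ]
  expect_equal(self$type, "TF->TF")
  expect_equal(attr(net, "dropped")[["tf"]], 1L)
  expect_equal(attr(net, "dropped")[["mirna"]], 1L)
  # empty miRNA edge list still assembles
  net2 <- assemble_network(tf_edges[1:2, ], mirna_edges[0, ], NULL, ann)
  expect_s3_class(net2, "integrated_network")
  expect_equal(sum(net2$edges$type == "miRNA->gene"), 0)
})

test_that("degree statistics fit exact exponential histograms and flag degenerate ones", {
  sim <- small_sim(seed = 41)
  suppressMessages(net <- assemble_network(
    call_tf_targets(sim$peaksets, sim$annotation),
    filter_conserved_sites(sim$sites, sim$annotation),
    sim$ppi, sim$annotation))
  rep <- degree_statistics(net)
  expect_s3_class(rep, "degree_report")
  # histogram mass equals the node count of each class
  n_genes <- sum(net$nodes$type %in% c("gene", "TF"))
  n_mirnas <- sum(net$nodes$type == "miRNA")
  expect_equal(sum(rep$histograms$tfs_per_gene), n_genes)
  expect_equal(sum(rep$histograms$mirnas_per_gene), n_genes)
  expect_equal(sum(rep$histograms$targets_per_mirna), n_mirnas)
  for (f in rep$fits) {
    if (f$ok) expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  }
  expect_true(is.finite(rep$mirna_inout$r))
})

test_that("target overlap uses the hypergeometric tail over the network universe", {
  # universe of 10 genes; A targets 5, B targets 4, overlap 4
  ids <- sprintf("g%02d", 1:10)
  types <- setNames(rep("gene", 10), ids)
  types <- c(types, tA = "TF", tB = "TF")
  edges <- c(lapply(ids[1:5], function(g) list("tA", g, "TF->gene")),
             lapply(ids[2:5], function(g) list("tB", g, "TF->gene")))
  net <- make_net(edges, types)
  net$gene_universe <- ids
  tab <- target_overlap_matrix(net, "TFxTF", "gene")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$overlap, 4)
  expect_equal(tab$p, 5 / 210, tolerance = 1e-10)
  # disjoint targets: p = 1
  edges2 <- c(lapply(ids[1:3], function(g) list("tA", g, "TF->gene")),
              lapply(ids[4:6], function(g) list("tB", g, "TF->gene")))
  net2 <- make_net(edges2, types)
  net2$gene_universe <- ids
  tab2 <- target_overlap_matrix(net2, "TFxTF", "gene")
  expect_equal(tab2$p, 1)
  expect_equal(tab2$overlap, 0)
})

test_that("self pairs are excluded and zero-target regulators flagged with p = 1", {
  ids <- sprintf("g%02d", 1:6)
  types <- c(setNames(rep("gene", 6), ids), tA = "TF", tB = "TF",
             mA = "miRNA")
  edges <- c(lapply(ids[1:3], function(g) list("tA", g, "TF->gene")),
             lapply(ids[1:2], function(g) list("mA", g, "miRNA->gene", -1L)),
             list(list("tB", "mA", "TF->miRNA")))
  net <- make_net(edges, types)
  net$gene_universe <- ids
  tab <- target_overlap_matrix(net, "TFxmiRNA", "gene")
  expect_true(all(tab$regulator_a != tab$regulator_b))
  # tB has no gene targets -> flagged, p = 1
  row <- tab[tab$regulator_a == "tB", ]
  expect_true(row$flagged)
  expect_equal(row$p, 1)
  expect_true(all(tab$q >= tab$p | abs(tab$q - tab$p) < 1e-12))
})

test_that("node and edge counts are conserved through a write/read round trip", {
  sim <- small_sim(seed = 43)
  suppressMessages(net <- assemble_network(
    call_tf_targets(sim$peaksets, sim$annotation),
    filter_conserved_sites(sim$sites, sim$annotation),
    sim$ppi, sim$annotation))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(nrow(net2$edges), nrow(net$edges))
  expect_equal(nrow(net2$ppi), nrow(net$ppi))
  expect_equal(sort(net2$nodes$id), sort(net$nodes$id))
  expect_equal(table(net2$edges$type), table(net$edges$type))
})
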