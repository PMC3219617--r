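test_that("HOT detection finds stacked factors at and below threshold", {
  stack16 <- lapply(sprintf("tf%02d", 1:16), function(tf) {
    peak_set(data.frame(chrom = "chrI", start = 1000L, end = 1400L,
                        center = 1200L, score = 1), tf, "L1")
  })
  hot <- detect_hot_regions(stack16, window_bp = 400, threshold = 15)
  expect_equal(nrow(hot), 1)
  expect_lte(hot$start, 1000)
  expect_gte(hot$end, 1400)
  expect_equal(hot$occupancy, 16L)
  # 14 factors: below threshold
  hot14 <- detect_hot_regions(stack16[1:14], window_bp = 400, threshold = 15)
  expect_equal(nrow(hot14), 0)
  # a factor's multiple conditions count once
  dup <- c(stack16[1:14],
           list(peak_set(data.frame(chrom = "chrI", start = 1000L, end = 1400L,
                                    center = 1200L, score = 1), "tf01", "L2")))
  expect_equal(nrow(detect_hot_regions(dup, 400, 15)), 0)
  expect_error(detect_hot_regions(stack16, 400, 0), "threshold")
})

test_that("two distant stacks give exactly two merged HOT intervals (scan oracle)", {
  mk <- function(tf, centers) peaks_at(centers, tf)
  sets <- lapply(sprintf("tf%02d", 1:16), function(tf) mk(tf, c(5000L, 15000L)))
  hot <- detect_hot_regions(sets, window_bp = 400, threshold = 15)
  expect_equal(nrow(hot), 2)
  # brute-force position-wise occupancy scan over the relevant region
  pos <- 4000:16500
  occ <- vapply(pos, function(p) {
    sum(vapply(sets, function(ps) {
      any(ps$start < p + 200 & ps$end > p - 200)
    }, logical(1)))
  }, integer(1))
  hot_pos <- pos[occ >= 15]
  runs <- cumsum(c(1, diff(hot_pos) != 1))
  expect_equal(max(runs), 2)
  # interval bounds agree with the scan
  expect_equal(hot$start, c(min(hot_pos[runs == 1]), min(hot_pos[runs == 2])))
  expect_equal(hot$end, c(max(hot_pos[runs == 1]) + 1L,
                          max(hot_pos[runs == 2]) + 1L))
})

test_that("promoter membership is decided by the peak center, strand-aware", {
  ann <- tiny_annotation()  # gA: + strand TSS 10000; gB: - strand TSS 45999
  # 800 bp upstream of gA -> target
  hits <- call_tf_targets(peaks_at(9200L, "tfA"), ann)
  expect_true("gA" %in% hits$target_id)
  # 600 bp downstream -> outside the 500 bp bound
  hits <- call_tf_targets(peaks_at(10600L, "tfA"), ann)
  expect_false("gA" %in% hits$target_id)
  # exactly at the half-open boundaries
  expect_true("gA" %in% call_tf_targets(peaks_at(9000L, "tfA"), ann)$target_id)
  expect_true("gA" %in% call_tf_targets(peaks_at(10499L, "tfA"), ann)$target_id)
  expect_false("gA" %in% call_tf_targets(peaks_at(10500L, "tfA"), ann)$target_id)
  # minus strand gene: upstream = larger coordinates
  expect_true("gB" %in% call_tf_targets(peaks_at(46800L, "tfA"), ann)$target_id)
  expect_false("gB" %in% call_tf_targets(peaks_at(44000L, "tfA"), ann)$target_id)
  # miRNA anchored at its pre-miRNA 5' end (mir-i: + strand at 12000)
  hits <- call_tf_targets(peaks_at(11500L, "tfA"), ann)
  expect_true("mir-i" %in% hits$target_id[hits$target_type == "mirna"])
})

test_that("HOT exclusion removes peaks by overlap or center as requested", {
  ann <- tiny_annotation()
  hot <- structure(data.frame(chrom = "chrI", start = 9300L, end = 9700L,
                              occupancy = 16L, stringsAsFactors = FALSE),
                   class = c("hot_regions", "data.frame"),
                   window_bp = 400L, threshold = 15L)
  # peak center in gA's promoter and interval overlapping the HOT region
  ps <- peaks_at(9800L, "tfA", halfwidth = 150L)  # interval [9650, 9950)
  expect_true("gA" %in% call_tf_targets(ps, ann)$target_id)
  expect_false("gA" %in% call_tf_targets(ps, ann, hot = hot,
                                         hot_mode = "exclude_overlap")$target_id)
  # center outside the HOT region: center mode keeps it
  expect_true("gA" %in% call_tf_targets(ps, ann, hot = hot,
                                        hot_mode = "exclude_center")$target_id)
  expect_error(call_tf_targets(ps, ann, hot = NULL, hot_mode = "exclude_overlap"),
               "requires")
})

test_that("window growth only adds edges; HOT exclusion only removes them", {
  sim <- small_sim(seed = 17)
  hot <- detect_hot_regions(sim$peaksets, threshold = hot_auto_threshold(8))
  key <- function(d) paste(d$tf_id, d$target_id)
  e_strict <- call_tf_targets(sim$peaksets, sim$annotation, promoter_window("strict"))
  e_default <- call_tf_targets(sim$peaksets, sim$annotation)
  e_relaxed <- call_tf_targets(sim$peaksets, sim$annotation, promoter_window("relaxed"))
  expect_true(all(key(e_strict) %in% key(e_default)))
  expect_true(all(key(e_default) %in% key(e_relaxed)))
  e_hot <- call_tf_targets(sim$peaksets, sim$annotation, hot = hot,
                           hot_mode = "exclude_overlap")
  expect_true(all(key(e_hot) %in% key(e_default)))
})

test_that("with zero background and kept HOT peaks, calls match planted truth", {
  p <- simulation_params(seed = 23, n_genes = 100, n_tfs = 6, n_mirnas = 15,
                         background_peaks_per_tf = 0, n_hot_loci = 0)
  sim <- simulate_study(p)
  called <- call_tf_targets(sim$peaksets, sim$annotation)
  truth <- paste(sim$tf_edges$tf_id, sim$tf_edges$target_id)
  got <- paste(called$tf_id, called$target_id)
  expect_true(all(truth %in% got))   # recall 1
  expect_true(all(got %in% truth))   # precision 1 (windows never collide)
})

test_that("target calls are invariant under coordinate reflection with strand flip", {
  ann <- tiny_annotation()
  ps <- peaks_at(c(9200L, 46800L, 11500L), "tfA", halfwidth = 100L)
  fwd <- call_tf_targets(ps, ann)
  L <- 100000L
  flip_strand <- function(s) ifelse(s == "+", "-", "+")
  refl <- function(d) {
    ns <- L - d$end
    ne <- L - d$start
    d$start <- ns; d$end <- ne
    if (!is.null(d$strand)) d$strand <- flip_strand(d$strand)
    d
  }
  ann2 <- genome_annotation(refl(ann$genes), refl(ann$transcripts),
                            refl(ann$exons), refl(ann$utr3), refl(ann$mirnas))
  pd <- as.data.frame(ps)
  pd2 <- refl(pd)
  pd2$center <- L - 1L - pd$center
  ps2 <- peak_set(pd2, "tfA")
  rev <- call_tf_targets(ps2, ann2)
  expect_equal(fwd[order(fwd$target_id), ], rev[order(rev$target_id), ])
})
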