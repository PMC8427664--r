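test_that("clustering statistics match direct arithmetic and are translation invariant", {
  expect_equal(clustering_stat(c(10, 20)), 10)
  expect_equal(clustering_stat(c(10, 20, 30)), 40 / 3)
  expect_equal(clustering_stat(c(10, 20, 30), "consecutive_gap"), 10)
  for (c0 in c(-5, 0, 1000)) {
    x <- c(3, 17, 40, 99)
    expect_equal(clustering_stat(x + c0), clustering_stat(x))
    expect_equal(clustering_stat(x + c0, "consecutive_gap"),
                 clustering_stat(x, "consecutive_gap"))
  }
  expect_error(clustering_stat(5), "at least 2")
})

test_that("fusion counting honours gene boundaries and the distinct-gene rule", {
  empty <- gene_annotation()
  pairs <- cbind(pos_a = c(25, 60), pos_b = c(75, 80))
  expect_equal(fusion_count(pairs, empty), 0L)

  whole <- gene_annotation("G1", 1, 100)
  # both breakends inside one gene: no fusion of two distinct genes
  expect_equal(fusion_count(pairs, whole, "junction_fusion"), 0L)
  expect_equal(fusion_count(pairs, whole, "breakpoint_in_gene",
                            cut_sites = c(25, 60, 75, 80)), 4L)

  two <- gene_annotation(c("G1", "G2"), c(1, 51), c(50, 100))
  expect_equal(fusion_count(cbind(25, 75), two, "junction_fusion"), 1L)
  # non-protein-coding genes are ignored
  nc <- gene_annotation(c("G1", "G2"), c(1, 51), c(50, 100),
                        biotype = c("protein_coding", "lincRNA"))
  expect_equal(fusion_count(cbind(25, 75), nc, "junction_fusion"), 0L)
})

test_that("null draws have the right shape and uniform cut sites", {
  m <- chromosome_model("chr6", 171115067)
  cfg <- simulation_config(m, n_segments = 7, seed = 1)
  d <- draw_rearrangement(cfg)
  expect_length(d$cut_sites, 6L)
  expect_length(d$permutation, 7L)
  expect_equal(d$permutation[1], 1L)
  expect_equal(d$permutation[7], 7L)
  expect_equal(d$orientations[c(1, 7)], c("direct", "direct"))
  expect_identical(d, draw_rearrangement(cfg))

  # order statistics of uniform cuts: smallest of 6 ~ Beta(1, 6)
  mins <- vapply(1:400, function(s)
    min(draw_rearrangement(cfg, seed = s)$cut_sites) / m$length, numeric(1))
  ks <- suppressWarnings(stats::ks.test(mins, stats::pbeta, 1, 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_simulation is deterministic and degenerate cases behave", {
  m <- tiny_model(1e6)
  case <- generate_case(m, 7, 0.5, seed = 3)
  obs <- observed_case(case$junctions, m)
  cfg <- simulation_config(m, reps = 300, seed = 11)
  r1 <- run_simulation(cfg, obs)
  r2 <- run_simulation(cfg, obs)
  expect_identical(r1$clustering_stats, r2$clustering_stats)
  expect_identical(r1$p_clustering, r2$p_clustering)
  expect_length(r1$clustering_stats, 300L)
  expect_true(r1$p_clustering >= 0 && r1$p_clustering <= 1)
  # no genes: observed fusion count 0, all replicates >= 0
  expect_equal(r1$p_fusion, 1)
  # mismatched segment count
  cfg5 <- simulation_config(m, n_segments = 5, reps = 10, seed = 1)
  expect_error(run_simulation(cfg5, obs), "cut sites")
})

test_that("p-values move monotonically with the observed values", {
  m <- tiny_model(1e6)
  genes <- generate_genes(m, 40, 10000, seed = 2)
  case <- generate_case(m, 7, 0.5, seed = 5)
  obs <- observed_case(case$junctions, m, genes)
  cfg <- simulation_config(m, reps = 400, seed = 9)
  base <- run_simulation(cfg, obs, genes)

  # shrinking the observed clustering statistic cannot increase p_clustering
  shrunk <- obs
  shrunk$clustering_pairwise <- obs$clustering_pairwise / 10
  shrunk$clustering_gap <- obs$clustering_gap / 10
  less <- run_simulation(cfg, shrunk, genes)
  expect_lte(less$p_clustering, base$p_clustering)

  # enlarging the observed fusion count cannot increase p_fusion
  more <- obs
  more$fusion_junction <- obs$fusion_junction + 3L
  bigger <- run_simulation(cfg, more, genes)
  expect_lte(bigger$p_fusion, base$p_fusion)
})

test_that("the (k+1)/(R+1) correction never returns zero", {
  m <- tiny_model(1e6)
  case <- generate_case(m, 7, 0.5, seed = 3)
  obs <- observed_case(case$junctions, m)
  obs$clustering_pairwise <- 1  # more clustered than any replicate can be
  obs$clustering_gap <- 1
  cfg <- simulation_config(m, reps = 50, seed = 4, pvalue_correction = TRUE)
  res <- run_simulation(cfg, obs)
  expect_equal(res$p_clustering, 1 / 51)
  cfg0 <- simulation_config(m, reps = 50, seed = 4)
  expect_equal(run_simulation(cfg0, obs)$p_clustering, 0)
})

test_that("small-instance enumeration matches the Monte Carlo distributions", {
  # length 30, 3 segments: 2 cuts from [1, 29], middle segment inverted or not
  L <- 30
  m <- tiny_model(L)
  genes <- gene_annotation(c("g1", "g2"), c(3, 20), c(12, 27))
  combos <- utils::combn(29, 2)
  stats_ex <- numeric(0); fus_ex <- numeric(0)
  for (i in seq_len(ncol(combos))) {
    cuts <- combos[, i]
    for (invert in c(FALSE, TRUE)) {
      stats_ex <- c(stats_ex, clustering_stat(cuts))
      pairs <- if (invert)
        rbind(c(cuts[1], cuts[2]), c(cuts[1] + 1, cuts[2] + 1))
      else matrix(numeric(0), ncol = 2)
      fus_ex <- c(fus_ex, fusion_count(pairs, genes, "junction_fusion"))
    }
  }
  cfg <- simulation_config(m, n_segments = 3, reps = 4000, seed = 17)
  case <- generate_case(m, 3, 0.5, seed = 1)
  obs <- observed_case(case$junctions, m, genes, merge_tolerance = 0)
  res <- run_simulation(cfg, obs, genes)
  # Monte Carlo means within 4 standard errors of the exhaustive means
  se_stat <- stats::sd(stats_ex) / sqrt(cfg$reps)
  expect_lt(abs(mean(res$clustering_stats) - mean(stats_ex)), 4 * se_stat)
  se_fus <- stats::sd(fus_ex) / sqrt(cfg$reps)
  expect_lt(abs(mean(res$fusion_counts) - mean(fus_ex)), 4 * se_fus)
})
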