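test_that("segments_from_cuts partitions the chromosome", {
  m <- tiny_model(100)
  p0 <- segments_from_cuts(numeric(), m)
  expect_equal(nrow(p0), 1L)
  expect_equal(c(p0$start, p0$end), c(1, 100))

  p1 <- segments_from_cuts(40, m)
  expect_equal(p1$start, c(1, 41))
  expect_equal(p1$end, c(40, 100))

  m6 <- chromosome_model("chr6", 171115067)
  cuts <- c(14000000, 109000000, 155210000, 156240700, 157240701, 158240700)
  p6 <- segments_from_cuts(cuts, m6)
  expect_equal(nrow(p6), 7L)
  expect_equal(sum(p6$end - p6$start + 1), 171115067)

  expect_error(segments_from_cuts(c(10, 10), m), "strictly increasing")
  expect_error(segments_from_cuts(c(100), m), "\\[1, length - 1\\]")
})

test_that("reference-adjacency junctions assemble to the identity path", {
  m <- tiny_model(1000)
  ident <- segments_from_cuts(c(200, 500), m)
  j <- junctions_from_path(ident, include_reference = TRUE)
  expect_equal(nrow(j), 2L)
  back <- assemble_path(j, m, merge_tolerance = 0)
  expect_equal(back$orientation, rep("direct", 3))
  expect_equal(back$start, ident$start)
  summ <- classify_inversions(back)
  expect_equal(summ$n_inversions, 0L)
  expect_equal(summ$n_junctions, 0L)
})

test_that("the index-case junction table assembles to the published architecture", {
  m <- index_case_model()
  path <- assemble_path(index_case_junctions(), m)
  expect_equal(paste0(path$segment_id,
                      ifelse(path$orientation == "inverted", "-", "+")),
               c("A+", "B-", "C-", "D-", "F+", "E-", "G+"))
  # junctions 3 and 5 sit 13 bp apart at one ARID1B disruption: merged cut
  expect_true(157240701 %in% path$end)
  summ <- classify_inversions(path)
  expect_equal(summ$n_inversions, 4L)
  expect_equal(summ$n_pericentric, 1L)
  expect_equal(summ$n_paracentric, 3L)
  expect_equal(summ$n_junctions, 6L)
  expect_equal(summ$per_segment$class[summ$per_segment$segment_id == "B"],
               "pericentric")
})

test_that("assemble_path round-trips generate_case truths", {
  m <- tiny_model(2e6)
  for (seed in 1:100) {
    case <- generate_case(m, 3 + seed %% 5, 0.5, seed = seed)
    got <- assemble_path(case$junctions, m, merge_tolerance = 0)
    expect_equal(got$start, case$truth_path$start)
    expect_equal(got$end, case$truth_path$end)
    expect_equal(got$orientation, case$truth_path$orientation)
  }
})

test_that("junctions_from_path inverts assemble_path up to normalization", {
  m <- tiny_model(2e6)
  for (seed in 1:60) {
    case <- generate_case(m, 7, 0.5, seed = 1000 + seed)
    j <- junctions_from_path(case$truth_path)   # non-reference adjacencies only
    back <- assemble_path(j, m, merge_tolerance = 0)
    norm <- cgrtools:::normalize_path(case$truth_path)
    expect_equal(back$start, norm$start)
    expect_equal(back$end, norm$end)
    expect_equal(back$orientation, norm$orientation)
  }
})

test_that("identity path yields no junctions and classify handles minimal inversions", {
  m <- tiny_model(1000, centromere = c(100, 120))
  ident <- segments_from_cuts(c(200, 500), m)
  expect_equal(nrow(junctions_from_path(ident)), 0L)
  expect_equal(classify_inversions(ident)$n_inversions, 0L)

  # single inverted middle segment away from the centromere
  inv <- ident; inv$orientation[2] <- "inverted"
  summ <- classify_inversions(inv)
  expect_equal(summ$n_inversions, 1L)
  expect_equal(summ$n_pericentric, 0L)
  expect_equal(summ$n_paracentric, 1L)
  expect_equal(summ$n_junctions, 2L)

  # same segment covering the centromere midpoint
  m2 <- tiny_model(1000, centromere = c(250, 450))
  inv2 <- segments_from_cuts(c(200, 500), m2)
  inv2$orientation[2] <- "inverted"
  expect_equal(classify_inversions(inv2)$n_pericentric, 1L)
})

test_that("classify_inversions requires a centromere only when inversions exist", {
  m <- tiny_model(1000)  # no centromere
  ident <- segments_from_cuts(c(200, 500), m)
  expect_silent(classify_inversions(ident))
  inv <- ident; inv$orientation[2] <- "inverted"
  expect_error(classify_inversions(inv), "centromere undefined")
})

test_that("classification is invariant under segment id relabeling", {
  m <- tiny_model(1000, centromere = c(100, 120))
  p <- segments_from_cuts(c(200, 500), m)
  p$orientation[2] <- "inverted"
  q <- p; q$segment_id <- c("X", "Y", "Z")
  a <- classify_inversions(p); b <- classify_inversions(q)
  expect_equal(a$n_inversions, b$n_inversions)
  expect_equal(a$n_pericentric, b$n_pericentric)
  expect_equal(a$n_junctions, b$n_junctions)
})

test_that("non-linear junction sets are rejected with informative errors", {
  m <- tiny_model(1000)
  # breakend used twice: two junctions claim the left flank of cut 200
  bad <- junction_table(c("j1", "j2"),
                        "chr", c(200, 200), c("left_of_cut", "left_of_cut"),
                        "chr", c(501, 500), c("right_of_cut", "left_of_cut"))
  expect_error(assemble_path(bad, m, merge_tolerance = 0), "used twice")

  # dangling end: cut 200 has only one breakend
  dangling <- junction_table("j1", "chr", 200, "left_of_cut",
                             "chr", 500, "left_of_cut")
  expect_error(assemble_path(dangling, m, merge_tolerance = 0), "dangling")

  # cyclic: middle segment circularized head-to-tail, terminals joined directly
  cyc <- junction_table(c("j1", "j2"),
                        "chr", c(201, 200), c("right_of_cut", "left_of_cut"),
                        "chr", c(500, 501), c("left_of_cut", "right_of_cut"))
  expect_error(assemble_path(cyc, m, merge_tolerance = 0), "non-linear")
})

test_that("breakend merging unifies nearby cuts at the midpoint", {
  m <- tiny_model(10000)
  # one disruption observed as 100|113 by two junctions (13 bp resection)
  j <- junction_table(
    c("a", "b"),
    "chr", c(100, 5000), c("left_of_cut", "left_of_cut"),
    "chr", c(113, 5001), c("right_of_cut", "right_of_cut"))
  path <- assemble_path(j, m, merge_tolerance = 100)
  expect_true(106 %in% path$end)  # floor((100 + 112) / 2)
  expect_error(assemble_path(j, m, merge_tolerance = 5), "dangling")
})
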