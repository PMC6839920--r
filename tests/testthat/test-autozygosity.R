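test_that("detect_roh handles the all-het and toy run fixtures", {
  # 1,000 heterozygous markers: no run survives
  pn <- make_panel(matrix(1L, nrow = 1000))
  expect_equal(nrow(detect_roh(pn, "S1", roh_params())), 0)

  # 20-marker toy: 8 hom, 1 het, 11 hom
  codes <- matrix(c(rep(2L, 8), 1L, rep(2L, 11)), ncol = 1)
  pn <- make_panel(codes)
  one <- detect_roh(pn, "S1", roh_params(min_markers = 10, min_length_bp = 1,
                                         max_het = 1))
  expect_equal(nrow(one), 1)          # the het is absorbed: one 20-marker run
  expect_equal(one$n_markers, 20)
  expect_equal(c(one$start, one$end), c(1000 - 1, 20000))

  zero_tol <- detect_roh(pn, "S1", roh_params(min_markers = 1,
                                              min_length_bp = 1, max_het = 0))
  expect_equal(zero_tol$n_markers, c(8, 11))  # split at the het call
  filtered <- detect_roh(pn, "S1", roh_params(min_markers = 10,
                                              min_length_bp = 1, max_het = 0))
  expect_equal(filtered$n_markers, 11)        # only the 11-marker run survives

  expect_error(detect_roh(pn, "nobody"), "unknown sample")
  empty <- make_panel(matrix(integer(), nrow = 0, ncol = 1,
                             dimnames = list(NULL, "S1")))
  expect_equal(nrow(detect_roh(empty, "S1")), 0)
})

test_that("detect_roh equals the brute-force sub-run oracle", {
  set.seed(42)
  for (k in 1:30) {
    n <- sample(30:120, 1)
    codes <- matrix(sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE,
                           prob = c(0.05, 0.45, 0.2, 0.3)), ncol = 1)
    pos <- sort(sample.int(n * 2000, n))
    pn <- make_panel(codes, pos = pos)
    params <- roh_params(min_markers = sample(1:10, 1),
                         min_length_bp = sample(c(1, 5000, 20000), 1),
                         max_het = sample(0:2, 1),
                         max_missing = sample(0:2, 1))
    got <- detect_roh(pn, "S1", params)
    want <- oracle_detect_roh(pn, "S1", params)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_markers, want$n_markers)
  }
})

test_that("shared_loh computes affected-intersection minus unaffected-union", {
  roh <- list(
    A1 = segments("c", c(0, 50), c(100, 200)),
    A2 = segments("c", 60, 150),
    U1 = segments("c", 120, 130)
  )
  got <- shared_loh(roh, c("A1", "A2"), "U1")
  expect_equal(got$start, c(60, 130))
  expect_equal(got$end, c(120, 150))
})

test_that("shared_loh identity and validation", {
  roh <- list(A = segments("c", c(10, 400), c(90, 600)))
  solo <- shared_loh(roh, "A", character())
  expect_equal(solo$start, c(10, 400))
  expect_equal(solo$end, c(90, 600))
  expect_error(shared_loh(roh, character()), "at least one affected")
  expect_error(shared_loh(roh, c("A", "B")), "no ROH set")
})

test_that("shared_loh equals per-base set algebra on random instances", {
  N <- 1000
  for (k in 1:40) {
    roh <- random_roh_sets(5, N, seed = 1000 + k)
    aff <- names(roh)[1:3]
    unaff <- names(roh)[4:5]
    min_bp <- sample(c(0, 5, 50), 1)
    got <- shared_loh(roh, aff, unaff, min_shared_bp = min_bp)
    want <- oracle_shared_loh(roh, aff, unaff, N, min_shared_bp = min_bp)
    expect_equal(got$start, want$start, info = paste("case", k))
    expect_equal(got$end, want$end, info = paste("case", k))
  }
})

test_that("merge_segments bridges the printed chr6 gap and is idempotent", {
  # adjacent published segments 19,686,123-19,803,768 and
  # 19,804,188-21,778,105: a 419 bp gap, merged under 1 kb tolerance
  co1 <- internal_coords(19686123, 19803768)
  co2 <- internal_coords(19804188, 21778105)
  segs <- segments("chr6", c(co1$start, co2$start), c(co1$end, co2$end))
  merged <- merge_segments(segs, max_gap_bp = 1000)
  expect_equal(nrow(merged), 1)
  disp <- display_coords(merged$start, merged$end)
  expect_equal(c(disp$start, disp$end), c(19686123, 21778105))

  # idempotence
  expect_equal(merge_segments(merged, 1000), merged)

  # max_gap 0 keeps disjoint segments apart
  expect_equal(nrow(merge_segments(segs, 0)), 2)

  expect_error(merge_segments(segs, -1), "non-negative")
})

test_that("merging all chr12 published segments never increases the count", {
  starts <- c(71016157, 72320251, 73671276, 77249400, 79302419, 82147487,
              83541966, 88594159, 89915484, 91766720, 93251750)
  ends <- c(72070710, 73669855, 75891939, 79204389, 82139004, 83157896,
            88441286, 89910070, 91765486, 93152115, 95410845)
  co <- internal_coords(starts, ends)
  segs <- segments("chr12", co$start, co$end)
  merged <- merge_segments(segs, max_gap_bp = 1e6)
  expect_lte(nrow(merged), nrow(segs))
  # union never loses covered bases
  expect_gte(segment_span(merged), segment_span(segs))
  # idempotent at this tolerance too
  expect_equal(merge_segments(merged, 1e6), merged)
})

test_that("window heterozygosity matches a hand-tallied fixture", {
  v <- make_variants(
    data.frame(chrom = "chr6",
               pos = c(5e4, 9e4, 1.2e5, 1.5e5, 1.8e5, 2.1e5, 2.4e5,
                       2.6e5, 2.8e5, 2.9e5)),
    gt = list(P1 = c(1, 2, 2, 2, 0, 1, 1, 1, 2, -1))
  )
  win <- window_heterozygosity(v, "P1", window_bp = 1e5,
                               region = list(chrom = "chr6", start = 1,
                                             end = 3e5))
  # hand tally: win1 {het@50k, hom@90k}; win2 {hom@120k, hom@150k; the
  # code-0 call at 180k is excluded}; win3 {het@210k,240k,260k, hom@280k;
  # missing call at 290k excluded}
  expect_equal(win$n_het, c(1, 0, 3))
  expect_equal(win$n_hom, c(1, 2, 1))
  expect_equal(win$avg_het, c(0.5, 0, 0.75))
  # conservation: window n_het sums to total het calls in region
  expect_equal(sum(win$n_het), sum(v$gt_P1 == 1))
})

test_that("window heterozygosity handles pure, empty and truncated windows", {
  v <- make_variants(data.frame(chrom = "c", pos = c(10, 20, 150)),
                     gt = list(S = c(2, 2, 1)))
  win <- window_heterozygosity(v, "S", window_bp = 100,
                               region = list(chrom = "c", start = 1, end = 350))
  expect_equal(win$avg_het, c(0, 1, NA, NA))  # empty windows are NA, not 0
  expect_equal(win$end[4], 350)               # terminal window truncated
  all_het <- window_heterozygosity(
    make_variants(data.frame(chrom = "c", pos = c(5, 6)),
                  gt = list(S = c(1, 1))),
    "S", window_bp = 100, region = list(chrom = "c", start = 1, end = 100))
  expect_equal(all_het$avg_het, 1)
  expect_error(window_heterozygosity(v, "S", window_bp = 0,
                                     region = list(chrom = "c", start = 1,
                                                   end = 10)),
               "positive")
  expect_error(window_heterozygosity(v, "missing", window_bp = 10,
                                     region = list(chrom = "c", start = 1,
                                                   end = 10)),
               "no genotypes")
})

test_that("avg_het stays within [0,1] and het counts are conserved", {
  set.seed(11)
  for (k in 1:10) {
    n <- 50
    v <- make_variants(
      data.frame(chrom = "c", pos = sort(sample.int(5e5, n))),
      gt = list(S = sample(c(-1, 0, 1, 2), n, replace = TRUE)))
    win <- window_heterozygosity(v, "S", window_bp = 5e4,
                                 region = list(chrom = "c", start = 1,
                                               end = 5e5))
    ok <- !is.na(win$avg_het)
    expect_true(all(win$avg_het[ok] >= 0 & win$avg_het[ok] <= 1))
    expect_equal(sum(win$n_het), sum(v$gt_S == 1))
  }
})
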