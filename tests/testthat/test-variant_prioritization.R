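variant_key_strings <- function(v)
  paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE, digits = 15),
        v$ref, v$alt, sep = ":")

fixture_variants <- function() {
  make_variants(
    data.frame(
      chrom = rep("chr6", 6),
      pos = c(25e6, 22e6, 24e6, 24.5e6, 25.5e6, 26e6),
      ref = "G", alt = "A",
      gene = paste0("G", 1:6),
      consequence = c("missense", "missense", "synonymous",
                      "splice_acceptor", "missense", "missense")
    ),
    af = list(ExAC = c(0.00014, 0.0001, 0.0001, 0.028, 0.0001, 0.01),
              `1KG` = c(0, 0, 0, 0.02, NA, 0),
              TOPMED = c(0.0002, 0.0001, 0, 0.03, 0.0001, 0)),
    gt = list(FA = c(1, 1, 1, 1, 1, 1), MO = c(1, 1, 1, 1, 2, 1),
              P1 = c(2, 2, 2, 2, 2, 2), P2 = c(2, 2, 2, 2, 2, 2),
              P3 = c(2, 1, 2, 2, 2, 2),
              S1 = c(1, 0, 1, 1, 2, 1), S2 = c(0, 0, 0, 0, 0, -1))
  )
}

test_that("functional filter keeps non-synonymous and splice classes", {
  v <- fixture_variants()
  res <- filter_functional(v)
  expect_equal(res$survivors$gene, c("G1", "G2", "G4", "G5", "G6"))
  trail <- res$trails
  expect_equal(trail$verdict[trail$variant_key == "chr6:24000000:G:A"], "fail")

  # unannotated consequence fails by default, passes in lenient mode
  v$consequence[1] <- NA
  strict <- filter_functional(v)
  expect_equal(strict$trails$detail[1], "unannotated")
  expect_false("G1" %in% strict$survivors$gene)
  lenient <- filter_functional(v, cascade_config(unannotated_policy = "pass"))
  expect_true("G1" %in% lenient$survivors$gene)
})

test_that("rarity filter applies strict < in every database", {
  v <- fixture_variants()
  res <- filter_rare(v)
  # G4 is the 2.8% splice allele: common, fails
  expect_false("G4" %in% res$survivors$gene)
  # G6 sits exactly at the 1% boundary: strict < fails it
  expect_false("G6" %in% res$survivors$gene)
  # G5 has a missing 1KG AF: treated as rare by default
  expect_true("G5" %in% res$survivors$gene)
  strict <- filter_rare(v, cascade_config(missing_af_policy = "fail"))
  expect_false("G5" %in% strict$survivors$gene)
  expect_match(strict$trails$detail[strict$trails$variant_key ==
                                      "chr6:25500000:G:A"], "missing AF")
})

test_that("recessive pattern demands hom-alt affecteds, carrier-free sibs", {
  v <- fixture_variants()
  ped <- nuclear_ped()
  res <- filter_recessive_pattern(v, ped)
  # G1: affected {2,2,2}, unaffected {1,0} -> pass
  expect_true("G1" %in% res$survivors$gene)
  # G2: one affected het -> fail
  expect_false("G2" %in% res$survivors$gene)
  # G5: an unaffected sibling is hom-alt -> fail
  expect_false("G5" %in% res$survivors$gene)
  # G6: missing genotype in a required sample -> fail, named detail
  trail <- res$trails
  expect_equal(trail$detail[trail$variant_key == "chr6:26000000:G:A"],
               "missing genotype")
  # sample required by the pedigree but absent from genotypes
  v2 <- v[setdiff(names(v), "gt_S2")]
  expect_error(filter_recessive_pattern(v2, ped), "absent from variant")
})

test_that("region restriction uses half-open membership on printed segments", {
  v <- fixture_variants()
  co <- internal_coords(23584375, 26148311)
  seg <- segments("chr6", co$start, co$end)
  res <- restrict_to_regions(v, seg)
  # 25,000,000 lies inside 23,584,375-26,148,311
  expect_true("G1" %in% res$survivors$gene)
  # 22,000,000 falls in the gap between published segments
  expect_false("G2" %in% res$survivors$gene)
  # boundary behaviour: first and last base of the printed interval pass
  edge <- make_variants(data.frame(chrom = "chr6",
                                   pos = c(23584375, 26148311, 26148312)))
  res_edge <- restrict_to_regions(edge, seg)
  expect_equal(res_edge$survivors$pos, c(23584375, 26148311))
  # empty segment set fails everything
  expect_equal(nrow(restrict_to_regions(v, segments())$survivors), 0)
})

test_that("parental segregation check reports carrier consistency", {
  ped <- nuclear_ped()
  v <- fixture_variants()
  expect_equal(parental_segregation_check(v[1, ], ped)$verdict, "consistent")
  # a hom-alt parent is inconsistent with recessive transmission
  expect_equal(parental_segregation_check(v[5, ], ped)$verdict, "inconsistent")
  v$gt_MO[1] <- -1L
  expect_equal(parental_segregation_check(v[1, ], ped)$verdict, "untestable")
  v2 <- v[setdiff(names(v), c("gt_FA", "gt_MO"))]
  expect_equal(parental_segregation_check(v2[1, ], ped)$verdict, "untestable")
})

test_that("the full cascade yields one audited survivor on the fixture", {
  v <- fixture_variants()
  ped <- nuclear_ped()
  co <- internal_coords(23584375, 26148311)
  report <- run_prioritization(v, ped, segments("chr6", co$start, co$end))
  expect_s3_class(report, "candidate_report")
  expect_equal(nrow(report$survivors), 1)
  expect_equal(report$survivors$gene, "G1")
  expect_equal(report$survivors$segregation, "consistent")

  # trail completeness: every variant appears at every stage, exactly once
  expect_equal(nrow(report$trails), 6 * 4)
  per_var <- table(report$trails$variant_key)
  expect_true(all(per_var == 4))
  # every non-survivor carries exactly one named failing filter, and
  # stages after a failure are recorded as not-evaluated
  survivor_keys <- variant_key_strings(report$survivors)
  for (key in unique(report$trails$variant_key)) {
    tr <- report$trails[report$trails$variant_key == key, ]
    n_fail <- sum(tr$verdict == "fail")
    if (key %in% survivor_keys) {
      expect_equal(n_fail, 0)
      expect_true(all(tr$verdict == "pass"))
    } else {
      expect_equal(n_fail, 1)
      expect_equal(sum(tr$verdict == "not-evaluated"),
                   4 - match(tr$filter[tr$verdict == "fail"],
                             c("functional", "rare", "recessive_pattern",
                               "region_overlap")))
    }
  }

  # removing the region restriction yields a survivor superset
  no_region <- run_prioritization(v, ped, segments(),
                                  cascade_config(require_region_overlap = FALSE))
  expect_true(all(variant_key_strings(report$survivors) %in%
                    variant_key_strings(no_region$survivors)))

  # empty input: empty report, no error
  empty <- run_prioritization(v[0, ], ped, segments("chr6", 0, 10))
  expect_equal(nrow(empty$survivors), 0)
  expect_equal(empty$n_input, 0)
})

test_that("the survivor set is invariant under filter-order permutation", {
  set.seed(8)
  ped <- nuclear_ped()
  samples <- ped$sample_id
  for (k in 1:10) {
    n <- 20
    v <- make_variants(
      data.frame(chrom = "chr6", pos = sort(sample.int(5e7, n)),
                 consequence = sample(c("missense", "synonymous", "intronic",
                                        "frameshift"), n, replace = TRUE)),
      af = list(ExAC = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.05)),
                `1KG` = runif(n, 0, 0.02), TOPMED = runif(n, 0, 0.02)),
      gt = stats::setNames(lapply(samples, function(s)
        sample(c(-1, 0, 1, 2), n, replace = TRUE, prob = c(0.05, 0.4, 0.3, 0.25))),
        samples))
    regions <- segments("chr6", c(0, 3e7), c(1e7, 4.5e7))
    cfg <- cascade_config()
    filters <- list(
      function(x) filter_functional(x, cfg)$survivors,
      function(x) filter_rare(x, cfg)$survivors,
      function(x) filter_recessive_pattern(x, ped, cfg)$survivors,
      function(x) restrict_to_regions(x, regions)$survivors
    )
    base <- Reduce(function(x, f) f(x), filters, v)
    for (perm in list(c(4, 3, 2, 1), sample(4))) {
      alt <- Reduce(function(x, f) f(x), filters[perm], v)
      expect_equal(sort(variant_key_strings(alt)),
                   sort(variant_key_strings(base)))
    }
    # each filter is contractive
    for (f in filters) {
      expect_true(all(variant_key_strings(f(v)) %in% variant_key_strings(v)))
    }
  }
})

test_that("decoys failing exactly one predicate never survive", {
  ped <- nuclear_ped()
  base <- list(chrom = "chr6", pos = 25e6, consequence = "missense")
  af_ok <- list(ExAC = 1e-4, `1KG` = 0, TOPMED = 1e-4)
  gt_ok <- list(FA = 1, MO = 1, P1 = 2, P2 = 2, P3 = 2, S1 = 1, S2 = 0)
  co <- internal_coords(23584375, 26148311)
  region <- segments("chr6", co$start, co$end)

  run1 <- function(core_patch = list(), af = af_ok, gt = gt_ok) {
    core <- modifyList(base, core_patch)
    v <- make_variants(as.data.frame(core, stringsAsFactors = FALSE),
                       af = af, gt = gt)
    nrow(run_prioritization(v, ped, region)$survivors)
  }
  expect_equal(run1(), 1)                                      # positive control
  expect_equal(run1(list(consequence = "synonymous")), 0)      # functional decoy
  expect_equal(run1(af = modifyList(af_ok, list(ExAC = 0.02))), 0)  # common decoy
  expect_equal(run1(gt = modifyList(gt_ok, list(P3 = 1))), 0)  # pattern decoy
  expect_equal(run1(list(pos = 22e6)), 0)                      # region decoy
})
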