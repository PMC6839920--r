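test_that("the looped template realises a first-cousin nuclear family", {
  ped <- build_looped_pedigree(sim_config())
  expect_equal(nrow(ped), 13)
  expect_equal(length(affected_ids(ped)), 3)
  expect_equal(sort(intersect(unaffected_ids(ped), offspring_ids(ped))),
               c("S1", "S2"))
  # the loop: both parents descend from the shared grandparental couple
  expect_equal(inbreeding_coefficient(ped, "P2"), 1 / 16)
  validate_pedigree(ped)

  ped42 <- build_looped_pedigree(sim_config(n_affected = 4, n_unaffected = 1))
  expect_equal(length(affected_ids(ped42)), 4)

  expect_error(sim_config(n_affected = 0), "at least one affected")
  expect_error(sim_config(marker_density = -1), "non-negative")
  expect_error(sim_config(causal_variant_spec = modifyList(
    default_causal_spec(), list(pop_afs = c(ExAC = 0.05)))), "rare")
  bad <- pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  cfg <- sim_config(pedigree_template = "custom", custom_pedigree = bad)
  expect_equal(nrow(build_looped_pedigree(cfg)), 2)
  expect_error(build_looped_pedigree(
    sim_config(pedigree_template = "custom")), "custom_pedigree")
})

test_that("gene dropping is deterministic and respects the seed contract", {
  cfg <- sim_config(chrom_lengths = c(chrA = 2e7), marker_density = 20,
                    background_variant_rate = 1, causal_variant_spec = NULL)
  ped <- build_looped_pedigree(cfg)
  a <- gene_drop(ped, cfg, seed = 5)
  b <- gene_drop(ped, cfg, seed = 5)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$autozygous_segments, b$truth$autozygous_segments)
  c2 <- gene_drop(ped, cfg, seed = 6)
  expect_false(identical(a$panel$calls, c2$panel$calls))
  expect_error(gene_drop(ped, cfg, seed = NULL), "seed is mandatory")
})

test_that("zero recombination transmits whole founder chromosomes", {
  cfg <- sim_config(chrom_lengths = c(chrA = 1e7), marker_density = 10,
                    recomb_rate = 0, background_variant_rate = 0,
                    causal_variant_spec = NULL, genotyping_error_rate = 0)
  ped <- build_looped_pedigree(cfg)
  for (s in 1:10) {
    ds <- gene_drop(ped, cfg, seed = s)
    segs <- ds$truth$autozygous_segments
    # every autozygous tract is a whole chromosome (or the offspring has none)
    if (nrow(segs)) {
      expect_true(all(segs$start == 0 & segs$end == 1e7))
    }
  }
})

test_that("mean autozygous fraction approaches F = 1/16 across replicates", {
  cfg <- sim_config(n_affected = 1, n_unaffected = 0, marker_density = 0,
                    background_variant_rate = 0, causal_variant_spec = NULL,
                    genotyping_error_rate = 0)
  ped <- build_looped_pedigree(cfg)
  n <- 600
  fr <- vapply(seq_len(n), function(s) {
    ds <- gene_drop(ped, cfg, seed = s)
    segs <- ds$truth$autozygous_segments
    segment_span(segs[segs$sample_id == "P1", , drop = FALSE]) /
      sum(cfg$chrom_lengths)
  }, numeric(1))
  f <- inbreeding_coefficient(ped, "P1")
  se <- stats::sd(fr) / sqrt(n)
  expect_lt(abs(mean(fr) - f), 3 * se)
})

test_that("planted causal variant is hom-alt in affecteds, het in parents", {
  ds <- find_valid_seed(sim_config(), seed = 11)
  cv <- ds$truth$causal_variant
  expect_equal(unlist(cv[paste0("gt_", c("P1", "P2", "P3"))],
                      use.names = FALSE), rep(2L, 3))
  expect_equal(unlist(cv[paste0("gt_", c("FATHER", "MOTHER"))],
                      use.names = FALSE), rep(1L, 2))
  expect_true(all(unlist(cv[paste0("gt_", c("S1", "S2"))]) <= 1L))
  # the variant sits inside a ground-truth autozygous tract of every affected
  segs <- ds$truth$autozygous_segments
  for (id in c("P1", "P2", "P3")) {
    own <- segs[segs$sample_id == id & segs$chrom == cv$chrom, ]
    expect_true(any(own$start < cv$pos & cv$pos <= own$end))
  }
  # pre-filter guarantee: the planted variant passes every cascade predicate
  expect_true(cv$consequence %in% cascade_config()$functional_classes)
  expect_true(all(unlist(cv[grep("^af_", names(cv))]) < 0.01))
})

test_that("planting errors out, not silently, when no shared tract exists", {
  cfg <- sim_config(chrom_lengths = c(chrA = 5e6), marker_density = 0,
                    background_variant_rate = 0)
  ped <- build_looped_pedigree(cfg)
  seen_error <- FALSE
  for (s in 1:60) {
    ds <- gene_drop(ped, cfg, seed = s)
    out <- tryCatch(plant_causal_variant(ds),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      seen_error <- TRUE
      expect_match(out, "different seed")
      break
    }
  }
  expect_true(seen_error)  # on a 5 Mb genome most seeds cannot plant
})

test_that("single affected offspring plants into any of its tracts", {
  cfg <- sim_config(n_affected = 1, n_unaffected = 0,
                    background_variant_rate = 0, marker_density = 0,
                    genotyping_error_rate = 0)
  ds <- find_valid_seed(cfg, seed = 1, require_unique = FALSE)
  cv <- ds$truth$causal_variant
  segs <- ds$truth$autozygous_segments
  own <- segs[segs$sample_id == "P1" & segs$chrom == cv$chrom, ]
  expect_true(any(own$start < cv$pos & cv$pos <= own$end))
  expect_equal(cv$gt_P1, 2L)
})

test_that("genotyping error injection is calibrated and reproducible", {
  set.seed(3)
  calls <- matrix(sample(c(0L, 1L, 2L), 1e5, replace = TRUE), ncol = 4)
  pn <- make_panel(calls, sample_id = paste0("S", 1:4))

  expect_identical(inject_genotyping_error(pn, 0, seed = 1), pn)

  rate <- 0.01
  out <- inject_genotyping_error(pn, rate, seed = 2)
  changed <- mean(out$calls != pn$calls)
  se <- sqrt(rate * (1 - rate) / length(calls))
  expect_lt(abs(changed - rate), 3 * se)
  # corrupted codes remain valid genotypes
  expect_true(all(out$calls %in% c(-1L, 0L, 1L, 2L)))

  out2 <- inject_genotyping_error(pn, rate, seed = 2)
  expect_identical(out$calls, out2$calls)

  # missing calls stay missing
  pn$calls[1:100] <- -1L
  out3 <- inject_genotyping_error(pn, 0.5, seed = 4)
  expect_true(all(out3$calls[1:100] == -1L))

  expect_error(inject_genotyping_error(pn, 1, seed = 1), "\\[0, 1\\)")
})

test_that("exported dataset files round-trip through the readers", {
  ds <- find_valid_seed(sim_config(marker_density = 10), seed = 21)
  dir <- withr::local_tempdir()
  paths <- export_dataset(ds, dir)
  expect_equal(as.data.frame(read_ped(paths["ped"])),
               as.data.frame(ds$pedigree))
  expect_equal(read_vcf_subset(paths["vcf"]), ds$variants)
  expect_equal(read_panel_tsv(paths["panel"])$calls, ds$panel$calls)
  truth_back <- read_bed(paths["truth_bed"])
  expect_equal(segment_span(truth_back),
               segment_span(ds$truth$autozygous_segments))
})
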