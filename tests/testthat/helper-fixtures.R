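# fixture builders shared across test files

make_panel <- function(codes, pos = NULL, chrom = "chr1",
                       sample_id = "S1") {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(nrow(codes)) * 1000
  genotype_panel(
    markers = data.frame(chrom = rep_len(chrom, nrow(codes)),
                         pos = as.numeric(pos),
                         marker_id = sprintf("m%04d", seq_len(nrow(codes))),
                         stringsAsFactors = FALSE),
    samples = if (is.null(colnames(codes))) sample_id else colnames(codes),
    calls = codes
  )
}

# assemble a variant table from a core data.frame plus named lists of
# per-database AFs and per-sample genotypes
make_variants <- function(core, af = list(), gt = list()) {
  defaults <- data.frame(chrom = "chr1", pos = 1000, ref = "A", alt = "G",
                         gene = "GENE1", consequence = "missense",
                         cds_pos = NA_real_, protein_pos = NA_real_,
                         stringsAsFactors = FALSE)
  n <- nrow(core)
  for (col in names(defaults))
    if (is.null(core[[col]])) core[[col]] <- rep(defaults[[col]], n)
  for (db in names(af)) core[[paste0("af_", db)]] <- af[[db]]
  for (s in names(gt)) core[[paste0("gt_", s)]] <- as.integer(gt[[s]])
  validate_variants(core)
  core
}

# nuclear family: parents FA/MO, probands P1..P3, sibs S1..S2
nuclear_ped <- function() {
  pedigree(
    sample_id = c("FA", "MO", "P1", "P2", "P3", "S1", "S2"),
    father_id = c(NA, NA, rep("FA", 5)),
    mother_id = c(NA, NA, rep("MO", 5)),
    sex = c("male", "female", "male", "male", "female", "female", "male"),
    affected = c("unaffected", "unaffected", rep("affected", 3),
                 rep("unaffected", 2))
  )
}

random_roh_sets <- function(n_samples, N, seed) {
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_samples)) {
    n_seg <- sample(0:4, 1)
    if (n_seg == 0) {
      out[[k]] <- segments()
      next
    }
    s <- sort(sample(0:(N - 2), n_seg))
    e <- pmin(N, s + sample(1:(N / 2), n_seg, replace = TRUE))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "c", IRanges::IRanges(s + 1, e)))
    out[[k]] <- segments(chrom = "c",
                         start = GenomicRanges::start(gr) - 1,
                         end = GenomicRanges::end(gr))
  }
  names(out) <- paste0("ind", seq_len(n_samples))
  out
}
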