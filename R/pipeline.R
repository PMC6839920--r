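#' End-to-end candidate mapping on a dataset
#'
#' Runs the discovery pipeline: per-offspring ROH detection on the
#' marker panel, shared-LOH derivation (homozygous in every affected,
#' subtracting unaffected homozygosity), optional gap-merging of the
#' shared segments, then the recessive-model variant filter cascade
#' restricted to those segments.
#'
#' @param dataset list with `pedigree`, `panel`, `variants` (as produced
#'   by [simulate_dataset()], or assembled from [read_ped()],
#'   [read_panel_tsv()], [read_vcf_subset()]).
#' @param roh a [roh_params()].
#' @param min_shared_bp minimum shared-LOH segment length (default 1e6).
#' @param merge_gap_bp gap tolerance applied to the shared segments
#'   (default 1e5; whole-genome data show LOH regions are more
#'   continuous than fragmented array calls suggest).
#' @param config a [cascade_config()].
#' @return list: `report` ([run_prioritization()] result), `shared_loh`
#'   segments, `roh_by_sample` list.
#' @export
map_candidates <- function(dataset, roh = roh_params(),
                           min_shared_bp = 1e6, merge_gap_bp = 1e5,
                           config = cascade_config()) {
  ped <- dataset$pedigree
  aff <- affected_ids(ped)
  unaff <- intersect(unaffected_ids(ped), offspring_ids(ped))
  ids <- c(aff, unaff)
  roh_by_sample <- lapply(ids, function(id)
    detect_roh(dataset$panel, id, roh))
  names(roh_by_sample) <- ids
  shared <- shared_loh(roh_by_sample, aff, unaff,
                       min_shared_bp = min_shared_bp)
  if (merge_gap_bp > 0 && nrow(shared) > 0)
    shared <- merge_segments(shared, merge_gap_bp)
  report <- run_prioritization(dataset$variants, ped, shared, config)
  list(report = report, shared_loh = shared, roh_by_sample = roh_by_sample)
}

#' Reciprocal-overlap recovery of known segments
#'
#' For each truth segment, reports: the fraction of it covered by the
#' union of detected segments (`covered_fraction`); the reciprocal
#' overlap against the single best-matching detected segment
#' (`reciprocal_overlap`); and the reciprocal overlap against the union
#' of all detected segments touching the truth segment
#' (`reciprocal_union` =
#' `min(covered / truth_length, covered / union_length)`, where
#' `union_length` sums every overlapping detected segment in full).
#' The union form is the robust recovery measure when calls are
#' fragmented by genotyping error: fragmentation does not count against
#' recovery twice, while a detected blob much larger than the truth
#' segment still drives the score down. Used to benchmark ROH detection
#' against simulated autozygous tracts.
#'
#' @param truth,detected segment data.frames (0-based half-open).
#' @return data.frame: one row per truth segment with `chrom`, `start`,
#'   `end`, `length`, `covered_fraction`, `reciprocal_overlap`,
#'   `reciprocal_union`.
#' @export
segment_recovery <- function(truth, detected) {
  validate_segments(truth)
  validate_segments(detected)
  out <- truth[c("chrom", "start", "end")]
  out$length <- truth$end - truth$start
  n <- nrow(truth)
  out$covered_fraction <- numeric(n)
  out$reciprocal_overlap <- numeric(n)
  out$reciprocal_union <- numeric(n)
  for (i in seq_len(n)) {
    d <- detected[detected$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(d) == 0) next
    ov <- pmax(0, pmin(d$end, truth$end[i]) - pmax(d$start, truth$start[i]))
    covered <- sum(ov)
    out$covered_fraction[i] <- covered / out$length[i]
    rec <- ifelse(ov > 0, pmin(ov / out$length[i], ov / (d$end - d$start)), 0)
    out$reciprocal_overlap[i] <- max(rec)
    union_len <- sum((d$end - d$start)[ov > 0])
    out$reciprocal_union[i] <- if (union_len > 0) {
      min(covered / out$length[i], covered / union_len)
    } else 0
  }
  rownames(out) <- NULL
  out
}

#' Export a simulated dataset to standard files
#'
#' Writes the PED, annotated VCF, genotype-panel TSV, and ground-truth
#' BED (autozygous tracts) of a simulated dataset into a directory.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ped = file.path(dir, "family.ped"),
             vcf = file.path(dir, "variants.vcf"),
             panel = file.path(dir, "panel.tsv"),
             truth_bed = file.path(dir, "autozygous_truth.bed"))
  write_ped(dataset$pedigree, paths["ped"])
  write_vcf_subset(dataset$variants, paths["vcf"])
  write_panel_tsv(dataset$panel, paths["panel"])
  write_bed(dataset$truth$autozygous_segments[
    c("chrom", "start", "end", "sample_id", "n_markers")], paths["truth_bed"])
  invisible(paths)
}
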