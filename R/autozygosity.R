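#' Parameters for run-of-homozygosity detection
#'
#' Defaults are motivated by genotyping-array densities of roughly
#' 80-100 markers/Mb: 50 markers and 1 Mb correspond to about half a
#' megabase of supporting markers per called megabase, one tolerated
#' heterozygous call absorbs isolated genotyping errors, and five
#' tolerated no-calls absorb array dropouts.
#'
#' @param min_markers minimum markers per reported run (default 50).
#' @param min_length_bp minimum run span in bp (default 1e6).
#' @param max_het maximum heterozygous calls tolerated within a run
#'   (default 1).
#' @param max_missing maximum missing calls tolerated within a run
#'   (default 5).
#' @return list of class `"roh_params"`.
#' @export
roh_params <- function(min_markers = 50, min_length_bp = 1e6,
                       max_het = 1, max_missing = 5) {
  p <- list(min_markers = min_markers, min_length_bp = min_length_bp,
            max_het = max_het, max_missing = max_missing)
  if (any(unlist(p) < 0) || min_length_bp <= 0)
    stop("roh_params must be non-negative with min_length_bp > 0",
         call. = FALSE)
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity for one sample
#'
#' Scans each chromosome left to right and greedily extends a run from
#' the current marker as far right as the tolerance budget allows (at
#' most `max_het` heterozygous and `max_missing` missing calls per run);
#' the next run starts after the previous one ends, so runs are disjoint
#' and the scan is deterministic (ties at a boundary heterozygous call
#' extend rightward). Runs with fewer than `min_markers` markers or
#' spanning less than `min_length_bp` are dropped. A run covers
#' `[pos(first marker) - 1, pos(last marker))` in 0-based half-open
#' coordinates.
#'
#' @param panel a [genotype_panel()] (markers sorted by chrom, pos).
#' @param sample_id sample to scan.
#' @param params a [roh_params()].
#' @return segment `data.frame` (see [segments()]) with `n_markers`
#'   filled in; sorted and non-overlapping.
#' @export
detect_roh <- function(panel, sample_id, params = roh_params()) {
  validate_panel(panel)
  g <- panel_sample_calls(panel, sample_id)
  if (!length(g)) return(segments())
  out <- list()
  for (chr in unique(panel$markers$chrom)) {
    idx <- which(panel$markers$chrom == chr)
    runs <- scan_runs(g[idx], params$max_het, params$max_missing)
    if (!nrow(runs)) next
    pos <- panel$markers$pos[idx]
    first <- pos[runs$from]
    last <- pos[runs$to]
    keep <- (runs$to - runs$from + 1) >= params$min_markers &
      (last - first + 1) >= params$min_length_bp
    if (!any(keep)) next
    out[[chr]] <- segments(chrom = chr,
                           start = first[keep] - 1, end = last[keep],
                           sample_id = sample_id,
                           n_markers = (runs$to - runs$from + 1)[keep])
  }
  if (!length(out)) return(segments())
  sort_segments(do.call(rbind, out))
}

## greedy left-to-right maximal extension; returns marker index ranges
scan_runs <- function(g, max_het, max_missing) {
  n <- length(g)
  from <- integer()
  to <- integer()
  i <- 1L
  while (i <= n) {
    het <- 0L
    miss <- 0L
    j <- i
    while (j <= n) {
      cj <- g[j]
      if (cj == 1L) {
        if (het + 1L > max_het) break
        het <- het + 1L
      } else if (cj == -1L) {
        if (miss + 1L > max_missing) break
        miss <- miss + 1L
      }
      j <- j + 1L
    }
    j <- j - 1L
    if (j < i) {           # marker i alone exceeds the budget
      i <- i + 1L
      next
    }
    from <- c(from, i)
    to <- c(to, j)
    i <- j + 1L
  }
  data.frame(from = from, to = to)
}

#' Shared loss-of-heterozygosity across affected vs unaffected siblings
#'
#' Per-base intersection of all affected samples' ROH sets, minus the
#' union of all unaffected samples' ROH sets; residual pieces shorter
#' than `min_shared_bp` are dropped. This encodes "homozygous in every
#' affected sibling and not homozygous in any unaffected sibling" (the
#' strictest reading; set `mode = "all"` to subtract only regions
#' homozygous in *all* unaffected siblings).
#'
#' @param roh_by_sample named list of ROH segment data.frames (one per
#'   sample, as from [detect_roh()]).
#' @param affected_ids,unaffected_ids sample id vectors; all must be
#'   names of `roh_by_sample`.
#' @param min_shared_bp minimum length of a reported shared region.
#' @param mode `"any"` (default: subtract the union of unaffected ROH)
#'   or `"all"` (subtract only their intersection).
#' @return sorted, disjoint segment `data.frame` with `sample_id = NA`.
#' @export
shared_loh <- function(roh_by_sample, affected_ids, unaffected_ids = character(),
                       min_shared_bp = 0, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (length(affected_ids) == 0)
    stop("at least one affected sample is required", call. = FALSE)
  missing_ids <- setdiff(c(affected_ids, unaffected_ids), names(roh_by_sample))
  if (length(missing_ids))
    stop("no ROH set for sample(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  levels <- unique(unlist(lapply(roh_by_sample[c(affected_ids, unaffected_ids)],
                                 function(x) x$chrom)))
  if (!length(levels)) return(segments())
  as_gr <- function(x) {
    gr <- GenomicRanges::reduce(segments_to_granges(x))
    GenomeInfoDb::seqlevels(gr) <- levels
    gr
  }
  shared <- Reduce(GenomicRanges::intersect,
                   lapply(roh_by_sample[affected_ids], as_gr))
  if (length(unaffected_ids)) {
    un <- lapply(roh_by_sample[unaffected_ids], as_gr)
    un_comb <- if (mode == "any") {
      GenomicRanges::reduce(do.call(c, unname(un)))
    } else {
      Reduce(GenomicRanges::intersect, un)
    }
    shared <- GenomicRanges::setdiff(shared, un_comb)
  }
  shared <- shared[GenomicRanges::width(shared) >= min_shared_bp]
  granges_to_segments(shared)
}

#' Merge segments separated by small gaps
#'
#' Segments on one track whose gap is at most `max_gap_bp` are unioned;
#' used to recover the continuity of autozygous regions that array-based
#' LOH calls fragment. Idempotent.
#'
#' @param x segment data.frame on a single track (at most one distinct
#'   `sample_id`).
#' @param max_gap_bp non-negative gap tolerance in bp; 0 merges only
#'   touching/overlapping segments.
#' @return merged, sorted segment data.frame. `n_markers` is summed over
#'   merged members when all are known, otherwise `NA`.
#' @export
merge_segments <- function(x, max_gap_bp = 0) {
  if (!is.numeric(max_gap_bp) || max_gap_bp < 0)
    stop("max_gap_bp must be non-negative", call. = FALSE)
  validate_segments(x)
  if (nrow(x) == 0) return(segments())
  sid <- unique(x$sample_id)
  if (length(sid) > 1)
    stop("merge_segments expects segments of a single sample/track",
         call. = FALSE)
  gr <- segments_to_granges(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap_bp + 1,
                               with.revmap = TRUE)
  nm <- vapply(S4Vectors::mcols(red)$revmap, function(ii) {
    v <- x$n_markers[ii]
    if (any(is.na(v))) NA_real_ else sum(v)
  }, numeric(1))
  out <- granges_to_segments(red, sample_id = sid)
  out$n_markers <- nm
  out
}

#' Windowed average heterozygosity along a chromosome arm
#'
#' Assigns a sample's variant calls to consecutive fixed-width windows
#' anchored at the region start (the last window is truncated at the
#' region end) and computes per-window average heterozygosity
#' `n_het / (n_het + n_hom)`, where `n_het` counts heterozygous (code 1)
#' and `n_hom` homozygous-alternate (code 2) calls. Homozygous-reference
#' sites do not enter the denominator (variant-only calls); windows with
#' no variant calls have `avg_het = NA`, not 0.
#'
#' @param variants a variant table (see [read_vcf_subset()]).
#' @param sample_id sample whose genotypes are tallied.
#' @param window_bp window width in bp (default 100000).
#' @param region list with `chrom`, `start`, `end` (1-based inclusive,
#'   e.g. a chromosome arm).
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_het`, `n_hom`, `avg_het`.
#' @export
window_heterozygosity <- function(variants, sample_id, window_bp = 1e5,
                                  region) {
  if (!is.numeric(window_bp) || window_bp <= 0)
    stop("window_bp must be positive", call. = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  validate_variants(variants)
  gt_col <- paste0("gt_", sample_id)
  if (!gt_col %in% names(variants))
    stop("no genotypes for sample ", sample_id, call. = FALSE)
  rg <- internal_coords(region$start, region$end)
  span <- rg$end - rg$start
  n_win <- ceiling(span / window_bp)
  win_start <- rg$start + (seq_len(n_win) - 1) * window_bp
  win_end <- pmin(win_start + window_bp, rg$end)
  sel <- variants$chrom == region$chrom &
    variants$pos >= region$start & variants$pos <= region$end
  code <- variants[[gt_col]][sel]
  widx <- floor((variants$pos[sel] - 1 - rg$start) / window_bp) + 1
  n_het <- tabulate(widx[code == 1], nbins = n_win)
  n_hom <- tabulate(widx[code == 2], nbins = n_win)
  denom <- n_het + n_hom
  data.frame(chrom = region$chrom, start = win_start, end = win_end,
             n_het = n_het, n_hom = n_hom,
             avg_het = ifelse(denom > 0, n_het / denom, NA_real_),
             stringsAsFactors = FALSE)
}
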