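#' Construct a dense genotype panel
#'
#' A genotype panel holds per-sample genotype codes at an ordered set of
#' markers, the input to run-of-homozygosity detection. Codes are
#' `0` hom-ref, `1` het, `2` hom-alt, `-1` missing.
#'
#' @param markers data.frame with columns `chrom`, `pos` (1-based) and
#'   `marker_id`; must be strictly sorted by `(chrom, pos)`.
#' @param samples character vector of sample ids.
#' @param calls integer matrix, `nrow(markers)` x `length(samples)`,
#'   entries in `{-1, 0, 1, 2}`.
#' @return list of class `"genotype_panel"` with elements `markers`,
#'   `samples`, `calls`.
#' @export
genotype_panel <- function(markers, samples, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(markers$marker_id, samples)
  panel <- structure(list(markers = markers, samples = samples, calls = calls),
                     class = "genotype_panel")
  validate_panel(panel)
  panel
}

#' Validate a genotype panel
#' @param panel a `genotype_panel`.
#' @return `panel`, invisibly, or an error.
#' @export
validate_panel <- function(panel) {
  m <- panel$markers
  stopifnot(is.data.frame(m),
            all(c("chrom", "pos", "marker_id") %in% names(m)))
  if (nrow(m)) {
    o <- order(m$chrom, m$pos)
    if (!identical(o, seq_len(nrow(m))))
      stop("panel markers must be sorted by (chrom, pos)", call. = FALSE)
    dup <- duplicated(m[c("chrom", "pos")])
    if (any(dup))
      stop("panel markers must be strictly sorted: duplicate position at ",
           m$marker_id[dup][1], call. = FALSE)
  }
  if (!identical(dim(panel$calls), c(nrow(m), length(panel$samples))))
    stop("calls matrix must be |markers| x |samples|", call. = FALSE)
  if (length(panel$calls) && !all(panel$calls %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype codes must be in {-1, 0, 1, 2}", call. = FALSE)
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d markers x %d samples on %d chromosome(s)\n",
              nrow(x$markers), length(x$samples),
              length(unique(x$markers$chrom))))
  invisible(x)
}

panel_sample_calls <- function(panel, sample_id) {
  j <- match(sample_id, panel$samples)
  if (is.na(j)) stop("unknown sample in panel: ", sample_id, call. = FALSE)
  panel$calls[, j]
}
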