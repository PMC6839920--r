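# Independent oracles used across the suite. These recompute results by
# brute force (explicit enumeration, per-base set algebra, single-locus
# Monte-Carlo gene dropping) and never share code with the implementation
# paths they check.

# ROH oracle: enumerate every marker sub-run satisfying the het/missing
# budget, select greedily (leftmost start, longest extension), then apply
# the size filters. O(n^2) enumeration with naive counting.
oracle_roh_runs <- function(g, max_het, max_missing) {
  n <- length(g)
  sat_from <- integer()
  sat_to <- integer()
  for (i in seq_len(n)) {
    het <- 0L
    miss <- 0L
    for (j in i:n) {
      if (g[j] == 1L) het <- het + 1L
      if (g[j] == -1L) miss <- miss + 1L
      if (het > max_het || miss > max_missing) break
      sat_from <- c(sat_from, i)
      sat_to <- c(sat_to, j)
    }
  }
  if (!length(sat_from)) return(data.frame(from = integer(), to = integer()))
  out_from <- integer()
  out_to <- integer()
  lo <- 1L
  repeat {
    ok <- sat_from >= lo
    if (!any(ok)) break
    s <- min(sat_from[ok])
    e <- max(sat_to[ok & sat_from == s])
    out_from <- c(out_from, s)
    out_to <- c(out_to, e)
    lo <- e + 1L
  }
  data.frame(from = out_from, to = out_to)
}

oracle_detect_roh <- function(panel, sample_id, params) {
  j <- match(sample_id, panel$samples)
  res <- list()
  for (chr in unique(panel$markers$chrom)) {
    rows <- which(panel$markers$chrom == chr)
    runs <- oracle_roh_runs(panel$calls[rows, j],
                            params$max_het, params$max_missing)
    if (!nrow(runs)) next
    pos <- panel$markers$pos[rows]
    nm <- runs$to - runs$from + 1
    span <- pos[runs$to] - pos[runs$from] + 1
    keep <- nm >= params$min_markers & span >= params$min_length_bp
    if (!any(keep)) next
    res[[chr]] <- data.frame(chrom = chr,
                             start = pos[runs$from][keep] - 1,
                             end = pos[runs$to][keep],
                             n_markers = nm[keep])
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_markers = numeric()))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base set-algebra oracle for shared LOH on a single chromosome of
# size N bp (positions 0 .. N-1)
oracle_shared_loh <- function(roh_by_sample, aff, unaff, N, min_shared_bp = 0) {
  member <- function(segs) {
    v <- logical(N)
    for (r in seq_len(nrow(segs))) {
      v[(segs$start[r] + 1):segs$end[r]] <- TRUE
    }
    v
  }
  sh <- Reduce(`&`, lapply(roh_by_sample[aff], member))
  if (length(unaff))
    sh <- sh & !Reduce(`|`, lapply(roh_by_sample[unaff], member))
  r <- rle(sh)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_shared_bp
  data.frame(start = starts[keep], end = ends[keep])
}

# single-locus Monte-Carlo gene-dropping estimate of the inbreeding
# coefficient (probability the two transmitted alleles are IBD)
mc_inbreeding <- function(ped, individual, n = 2e5, seed = 99) {
  set.seed(seed)
  alleles <- list()
  remaining <- ped$sample_id
  done <- character()
  lab <- 0
  while (length(remaining)) {
    idx <- match(remaining, ped$sample_id)
    ok <- (is.na(ped$father_id[idx]) | ped$father_id[idx] %in% done) &
      (is.na(ped$mother_id[idx]) | ped$mother_id[idx] %in% done)
    for (id in remaining[ok]) {
      i <- match(id, ped$sample_id)
      if (is.na(ped$father_id[i])) {
        alleles[[id]] <- rbind(rep(lab + 1, n), rep(lab + 2, n))
        lab <- lab + 2
      } else {
        gam <- function(par) {
          a <- alleles[[par]]
          a[cbind(sample(1:2, n, replace = TRUE), seq_len(n))]
        }
        alleles[[id]] <- rbind(gam(ped$father_id[i]), gam(ped$mother_id[i]))
      }
    }
    done <- c(done, remaining[ok])
    remaining <- remaining[!ok]
  }
  a <- alleles[[individual]]
  mean(a[1, ] == a[2, ])
}
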