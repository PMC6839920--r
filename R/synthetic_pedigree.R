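## Gene-dropping simulator for a consanguineous nuclear family.
##
## Founder chromosomes carry unique haplotype labels; each meiosis places
## crossovers as a Poisson process (Haldane model, no interference) and
## transmits a mosaic of the parent's two haplotypes. Autozygous tracts
## are the maximal intervals where an offspring's two haplotype labels
## coincide, which gives every downstream stage an exact ground truth.

#' Simulation configuration
#'
#' @param pedigree_template `"first_cousin_parents"` (default: the two
#'   parents share one grandparental couple) or `"custom"` (supply
#'   `custom_pedigree`).
#' @param n_affected,n_unaffected offspring counts (defaults 3 and 2, the
#'   three-probands/two-siblings family structure).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   default `c(chr6 = 60e6, chr12 = 40e6)`, a 100 Mb two-chromosome
#'   genome.
#' @param marker_density genotyping markers per Mb (default 100, the
#'   density of a genome-wide tag-SNP array).
#' @param background_variant_rate coding/background variants per Mb
#'   emitted into the VCF (default 1).
#' @param causal_variant_spec list describing the planted recessive
#'   variant: `chrom`, `pos` (1-based), `ref`, `alt`, `gene`,
#'   `consequence`, `cds_pos`, `protein_pos`, `pop_afs` (named vector,
#'   all `< 0.01`).
#' @param recomb_rate Morgans per Mb (default 0.01, the genome-average
#'   1 cM/Mb).
#' @param genotyping_error_rate per-call error probability applied to the
#'   marker panel (default 0.001, a typical array discordance rate).
#' @param seed integer seed; mandatory for any stochastic call.
#' @param custom_pedigree a [pedigree()] when `pedigree_template` is
#'   `"custom"`.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(pedigree_template = "first_cousin_parents",
                       n_affected = 3, n_unaffected = 2,
                       chrom_lengths = c(chr6 = 60e6, chr12 = 40e6),
                       marker_density = 100,
                       background_variant_rate = 1,
                       causal_variant_spec = default_causal_spec(),
                       recomb_rate = 0.01,
                       genotyping_error_rate = 0.001,
                       seed = NULL,
                       custom_pedigree = NULL) {
  cfg <- list(pedigree_template = pedigree_template,
              n_affected = n_affected, n_unaffected = n_unaffected,
              chrom_lengths = chrom_lengths,
              marker_density = marker_density,
              background_variant_rate = background_variant_rate,
              causal_variant_spec = causal_variant_spec,
              recomb_rate = recomb_rate,
              genotyping_error_rate = genotyping_error_rate,
              seed = seed, custom_pedigree = custom_pedigree)
  if (any(c(marker_density, background_variant_rate, recomb_rate,
            genotyping_error_rate) < 0))
    stop("all rates must be non-negative", call. = FALSE)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths",
         call. = FALSE)
  if (!is.null(causal_variant_spec) && n_affected < 1)
    stop("at least one affected offspring is required to plant a causal variant",
         call. = FALSE)
  if (!is.null(causal_variant_spec) &&
      any(causal_variant_spec$pop_afs >= 0.01))
    stop("planted causal variant must be rare (all pop_afs < 0.01)",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Default planted causal variant: a rare homozygous missense change
#' @return spec list, see [sim_config()].
#' @export
default_causal_spec <- function() {
  list(chrom = "chr6", pos = 25e6, ref = "G", alt = "A",
       gene = "GENE_CAUSAL", consequence = "missense",
       cds_pos = 230, protein_pos = 77,
       pop_afs = c(ExAC = 0.00014, `1KG` = 0, TOPMED = 0.0002))
}

#' Build the looped (consanguineous) pedigree of the default template
#'
#' The first-cousin template: a shared grandparental couple, two of their
#' children who marry unrelated founders, the two parents (first
#' cousins), and `n_affected + n_unaffected` offspring — 13 individuals
#' for the default 3 + 2 family. Offspring of first cousins have
#' inbreeding coefficient 1/16.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()].
#' @export
build_looped_pedigree <- function(config) {
  if (config$pedigree_template == "custom") {
    if (is.null(config$custom_pedigree))
      stop("custom template requires custom_pedigree", call. = FALSE)
    return(validate_pedigree(config$custom_pedigree))
  }
  off_aff <- if (config$n_affected) paste0("P", seq_len(config$n_affected)) else character()
  off_un <- if (config$n_unaffected) paste0("S", seq_len(config$n_unaffected)) else character()
  off <- c(off_aff, off_un)
  pedigree(
    sample_id = c("GGP1", "GGP2", "GP1", "GP1S", "GP2", "GP2S",
                  "FATHER", "MOTHER", off),
    father_id = c(NA, NA, "GGP1", NA, "GGP1", NA,
                  "GP1", "GP2S", rep("FATHER", length(off))),
    mother_id = c(NA, NA, "GGP2", NA, "GGP2", NA,
                  "GP1S", "GP2", rep("MOTHER", length(off))),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female",
            rep(c("male", "female"), length.out = length(off))),
    affected = c(rep("unknown", 6), "unaffected", "unaffected",
                 rep("affected", length(off_aff)),
                 rep("unaffected", length(off_un))),
    family_id = "SIMFAM"
  )
}

## ---- haplotype machinery ------------------------------------------------

## a haplotype on one chromosome is a matrix with columns start, end,
## label (0-based half-open tiling of [0, L))
founder_hap <- function(L, label) matrix(c(0, L, label), nrow = 1,
                                         dimnames = list(NULL, c("start", "end", "label")))

slice_hap <- function(hap, s, e) {
  keep <- hap[, 2] > s & hap[, 1] < e
  out <- hap[keep, , drop = FALSE]
  out[1, 1] <- max(out[1, 1], s)
  out[nrow(out), 2] <- min(out[nrow(out), 2], e)
  out
}

simplify_hap <- function(hap) {
  if (nrow(hap) < 2) return(hap)
  keep <- c(TRUE, hap[-1, 3] != hap[-nrow(hap), 3])
  starts <- hap[keep, 1]
  grp <- cumsum(keep)
  ends <- vapply(split(hap[, 2], grp), max, numeric(1))
  cbind(start = starts, end = unname(ends), label = hap[keep, 3])
}

## one meiosis on one chromosome: Poisson(recomb_rate * L/1e6) crossovers
meiosis_chrom <- function(hap1, hap2, L, recomb_rate) {
  n_co <- stats::rpois(1, recomb_rate * L / 1e6)
  breaks <- sort(stats::runif(n_co, 0, L))
  phase <- sample(1:2, 1)
  bounds <- c(0, breaks, L)
  pieces <- vector("list", length(bounds) - 1)
  src <- list(hap1, hap2)
  for (k in seq_len(length(bounds) - 1)) {
    pieces[[k]] <- slice_hap(src[[phase]], bounds[k], bounds[k + 1])
    phase <- 3 - phase
  }
  simplify_hap(do.call(rbind, pieces))
}

meiosis <- function(haps, chrom_lengths, recomb_rate) {
  out <- list()
  for (chr in names(chrom_lengths)) {
    out[[chr]] <- meiosis_chrom(haps$pat[[chr]], haps$mat[[chr]],
                                chrom_lengths[[chr]], recomb_rate)
  }
  out
}

hap_label_at <- function(hap, pos0) {
  hap[findInterval(pos0, hap[, 1]), 3]
}

## autozygous tracts: intervals where the two haplotype labels coincide
autozygous_tracts_chrom <- function(pat, mat) {
  cuts <- sort(unique(c(pat[, 1], mat[, 1], pat[nrow(pat), 2])))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  lp <- hap_label_at(pat, starts)
  lm <- hap_label_at(mat, starts)
  same <- lp == lm
  if (!any(same)) return(NULL)
  d <- cbind(start = starts[same], end = ends[same], label = lp[same])
  ## merge adjacent identical-label pieces
  if (nrow(d) > 1) {
    glue <- c(FALSE, d[-1, 1] == d[-nrow(d), 2] & d[-1, 3] == d[-nrow(d), 3])
    grp <- cumsum(!glue)
    d <- cbind(start = vapply(split(d[, 1], grp), min, numeric(1)),
               end = vapply(split(d[, 2], grp), max, numeric(1)),
               label = d[!glue, 3])
  }
  d
}

## ---- gene dropping ------------------------------------------------------

#' Drop founder haplotypes through the pedigree
#'
#' Assigns two uniquely labelled haplotypes to every founder, simulates
#' every meiosis with Poisson crossovers, genotypes all members at a
#' random marker grid (marker alt-allele frequencies drawn uniform on
#' (0.05, 0.5) so heterozygosity carries signal), emits background
#' variants whose genotypes follow the same transmitted haplotypes, and
#' records the exact autozygous tracts of every offspring as ground
#' truth. Deterministic given `seed`.
#'
#' @param ped a [pedigree()] (e.g. [build_looped_pedigree()]).
#' @param config a [sim_config()].
#' @param seed integer; overrides `config$seed`.
#' @return list with elements `panel` ([genotype_panel()] over parents
#'   and offspring), `variants` (variant table), `truth` (list:
#'   `autozygous_segments` with per-offspring tracts and founder-label
#'   column, `founder_haplotypes`, later `causal_variant`), `pedigree`,
#'   `config`.
#' @export
gene_drop <- function(ped, config, seed = config$seed) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  validate_pedigree(ped)
  set.seed(seed)
  chrs <- config$chrom_lengths

  ## topological order
  order_ids <- character()
  remaining <- ped$sample_id
  while (length(remaining)) {
    idx <- match(remaining, ped$sample_id)
    ok <- (is.na(ped$father_id[idx]) | ped$father_id[idx] %in% order_ids) &
      (is.na(ped$mother_id[idx]) | ped$mother_id[idx] %in% order_ids)
    order_ids <- c(order_ids, remaining[ok])
    remaining <- remaining[!ok]
  }

  founders <- founder_ids(ped)
  haps <- list()
  label <- 0
  founder_labels <- list()
  for (id in order_ids) {
    row <- ped_row(ped, id)
    if (is.na(row$father_id)) {
      h <- list(pat = list(), mat = list())
      for (chr in names(chrs)) {
        h$pat[[chr]] <- founder_hap(chrs[[chr]], label + 1)
        h$mat[[chr]] <- founder_hap(chrs[[chr]], label + 2)
      }
      founder_labels[[id]] <- c(label + 1, label + 2)
      label <- label + 2
      haps[[id]] <- h
    } else {
      haps[[id]] <- list(
        pat = meiosis(haps[[row$father_id]], chrs, config$recomb_rate),
        mat = meiosis(haps[[row$mother_id]], chrs, config$recomb_rate)
      )
    }
  }

  offspring <- offspring_ids(ped)
  parents <- unique(c(ped$father_id[ped$sample_id %in% offspring],
                      ped$mother_id[ped$sample_id %in% offspring]))
  genotyped <- c(parents, offspring)

  ## ground truth autozygous tracts per offspring
  truth_segs <- list()
  for (id in offspring) {
    for (chr in names(chrs)) {
      d <- autozygous_tracts_chrom(haps[[id]]$pat[[chr]], haps[[id]]$mat[[chr]])
      if (!is.null(d)) {
        seg <- segments(chrom = chr, start = d[, 1], end = d[, 2],
                        sample_id = id)
        seg$label <- d[, 3]
        truth_segs[[length(truth_segs) + 1]] <- seg
      }
    }
  }
  truth_segs <- if (length(truth_segs)) {
    sort_segments(do.call(rbind, truth_segs))
  } else {
    cbind(segments(), label = numeric())
  }

  n_labels <- label

  ## marker panel
  panel <- NULL
  if (config$marker_density > 0) {
    mk <- list()
    for (chr in names(chrs)) {
      n_mk <- max(1, round(config$marker_density * chrs[[chr]] / 1e6))
      pos <- sort(sample.int(chrs[[chr]], n_mk))
      mk[[chr]] <- data.frame(chrom = chr, pos = as.numeric(pos),
                              marker_id = sprintf("%s_m%06d", chr,
                                                  seq_len(n_mk)),
                              stringsAsFactors = FALSE)
    }
    mk <- do.call(rbind, mk)
    mk <- mk[order(mk$chrom, mk$pos), , drop = FALSE]
    rownames(mk) <- NULL
    p_alt <- stats::runif(nrow(mk), 0.05, 0.5)
    hap_alleles <- matrix(stats::rbinom(nrow(mk) * n_labels, 1, p_alt),
                          nrow = nrow(mk), ncol = n_labels)
    calls <- matrix(0L, nrow = nrow(mk), ncol = length(genotyped))
    for (j in seq_along(genotyped)) {
      id <- genotyped[j]
      code <- integer(nrow(mk))
      for (chr in names(chrs)) {
        rows <- which(mk$chrom == chr)
        pos0 <- mk$pos[rows] - 1
        lp <- hap_label_at(haps[[id]]$pat[[chr]], pos0)
        lm <- hap_label_at(haps[[id]]$mat[[chr]], pos0)
        code[rows] <- hap_alleles[cbind(rows, lp)] + hap_alleles[cbind(rows, lm)]
      }
      calls[, j] <- code
    }
    panel <- genotype_panel(mk, genotyped, calls)
  } else {
    panel <- genotype_panel(
      data.frame(chrom = character(), pos = numeric(),
                 marker_id = character(), stringsAsFactors = FALSE),
      genotyped, matrix(integer(), 0, length(genotyped)))
  }

  ## background variants with transmission-consistent genotypes
  variants <- simulate_background_variants(config, haps, genotyped, n_labels)

  list(panel = panel, variants = variants,
       truth = list(autozygous_segments = truth_segs,
                    founder_haplotypes = founder_labels,
                    causal_variant = NULL),
       pedigree = ped, config = config, haps = haps)
}

simulate_background_variants <- function(config, haps, genotyped, n_labels) {
  chrs <- config$chrom_lengths
  total_mb <- sum(chrs) / 1e6
  dbs <- names(default_info_map()$pop_afs)
  n_bg <- stats::rpois(1, config$background_variant_rate * total_mb)
  out <- empty_variant_table(default_info_map(), genotyped)
  if (n_bg == 0) return(out)
  chrom <- sample(names(chrs), n_bg, replace = TRUE,
                  prob = chrs / sum(chrs))
  pos <- vapply(chrom, function(ch) sample.int(chrs[[ch]], 1), numeric(1))
  csq_levels <- c("missense", "synonymous", "intronic", "stop_gained",
                  "frameshift", "splice_acceptor", "splice_donor", "other")
  csq <- sample(csq_levels, n_bg, replace = TRUE,
                prob = c(0.30, 0.25, 0.28, 0.02, 0.03, 0.02, 0.02, 0.08))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_bg, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  is_rare <- stats::runif(n_bg) < 0.5
  rows <- vector("list", n_bg)
  for (i in seq_len(n_bg)) {
    if (is_rare[i]) {
      carrier <- sample.int(n_labels, 1)
      hap_has_alt <- seq_len(n_labels) == carrier
      afs <- 10^stats::runif(length(dbs), -5, log10(0.005))
    } else {
      af_true <- stats::runif(1, 0.01, 0.4)
      hap_has_alt <- stats::runif(n_labels) < af_true
      afs <- pmin(1, af_true * stats::runif(length(dbs), 0.8, 1.2))
    }
    if (stats::runif(1) < 0.1) afs[sample.int(length(dbs), 1)] <- NA
    gts <- vapply(genotyped, function(id) {
      lp <- hap_label_at(haps[[id]]$pat[[chrom[i]]], pos[i] - 1)
      lm <- hap_label_at(haps[[id]]$mat[[chrom[i]]], pos[i] - 1)
      as.integer(hap_has_alt[lp] + hap_has_alt[lm])
    }, integer(1))
    coding <- csq[i] %in% c("missense", "synonymous", "stop_gained",
                            "frameshift", "splice_acceptor", "splice_donor")
    rows[[i]] <- c(
      list(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
           gene = sprintf("GENE_%s_%07d", chrom[i], round(pos[i] / 100)),
           consequence = csq[i],
           cds_pos = if (coding) sample.int(1500, 1) else NA_real_,
           protein_pos = if (coding) sample.int(500, 1) else NA_real_),
      stats::setNames(as.list(afs), paste0("af_", dbs)),
      stats::setNames(as.list(gts), paste0("gt_", genotyped)))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  ## keep only variants actually seen in the family (variant-only VCF)
  out <- out[rowSums(variant_genotypes(out) > 0) > 0, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plant the causal recessive variant inside shared autozygosity
#'
#' Finds the tracts where every affected offspring is autozygous for the
#' same founder haplotype and no unaffected offspring is autozygous for
#' it, places the configured variant there (relocating from the
#' requested position to the nearest such tract when necessary, and
#' recording the move), and derives all genotypes from the transmitted
#' haplotypes: affected offspring are hom-alt, both parents are
#' heterozygous carriers, unaffected offspring are het or hom-ref.
#'
#' @param dataset output of [gene_drop()].
#' @param spec causal variant spec (see [sim_config()]); defaults to the
#'   dataset config's.
#' @return the dataset with the variant appended to `variants` and
#'   recorded in `truth$causal_variant` (plus `truth$causal_moved`).
#' @export
plant_causal_variant <- function(dataset, spec = dataset$config$causal_variant_spec) {
  ped <- dataset$pedigree
  aff <- affected_ids(ped)
  unaff <- intersect(unaffected_ids(ped), offspring_ids(ped))
  if (!length(aff))
    stop("cannot plant a causal variant without affected offspring",
         call. = FALSE)
  cand <- shared_label_tracts(dataset$truth$autozygous_segments, aff, unaff)
  if (nrow(cand) == 0)
    stop("no tract is autozygous for one founder haplotype in all affected ",
         "offspring (and non-autozygous in all unaffected): re-run the ",
         "generator with a different seed", call. = FALSE)
  inside <- cand$chrom == spec$chrom &
    cand$start < spec$pos & spec$pos <= cand$end
  if (any(inside)) {
    hit <- cand[which(inside)[1], ]
    pos <- spec$pos
    moved <- FALSE
  } else {
    mid <- (cand$start + cand$end) / 2
    dist <- ifelse(cand$chrom == spec$chrom, abs(mid - spec$pos),
                   Inf)
    hit <- if (all(is.infinite(dist))) {
      cand[which.max(cand$end - cand$start), ]
    } else {
      cand[which.min(dist), ]
    }
    pos <- floor((hit$start + hit$end) / 2) + 1
    moved <- TRUE
  }
  lab <- hit$label
  samples <- variant_samples(dataset$variants)
  gts <- vapply(samples, function(id) {
    lp <- hap_label_at_sample(dataset, id, hit$chrom, pos - 1, "pat")
    lm <- hap_label_at_sample(dataset, id, hit$chrom, pos - 1, "mat")
    as.integer((lp == lab) + (lm == lab))
  }, integer(1))
  parents <- c(ped$father_id[match(aff[1], ped$sample_id)],
               ped$mother_id[match(aff[1], ped$sample_id)])
  stopifnot(all(gts[aff] == 2L), all(gts[parents] == 1L),
            all(gts[unaff] <= 1L))
  row <- c(list(chrom = hit$chrom, pos = pos, ref = spec$ref,
                alt = spec$alt, gene = spec$gene,
                consequence = spec$consequence,
                cds_pos = spec$cds_pos, protein_pos = spec$protein_pos),
           stats::setNames(as.list(spec$pop_afs),
                           paste0("af_", names(spec$pop_afs))),
           stats::setNames(as.list(gts), paste0("gt_", samples)))
  row <- as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  v <- rbind(dataset$variants[names(row)], row)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  dataset$variants <- v
  dataset$truth$causal_variant <- row
  dataset$truth$causal_moved <- moved
  dataset
}

## haplotypes are kept alongside the dataset for planting; gene_drop
## stores them in an environment to avoid deep copies
hap_label_at_sample <- function(dataset, id, chrom, pos0, side) {
  hap_label_at(dataset$haps[[id]][[side]][[chrom]], pos0)
}

## tracts autozygous for one founder label in all affected and for that
## label in no unaffected offspring
shared_label_tracts <- function(truth_segs, aff, unaff) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(truth_segs) == 0) return(empty)
  labels <- sort(unique(truth_segs$label[truth_segs$sample_id %in% aff]))
  out <- list()
  levels <- unique(truth_segs$chrom)
  as_gr <- function(x) {
    gr <- if (nrow(x) == 0) GenomicRanges::GRanges() else segments_to_granges(x)
    GenomeInfoDb::seqlevels(gr) <- levels
    gr
  }
  for (lab in labels) {
    per_aff <- lapply(aff, function(id)
      as_gr(truth_segs[truth_segs$sample_id == id & truth_segs$label == lab, ]))
    shared <- Reduce(GenomicRanges::intersect, per_aff)
    if (!length(shared)) next
    if (length(unaff)) {
      un <- as_gr(truth_segs[truth_segs$sample_id %in% unaff &
                               truth_segs$label == lab, ])
      shared <- GenomicRanges::setdiff(shared, GenomicRanges::reduce(un))
    }
    if (!length(shared)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(shared)),
      start = GenomicRanges::start(shared) - 1,
      end = as.numeric(GenomicRanges::end(shared)),
      label = lab, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Inject genotyping error into a marker panel
#'
#' Each non-missing call is independently replaced, with probability
#' `rate`, by a uniformly chosen different code among `{0, 1, 2}`.
#' Missing calls stay missing (an array no-call is not re-called), and
#' the causal variant lives in the variant table, not the panel, so it
#' is exempt by construction.
#'
#' @param panel a [genotype_panel()].
#' @param rate per-call error probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the corrupted panel.
#' @export
inject_genotyping_error <- function(panel, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("error rate must lie in [0, 1)", call. = FALSE)
  validate_panel(panel)
  if (rate == 0 || !length(panel$calls)) return(panel)
  set.seed(seed)
  hit <- which(panel$calls != -1L &
                 stats::runif(length(panel$calls)) < rate)
  if (length(hit)) {
    cur <- panel$calls[hit]
    panel$calls[hit] <- (cur + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  panel
}

#' Simulate a complete dataset with planted ground truth
#'
#' Convenience wrapper: [build_looped_pedigree()], [gene_drop()],
#' [plant_causal_variant()], [inject_genotyping_error()] on the panel.
#' Ground truth (autozygous tracts, causal genotypes) is recorded before
#' error injection. Errors if the replicate has no tract autozygous in
#' all affected offspring (a minority of replicates at the default 100 Mb
#' genome scale); see [find_valid_seed()] for the deterministic reseed
#' loop.
#'
#' @param config a [sim_config()].
#' @param seed integer; overrides `config$seed`.
#' @return dataset list: `pedigree`, `panel`, `variants`, `truth`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  ped <- build_looped_pedigree(config)
  ds <- gene_drop(ped, config, seed = seed)
  if (!is.null(config$causal_variant_spec))
    ds <- plant_causal_variant(ds)
  ds$truth$n_confounders <- count_confounders(ds)
  if (config$genotyping_error_rate > 0)
    ds$panel <- inject_genotyping_error(ds$panel,
                                        config$genotyping_error_rate,
                                        seed = seed + 1L)
  ds$seed <- seed
  ds
}

## background variants that coincidentally satisfy the full recessive
## cascade (functional, rare everywhere, affected hom-alt, unaffected
## at most het); the planted variant is excluded
count_confounders <- function(ds) {
  v <- ds$variants
  if (nrow(v) == 0) return(0L)
  if (!is.null(ds$truth$causal_variant)) {
    cv <- ds$truth$causal_variant
    v <- v[!(v$chrom == cv$chrom & v$pos == cv$pos &
               v$ref == cv$ref & v$alt == cv$alt), , drop = FALSE]
  }
  if (nrow(v) == 0) return(0L)
  cfg <- cascade_config()
  fun <- v$consequence %in% cfg$functional_classes
  af <- as.matrix(v[paste0("af_", intersect(cfg$databases,
                                            variant_databases(v)))])
  rare <- apply(af, 1, function(a) all(is.na(a) | a < cfg$max_maf))
  aff <- affected_ids(ds$pedigree)
  unaff <- intersect(unaffected_ids(ds$pedigree), offspring_ids(ds$pedigree))
  gt <- variant_genotypes(v)
  pat <- apply(gt[, aff, drop = FALSE] == 2L, 1, all) &
    apply(gt[, unaff, drop = FALSE] <= 1L &
            gt[, unaff, drop = FALSE] >= 0L, 1, all)
  sum(fun & rare & pat)
}

#' Deterministic reseed loop for a valid simulated replicate
#'
#' Scans `seed, seed + 1, ...` until [simulate_dataset()] yields a
#' replicate where the causal variant could be planted and, when
#' `require_unique`, no background variant coincidentally satisfies the
#' full recessive filter cascade (so ground truth confirms a unique
#' survivor).
#'
#' @param config a [sim_config()].
#' @param seed starting seed.
#' @param max_tries attempts before giving up.
#' @param require_unique demand `truth$n_confounders == 0`.
#' @return the first valid dataset (its `$seed` records the seed used).
#' @export
find_valid_seed <- function(config = sim_config(), seed = 1,
                            max_tries = 2000, require_unique = TRUE) {
  ## cheap probe: haplotypes are drawn first and identically for a given
  ## seed, so plantability can be checked without markers or variants
  probe_cfg <- config
  probe_cfg$marker_density <- 0
  probe_cfg$background_variant_rate <- 0
  probe_cfg$causal_variant_spec <- NULL
  probe_cfg$genotyping_error_rate <- 0
  ped <- build_looped_pedigree(config)
  aff <- affected_ids(ped)
  unaff <- intersect(unaffected_ids(ped), offspring_ids(ped))
  for (s in seq(seed, seed + max_tries - 1)) {
    probe <- gene_drop(ped, probe_cfg, seed = s)
    cand <- shared_label_tracts(probe$truth$autozygous_segments, aff, unaff)
    if (nrow(cand) == 0) next
    ds <- tryCatch(simulate_dataset(config, seed = s),
                   error = function(e) NULL)
    if (is.null(ds)) next
    if (require_unique && ds$truth$n_confounders > 0) next
    return(ds)
  }
  stop("no valid replicate found in ", max_tries, " seeds", call. = FALSE)
}
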