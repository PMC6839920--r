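#' Genotype counts from a carrier screen
#'
#' @param n_homref,n_het,n_homalt,n_missing non-negative integer tallies.
#' @return list of class `"genotype_counts"`.
#' @export
genotype_counts <- function(n_homref, n_het, n_homalt, n_missing = 0) {
  counts <- list(n_homref = n_homref, n_het = n_het,
                 n_homalt = n_homalt, n_missing = n_missing)
  if (any(unlist(counts) < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  structure(counts, class = "genotype_counts")
}

#' Sample allele frequency from genotype counts
#'
#' `(n_het + 2 * n_homalt) / (2 * n_typed)`, with missing genotypes
#' excluded from the denominator.
#'
#' @param counts a [genotype_counts()].
#' @return allele frequency in `[0, 1]`.
#' @examples
#' allele_frequency(genotype_counts(1999, 1, 0))  # 0.00025, i.e. 0.025%
#' @export
allele_frequency <- function(counts) {
  n_typed <- counts$n_homref + counts$n_het + counts$n_homalt
  if (n_typed <= 0)
    stop("no typed individuals: allele frequency undefined", call. = FALSE)
  (counts$n_het + 2 * counts$n_homalt) / (2 * n_typed)
}

#' Hardy-Weinberg expected genotype frequencies
#'
#' For alternate-allele frequency `q`, returns
#' `((1-q)^2, 2q(1-q), q^2)`; the components sum to 1.
#'
#' @param q allele frequency in `[0, 1]`.
#' @return list with `f_homref`, `f_het`, `f_homalt`.
#' @examples
#' hwe_expected(0.028)$f_homalt  # 0.000784: 0.08% homozygote prevalence
#' @export
hwe_expected <- function(q) {
  if (!is.finite(q) || q < 0 || q > 1)
    stop("allele frequency q must lie in [0, 1]", call. = FALSE)
  list(f_homref = (1 - q)^2, f_het = 2 * q * (1 - q), f_homalt = q^2)
}

#' Wright's inbreeding coefficient by path counting
#'
#' For individual X with parents P and Q,
#' `F = sum over common ancestors A and pairs of parent-to-ancestor paths
#' (disjoint except at A) of (1/2)^(n1 + n2 + 1) * (1 + F_A)`, where
#' `n1`, `n2` are the path lengths in meioses and `F_A` is the ancestor's
#' own inbreeding coefficient, computed recursively. Founders (and
#' offspring of unrelated parents) have `F = 0`.
#'
#' @param ped a [pedigree()].
#' @param individual sample id.
#' @return inbreeding coefficient in `[0, 1]`.
#' @examples
#' # offspring of first cousins: F = 1/16
#' @export
inbreeding_coefficient <- function(ped, individual) {
  validate_pedigree(ped)
  if (!individual %in% ped$sample_id)
    stop("unknown individual: ", individual, call. = FALSE)
  memo <- new.env(parent = emptyenv())
  f_of(ped, individual, memo)
}

f_of <- function(ped, id, memo) {
  if (!is.null(memo[[id]])) return(memo[[id]])
  row <- ped_row(ped, id)
  if (is.na(row$father_id)) {
    memo[[id]] <- 0
    return(0)
  }
  pf <- ancestor_paths(ped, row$father_id)
  pm <- ancestor_paths(ped, row$mother_id)
  common <- intersect(vapply(pf, utils::tail, character(1), n = 1),
                      vapply(pm, utils::tail, character(1), n = 1))
  f <- 0
  for (a in common) {
    pa <- pf[vapply(pf, function(p) utils::tail(p, 1) == a, logical(1))]
    pb <- pm[vapply(pm, function(p) utils::tail(p, 1) == a, logical(1))]
    for (p1 in pa) for (p2 in pb) {
      ## loop paths must be disjoint except at the common ancestor
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) == 0) {
        n1 <- length(p1) - 1
        n2 <- length(p2) - 1
        f <- f + 0.5^(n1 + n2 + 1) * (1 + f_of(ped, a, memo))
      }
    }
  }
  memo[[id]] <- f
  f
}

## all upward simple paths from id (including the trivial path c(id));
## each path is a vector of ids ending at an ancestor
ancestor_paths <- function(ped, id) {
  row <- ped_row(ped, id)
  out <- list(id)
  if (!is.na(row$father_id)) {
    out <- c(out,
             lapply(ancestor_paths(ped, row$father_id), function(p) c(id, p)),
             lapply(ancestor_paths(ped, row$mother_id), function(p) c(id, p)))
  }
  out
}

#' Summarise a cohort carrier screen at one variant
#'
#' Tallies genotype codes for a single variant across a screening panel
#' and formats the allele frequency in percent (the display convention
#' used for carrier screens, e.g. "0.025%").
#'
#' @param genotypes integer vector of codes in `{-1, 0, 1, 2}`, one per
#'   screened individual.
#' @return list with `counts` ([genotype_counts()]), `allele_freq`
#'   (fraction), `allele_freq_pct` (formatted string, 4 significant
#'   digits), `n_homalt`.
#' @examples
#' screen_summary(c(rep(0L, 1999), 1L))  # 1 het in 2000 -> "0.025%"
#' @export
screen_summary <- function(genotypes) {
  stopifnot(all(genotypes %in% c(-1L, 0L, 1L, 2L)))
  counts <- genotype_counts(sum(genotypes == 0), sum(genotypes == 1),
                            sum(genotypes == 2), sum(genotypes == -1))
  af <- allele_frequency(counts)
  list(counts = counts, allele_freq = af,
       allele_freq_pct = paste0(signif(af * 100, 4), "%"),
       n_homalt = counts$n_homalt)
}
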