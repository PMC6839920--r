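#' Configuration for the recessive-model filter cascade
#'
#' Encodes the discovery filter: exonic non-synonymous changes, minor
#' allele frequency strictly below `max_maf` in every configured
#' population database, homozygous-alternate in every affected sibling
#' and at most heterozygous in every unaffected sibling, optionally
#' restricted to shared-LOH regions.
#'
#' @param max_maf frequency ceiling, strict `<` (default 0.01).
#' @param databases database labels whose `af_<db>` columns are checked
#'   (default ExAC, 1KG, TOPMED).
#' @param functional_classes consequence classes that count as
#'   non-synonymous/deleterious; splice classes are included by default
#'   since splice-disrupting alleles are treated as potentially
#'   deleterious.
#' @param missing_af_policy `"treat_as_rare"` (absence from a database is
#'   evidence of rarity, the default) or `"fail"` (strict mode).
#' @param require_region_overlap restrict survivors to shared-LOH
#'   segments (default TRUE).
#' @param max_unaffected_code genotype ceiling for unaffected siblings
#'   (default 1 = at most heterozygous).
#' @param unannotated_policy `"fail"` (default) or `"pass"` for variants
#'   with no consequence annotation.
#' @return list of class `"cascade_config"`.
#' @export
cascade_config <- function(max_maf = 0.01,
                           databases = c("ExAC", "1KG", "TOPMED"),
                           functional_classes = c("missense", "stop_gained",
                                                  "stop_lost", "frameshift",
                                                  "inframe_indel",
                                                  "splice_acceptor",
                                                  "splice_donor", "start_lost"),
                           missing_af_policy = c("treat_as_rare", "fail"),
                           require_region_overlap = TRUE,
                           max_unaffected_code = 1,
                           unannotated_policy = c("fail", "pass")) {
  if (!is.numeric(max_maf) || max_maf <= 0 || max_maf > 1)
    stop("max_maf must lie in (0, 1]", call. = FALSE)
  structure(list(max_maf = max_maf, databases = databases,
                 functional_classes = functional_classes,
                 missing_af_policy = match.arg(missing_af_policy),
                 require_region_overlap = require_region_overlap,
                 max_unaffected_code = max_unaffected_code,
                 unannotated_policy = match.arg(unannotated_policy)),
            class = "cascade_config")
}

variant_key <- function(variants) {
  if (nrow(variants) == 0) return(character())
  paste(variants$chrom,
        format(variants$pos, scientific = FALSE, trim = TRUE, digits = 15),
        variants$ref, variants$alt, sep = ":")
}

new_trail <- function(variants, filter, pass, detail) {
  if (nrow(variants) == 0)
    return(data.frame(variant_key = character(), filter = character(),
                      verdict = character(), detail = character(),
                      stringsAsFactors = FALSE))
  data.frame(variant_key = variant_key(variants), filter = filter,
             verdict = ifelse(pass, "pass", "fail"), detail = detail,
             stringsAsFactors = FALSE)
}

filter_result <- function(variants, pass, filter, detail) {
  list(survivors = {
    s <- variants[pass, , drop = FALSE]
    rownames(s) <- NULL
    s
  }, trails = new_trail(variants, filter, pass, detail))
}

#' Keep exonic, non-synonymous (functional) variants
#'
#' @param variants a variant table.
#' @param config a [cascade_config()].
#' @return list with `survivors` (variant table) and `trails`
#'   (data.frame: `variant_key`, `filter`, `verdict`, `detail`).
#' @export
filter_functional <- function(variants, config = cascade_config()) {
  validate_variants(variants)
  csq <- variants$consequence
  annotated <- !is.na(csq) & nzchar(csq)
  pass <- annotated & csq %in% config$functional_classes
  if (config$unannotated_policy == "pass") pass <- pass | !annotated
  detail <- ifelse(!annotated, "unannotated",
                   ifelse(pass, paste0("consequence=", csq),
                          paste0("excluded class: ", csq)))
  filter_result(variants, pass, "functional", detail)
}

#' Keep variants rare in every configured population database
#'
#' Pass iff the allele frequency is strictly below `max_maf` in EVERY
#' configured database; a missing frequency passes or fails that
#' database according to `missing_af_policy`.
#'
#' @inheritParams filter_functional
#' @return list with `survivors` and `trails`.
#' @export
filter_rare <- function(variants, config = cascade_config()) {
  validate_variants(variants)
  n <- nrow(variants)
  pass <- rep(TRUE, n)
  detail <- rep("rare in all databases", n)
  for (db in config$databases) {
    col <- paste0("af_", db)
    af <- if (col %in% names(variants)) variants[[col]] else rep(NA_real_, n)
    db_ok <- if (config$missing_af_policy == "treat_as_rare") {
      is.na(af) | af < config$max_maf
    } else {
      !is.na(af) & af < config$max_maf
    }
    newly <- pass & !db_ok
    detail[newly] <- ifelse(is.na(af[newly]),
                            paste0("missing AF in ", db),
                            sprintf("AF %s = %g >= %g", db, af[newly],
                                    config$max_maf))
    pass <- pass & db_ok
  }
  filter_result(variants, pass, "rare", detail)
}

#' Keep variants segregating as a recessive trait in the siblings
#'
#' Pass iff every affected sibling is homozygous-alternate (code 2) and
#' every unaffected sibling carries at most `max_unaffected_code`
#' (default: at most heterozygous). A missing genotype in any required
#' sample fails the variant (conservative: no-calls cannot support a
#' candidate). Parents are not constrained here; their carrier status is
#' reported separately by [parental_segregation_check()].
#'
#' @inheritParams filter_functional
#' @param pedigree a [pedigree()]; affected members and unaffected
#'   offspring define the required samples, all of which must have
#'   genotype columns.
#' @return list with `survivors` and `trails`.
#' @export
filter_recessive_pattern <- function(variants, pedigree,
                                     config = cascade_config()) {
  validate_variants(variants)
  aff <- affected_ids(pedigree)
  unaff <- intersect(unaffected_ids(pedigree), offspring_ids(pedigree))
  need <- c(aff, unaff)
  absent <- setdiff(need, variant_samples(variants))
  if (length(absent))
    stop("pedigree sample(s) absent from variant genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (nrow(variants) == 0)
    return(filter_result(variants, logical(), "recessive_pattern", character()))
  gt <- variant_genotypes(variants)
  miss <- apply(gt[, need, drop = FALSE] == -1L, 1, any)
  aff_ok <- apply(gt[, aff, drop = FALSE] == 2L, 1, all)
  un_ok <- if (length(unaff)) {
    apply(gt[, unaff, drop = FALSE] <= config$max_unaffected_code, 1, all)
  } else rep(TRUE, nrow(gt))
  pass <- !miss & aff_ok & un_ok
  detail <- ifelse(miss, "missing genotype",
                   ifelse(!aff_ok, "affected not all hom-alt",
                          ifelse(!un_ok, "unaffected sibling exceeds ceiling",
                                 "recessive pattern")))
  filter_result(variants, pass, "recessive_pattern", detail)
}

#' Keep variants falling inside given segments (e.g. shared LOH)
#'
#' @inheritParams filter_functional
#' @param regions segment data.frame (0-based half-open), e.g. from
#'   [shared_loh()].
#' @return list with `survivors` and `trails`.
#' @export
restrict_to_regions <- function(variants, regions) {
  validate_variants(variants)
  validate_segments(regions)
  pass <- vapply(seq_len(nrow(variants)), function(i) {
    pos0 <- variants$pos[i] - 1
    any(regions$chrom == variants$chrom[i] &
          regions$start <= pos0 & pos0 < regions$end)
  }, logical(1))
  detail <- ifelse(pass, "inside shared region", "outside shared regions")
  filter_result(variants, pass, "region_overlap", detail)
}

#' Check parental carrier status for a recessive candidate
#'
#' For a recessive causal variant both parents of the affected siblings
#' should be heterozygous carriers. Returns `"consistent"` iff both
#' parents have code 1, `"untestable"` if either parental genotype is
#' missing, `"inconsistent"` otherwise.
#'
#' @param variant one-row variant table.
#' @param pedigree a [pedigree()].
#' @return list with `verdict` and `detail`.
#' @export
parental_segregation_check <- function(variant, pedigree) {
  stopifnot(nrow(variant) == 1)
  aff <- affected_ids(pedigree)
  if (!length(aff)) stop("pedigree has no affected member", call. = FALSE)
  i <- match(aff[1], pedigree$sample_id)
  parents <- c(pedigree$father_id[i], pedigree$mother_id[i])
  if (any(is.na(parents)))
    return(list(verdict = "untestable", detail = "affected member is a founder"))
  cols <- paste0("gt_", parents)
  if (!all(cols %in% names(variant)))
    return(list(verdict = "untestable", detail = "parent not genotyped"))
  g <- as.integer(variant[1, cols])
  if (any(g == -1L))
    return(list(verdict = "untestable", detail = "parent genotype missing"))
  if (all(g == 1L))
    return(list(verdict = "consistent", detail = "both parents heterozygous"))
  list(verdict = "inconsistent",
       detail = sprintf("parental codes %d/%d", g[1], g[2]))
}

#' Run the full recessive-model prioritization cascade
#'
#' Applies, in order: functional class, population rarity, recessive
#' segregation pattern, and (when configured) restriction to shared-LOH
#' regions. Each filter is an independent predicate, so the survivor set
#' does not depend on the order; the order fixes only which filter a
#' failing variant is attributed to in the audit trail. Once a variant
#' fails, later filters are recorded as `"not-evaluated"`.
#'
#' @param variants a variant table (e.g. [read_vcf_subset()]).
#' @param pedigree a [pedigree()].
#' @param shared_loh_segments segment data.frame from [shared_loh()]
#'   (ignored when `config$require_region_overlap` is FALSE).
#' @param config a [cascade_config()].
#' @return list of class `"candidate_report"`: `survivors` (variant
#'   table sorted by chrom, pos, with a `segregation` column),
#'   `trails` (long data.frame of per-variant per-filter verdicts),
#'   `n_input`.
#' @export
run_prioritization <- function(variants, pedigree,
                               shared_loh_segments = segments(),
                               config = cascade_config()) {
  validate_variants(variants)
  stages <- list(
    functional = function(v) filter_functional(v, config),
    rare = function(v) filter_rare(v, config),
    recessive_pattern = function(v) filter_recessive_pattern(v, pedigree, config)
  )
  if (isTRUE(config$require_region_overlap))
    stages$region_overlap <- function(v) restrict_to_regions(v, shared_loh_segments)

  active <- variants
  all_keys <- variant_key(variants)
  trails <- list()
  for (nm in names(stages)) {
    res <- stages[[nm]](active)
    inactive <- setdiff(all_keys, variant_key(active))
    trails[[nm]] <- rbind(
      res$trails,
      if (length(inactive)) data.frame(variant_key = inactive, filter = nm,
                                       verdict = "not-evaluated",
                                       detail = "", stringsAsFactors = FALSE)
    )
    active <- res$survivors
  }
  trails <- do.call(rbind, trails)
  rownames(trails) <- NULL
  survivors <- active[order(active$chrom, active$pos), , drop = FALSE]
  rownames(survivors) <- NULL
  survivors$segregation <- if (nrow(survivors)) {
    vapply(seq_len(nrow(survivors)), function(i)
      parental_segregation_check(survivors[i, , drop = FALSE],
                                 pedigree)$verdict, character(1))
  } else character()
  structure(list(survivors = survivors, trails = trails,
                 n_input = nrow(variants)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %d input variant(s), %d survivor(s)\n",
              x$n_input, nrow(x$survivors)))
  if (nrow(x$survivors)) {
    cat(paste0("  ", variant_key(x$survivors), " [", x$survivors$gene,
               ", ", x$survivors$consequence, ", segregation ",
               x$survivors$segregation, "]\n"), sep = "")
  }
  invisible(x)
}

#' Write a candidate report as TSV (survivors + audit trail)
#' @param report a `candidate_report`.
#' @param path output TSV path for the trail; survivors are written next
#'   to it with suffix `.survivors.tsv`.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  utils::write.table(report$trails, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$survivors,
                     paste0(sub("\\.tsv$", "", path), ".survivors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
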