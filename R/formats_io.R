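## File formats: 6-column PED, a VCF v4.2 subset (GT + configurable INFO
## annotation keys), BED3+name for segments, TSV genotype panels, YAML
## config. VCF parsing is delegated to vcfR; the writers emit the same
## subset so round-trips are lossless for every field in scope.

#' Read a 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex
#' (1=male, 2=female, other=unknown) and phenotype (2=affected,
#' 1=unaffected, 0/-9=unknown). Parent id `0` means founder.
#'
#' @param path path to a whitespace-delimited PED file.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) != 6)
    stop("PED file must have exactly 6 columns, found ", ncol(tab),
         call. = FALSE)
  decode_parent <- function(x) ifelse(x %in% c("0", ".", "-9"), NA_character_, x)
  decode <- function(x, map) {
    out <- unname(map[x])
    out[is.na(out)] <- "unknown"   # 0 / -9 / anything else
    out
  }
  pedigree(
    sample_id = tab[[2]],
    father_id = decode_parent(tab[[3]]),
    mother_id = decode_parent(tab[[4]]),
    sex = decode(tab[[5]], c("1" = "male", "2" = "female")),
    affected = decode(tab[[6]], c("2" = "affected", "1" = "unaffected")),
    family_id = tab[[1]][1]
  )
}

#' Write a pedigree as a 6-column PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  enc_parent <- function(x) ifelse(is.na(x), "0", x)
  tab <- data.frame(
    ped$family_id, ped$sample_id,
    enc_parent(ped$father_id), enc_parent(ped$mother_id),
    c(male = "1", female = "2", unknown = "0")[ped$sex],
    c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default INFO key mapping for annotated VCFs
#'
#' Maps the package's annotation fields to the INFO keys carrying them.
#' `pop_afs` is a named vector: names are database labels (used as
#' `af_<db>` columns), values the INFO keys.
#'
#' @return a list with elements `gene`, `consequence`, `cds_pos`,
#'   `protein_pos`, `pop_afs`.
#' @export
default_info_map <- function() {
  list(gene = "GENE", consequence = "CSQ", cds_pos = "CDS_POS",
       protein_pos = "PROT_POS",
       pop_afs = c(ExAC = "AF_EXAC", `1KG` = "AF_1KG", TOPMED = "AF_TOPMED"))
}

#' Read an annotated VCF subset into a variant table
#'
#' Reads CHROM/POS/REF/ALT, per-sample GT and the configured INFO keys.
#' Multi-allelic records are decomposed into one biallelic row per ALT
#' allele: scalar INFO values are duplicated across alleles, array-valued
#' (comma-separated) INFO values are split positionally. GT fields map to
#' codes `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`; any GT containing `.`
#' maps to `-1`; phase separators (`|`) are ignored. Missing INFO keys
#' yield `NA` fields, not errors.
#'
#' @param path path to a VCF v4.x file.
#' @param info_map INFO key mapping, see [default_info_map()].
#' @return a variant table: `data.frame` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gene`, `consequence`, `cds_pos`,
#'   `protein_pos`, one `af_<db>` column per configured database, and one
#'   `gt_<sample>` column per sample.
#' @export
read_vcf_subset <- function(path, info_map = default_info_map()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) return(empty_variant_table(info_map, character()))
  gt_raw <- if (ncol(v@gt) > 1) {
    vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  } else {
    matrix(character(), nrow = n_rec, ncol = 0)
  }
  samples <- colnames(gt_raw)
  info_val <- function(key) {
    out <- vcfR::extract.info(v, element = key)
    if (is.null(out)) rep(NA_character_, n_rec) else out
  }
  gene <- info_val(info_map$gene)
  csq <- info_val(info_map$consequence)
  cdsp <- info_val(info_map$cds_pos)
  protp <- info_val(info_map$protein_pos)
  afs <- lapply(info_map$pop_afs, info_val)

  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    pick <- function(x, k) {
      if (is.na(x)) return(NA_character_)
      parts <- strsplit(x, ",", fixed = TRUE)[[1]]
      if (length(parts) == n_alt) parts[k]
      else if (length(parts) == 1) parts
      else NA_character_
    }
    per_alt <- lapply(seq_len(n_alt), function(k) {
      gts <- vapply(seq_along(samples), function(j) {
        gt_to_code(gt_raw[i, j], allele = k,
                   where = sprintf("record %s:%s sample %s",
                                   fix[i, "CHROM"], fix[i, "POS"], samples[j]))
      }, integer(1))
      af_k <- vapply(afs, function(a) as.numeric(pick(a[i], k)), numeric(1))
      c(list(chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
             ref = fix[i, "REF"], alt = alts[k],
             gene = pick(gene[i], k), consequence = pick(csq[i], k),
             cds_pos = as.numeric(pick(cdsp[i], k)),
             protein_pos = as.numeric(pick(protp[i], k))),
        stats::setNames(as.list(af_k), paste0("af_", names(info_map$pop_afs))),
        stats::setNames(as.list(gts), paste0("gt_", samples)))
    })
    rows[[i]] <- per_alt
  }
  rows <- unlist(rows, recursive = FALSE)
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  validate_variants(out)
  out
}

gt_to_code <- function(gt, allele = 1L, where = "") {
  if (is.na(gt)) return(-1L)
  gt <- strsplit(gt, ":", fixed = TRUE)[[1]][1]
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(-1L)
  num <- suppressWarnings(as.integer(alleles))
  if (length(num) != 2 || any(is.na(num)))
    stop("malformed GT field '", gt, "' at ", where, call. = FALSE)
  as.integer(sum(num == allele))
}

empty_variant_table <- function(info_map, samples) {
  out <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                    alt = character(), gene = character(),
                    consequence = character(), cds_pos = numeric(),
                    protein_pos = numeric(), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (db in names(info_map$pop_afs)) out[[paste0("af_", db)]] <- numeric()
  for (s in samples) out[[paste0("gt_", s)]] <- integer()
  out
}

#' Accessors for variant-table columns
#'
#' @param variants a variant table (see [read_vcf_subset()]).
#' @return `variant_samples`: sample ids; `variant_databases`: database
#'   labels with an `af_` column; `variant_genotypes`: integer genotype
#'   matrix (variants x samples).
#' @export
variant_samples <- function(variants)
  sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))

#' @rdname variant_samples
#' @export
variant_databases <- function(variants)
  sub("^af_", "", grep("^af_", names(variants), value = TRUE))

#' @rdname variant_samples
#' @export
variant_genotypes <- function(variants) {
  cols <- grep("^gt_", names(variants), value = TRUE)
  m <- as.matrix(variants[cols])
  storage.mode(m) <- "integer"
  colnames(m) <- sub("^gt_", "", cols)
  m
}

#' Validate a variant table
#' @param variants a variant table.
#' @return `variants`, invisibly, or an error.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$ref == variants$alt))
    stop("ref must differ from alt", call. = FALSE)
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    stop("variant table rows must be biallelic (single alt)", call. = FALSE)
  for (col in grep("^af_", names(variants), value = TRUE)) {
    bad <- !is.na(variants[[col]]) &
      (variants[[col]] < 0 | variants[[col]] > 1)
    if (any(bad)) stop("allele frequencies must lie in [0,1]: ", col,
                       call. = FALSE)
  }
  gt <- variant_genotypes(variants)
  if (length(gt) && !all(gt %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype codes must be in {-1, 0, 1, 2}", call. = FALSE)
  invisible(variants)
}

#' Write a variant table as an annotated VCF
#'
#' Emits the same VCF v4.2 subset [read_vcf_subset()] consumes; the
#' round-trip `read_vcf_subset(write_vcf_subset(x))` is lossless for all
#' fields in scope.
#'
#' @param variants a variant table.
#' @param path output path.
#' @param info_map INFO key mapping, see [default_info_map()].
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(variants, path, info_map = default_info_map()) {
  validate_variants(variants)
  samples <- variant_samples(variants)
  dbs <- variant_databases(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            info_map$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence\">",
            info_map$consequence),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"CDS position\">",
            info_map$cds_pos),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Protein position\">",
            info_map$protein_pos),
    vapply(dbs, function(db) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s allele frequency\">",
      info_map$pop_afs[[db]], db), character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  recs <- vapply(seq_len(nrow(variants)), function(i) {
    info <- character()
    add <- function(key, val, num = FALSE) {
      if (length(val) == 1 && !is.na(val))
        info <<- c(info, paste0(key, "=", if (num) fmt_num(val) else val))
    }
    add(info_map$gene, variants$gene[i])
    add(info_map$consequence, variants$consequence[i])
    add(info_map$cds_pos, variants$cds_pos[i], num = TRUE)
    add(info_map$protein_pos, variants$protein_pos[i], num = TRUE)
    for (db in dbs) add(info_map$pop_afs[[db]],
                        variants[[paste0("af_", db)]][i], num = TRUE)
    gt_str <- vapply(samples, function(s) {
      switch(as.character(variants[[paste0("gt_", s)]][i]),
             "0" = "0/0", "1" = "0/1", "2" = "1/1", "./.")
    }, character(1))
    paste(c(variants$chrom[i], fmt_num(variants$pos[i]), ".",
            variants$ref[i], variants$alt[i], ".", ".",
            if (length(info)) paste(info, collapse = ";") else ".",
            if (length(samples)) c("GT", gt_str)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read / write segments as BED
#'
#' BED3 plus an optional name column (sample id) and an optional fifth
#' column (supporting marker count); `.` encodes missing. BED is 0-based
#' half-open, the package's internal convention, so no coordinate shift
#' occurs. `write_bed` sorts by `(chrom, start)`.
#'
#' @param path BED file path.
#' @return `read_bed`: a segment `data.frame` (see [segments()]).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(segments())
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  dot_na <- function(x) ifelse(x == ".", NA_character_, x)
  segments(
    chrom = tab[[1]],
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    sample_id = if (ncol(tab) >= 4) dot_na(tab[[4]]) else NA_character_,
    n_markers = if (ncol(tab) >= 5) as.numeric(dot_na(tab[[5]])) else NA_real_
  )
}

#' @rdname read_bed
#' @param x segment data.frame to write.
#' @export
write_bed <- function(x, path) {
  validate_segments(x)
  x <- sort_segments(x)
  fmt <- function(v) ifelse(is.na(v), ".",
                            format(v, scientific = FALSE, trim = TRUE,
                                   digits = 15))
  lines <- if (nrow(x) == 0) character() else
    paste(x$chrom, fmt(x$start), fmt(x$end), fmt(x$sample_id),
          fmt(x$n_markers), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genotype panel as TSV
#'
#' Header `marker_id  chrom  pos  <sample...>`; one row per marker; codes
#' in `{-1, 0, 1, 2}`.
#'
#' @param path TSV path.
#' @return `read_panel_tsv`: a [genotype_panel()].
#' @export
read_panel_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(tab)))
  samples <- setdiff(names(tab), c("marker_id", "chrom", "pos"))
  genotype_panel(
    markers = data.frame(chrom = as.character(tab$chrom),
                         pos = as.numeric(tab$pos),
                         marker_id = as.character(tab$marker_id),
                         stringsAsFactors = FALSE),
    samples = samples,
    calls = as.matrix(tab[samples])
  )
}

#' @rdname read_panel_tsv
#' @param panel a [genotype_panel()] to write.
#' @export
write_panel_tsv <- function(panel, path) {
  validate_panel(panel)
  tab <- cbind(
    data.frame(marker_id = panel$markers$marker_id,
               chrom = panel$markers$chrom,
               pos = panel$markers$pos, stringsAsFactors = FALSE),
    as.data.frame(panel$calls)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML configuration file
#' @param path YAML path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
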