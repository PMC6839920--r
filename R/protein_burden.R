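#' Map a CDS position to codon and within-codon position
#'
#' HGVS c. coordinates are 1-based offsets into the coding sequence;
#' codon index `ceiling(c/3)` is the protein residue number, e.g.
#' c.230 falls in codon 77 at codon position 2 (the p.Arg77 residue).
#'
#' @param cds_pos 1-based CDS offset(s), integer.
#' @return data.frame with `codon_index` and `position_in_codon`
#'   (1, 2 or 3); one row per input.
#' @examples
#' cds_to_codon(230)  # codon 77, position 2
#' @export
cds_to_codon <- function(cds_pos) {
  if (any(!is.finite(cds_pos)) || any(cds_pos < 1) ||
      any(cds_pos != floor(cds_pos)))
    stop("cds_pos must be a positive integer", call. = FALSE)
  data.frame(codon_index = ceiling(cds_pos / 3),
             position_in_codon = ((cds_pos - 1) %% 3) + 1)
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

#' Amino-acid consequence of a single-base codon change
#'
#' Substitutes `alt_base` at `position_in_codon` of `ref_codon` and
#' translates both codons with the standard genetic code.
#'
#' @param ref_codon 3 uppercase DNA bases.
#' @param position_in_codon 1, 2 or 3.
#' @param alt_base single DNA base, must differ from the reference base
#'   at that position.
#' @return list with `ref_aa` and `alt_aa` as three-letter codes
#'   (`"Ter"` for a stop codon).
#' @examples
#' apply_codon_change("CGC", 2, "A")  # Arg -> His (the p.Arg77His change)
#' @export
apply_codon_change <- function(ref_codon, position_in_codon, alt_base) {
  bases <- c("A", "C", "G", "T")
  if (!is.character(ref_codon) || nchar(ref_codon) != 3 ||
      !all(strsplit(ref_codon, "")[[1]] %in% bases))
    stop("ref_codon must be 3 uppercase DNA bases", call. = FALSE)
  if (!position_in_codon %in% 1:3)
    stop("position_in_codon must be 1, 2 or 3", call. = FALSE)
  if (!alt_base %in% bases)
    stop("alt_base must be a DNA base", call. = FALSE)
  split <- strsplit(ref_codon, "")[[1]]
  if (split[position_in_codon] == alt_base)
    stop("alt_base equals the reference base at that position",
         call. = FALSE)
  alt_codon <- split
  alt_codon[position_in_codon] <- alt_base
  alt_codon <- paste(alt_codon, collapse = "")
  code <- Biostrings::GENETIC_CODE
  list(ref_aa = unname(AA_THREE[code[[ref_codon]]]),
       alt_aa = unname(AA_THREE[code[[alt_codon]]]))
}

#' Per-residue variant allele-frequency burden track
#'
#' Maps coding variants to protein residues and aggregates their
#' population allele frequencies per residue (sum by default; max
#' available for sensitivity), the track plotted along a protein to
#' visualise which residues tolerate variation.
#'
#' @param variants variant table with `protein_pos` and `af_<db>`
#'   columns; rows with missing `protein_pos` or missing AF are skipped.
#' @param protein_length protein length in residues.
#' @param db database label supplying the frequencies (default
#'   `"ExAC"`).
#' @param aggregation `"sum"` or `"max"`.
#' @return list of class `"burden_track"`: `protein_length`,
#'   `per_residue_af` (numeric vector, zero where no variant),
#'   `contributing_variants` (list residue -> variant keys), `db`,
#'   `aggregation`.
#' @export
build_burden_track <- function(variants, protein_length, db = "ExAC",
                               aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  validate_variants(variants)
  col <- paste0("af_", db)
  if (!col %in% names(variants))
    stop("no column ", col, " in variant table", call. = FALSE)
  use <- !is.na(variants$protein_pos) & !is.na(variants[[col]])
  v <- variants[use, , drop = FALSE]
  bad <- v$protein_pos < 1 | v$protein_pos > protein_length
  if (any(bad))
    stop("protein_pos out of range for variant ",
         variant_key(v[bad, , drop = FALSE])[1], call. = FALSE)
  track <- numeric(protein_length)
  contrib <- vector("list", protein_length)
  for (i in seq_len(nrow(v))) {
    r <- v$protein_pos[i]
    track[r] <- if (aggregation == "sum") track[r] + v[[col]][i]
                else max(track[r], v[[col]][i])
    contrib[[r]] <- c(contrib[[r]], variant_key(v[i, , drop = FALSE]))
  }
  structure(list(protein_length = protein_length, per_residue_af = track,
                 contributing_variants = contrib, db = db,
                 aggregation = aggregation),
            class = "burden_track")
}

#' Domain annotations for a protein
#'
#' @param name domain names (e.g. `"EF-hand 2"`).
#' @param start_residue,end_residue 1-based inclusive residue bounds.
#' @param protein_length optional length for bound checking.
#' @return data.frame with `name`, `start_residue`, `end_residue`.
#' @export
domain_annotation <- function(name, start_residue, end_residue,
                              protein_length = NULL) {
  d <- data.frame(name = as.character(name),
                  start_residue = as.numeric(start_residue),
                  end_residue = as.numeric(end_residue),
                  stringsAsFactors = FALSE)
  if (any(d$start_residue < 1) || any(d$start_residue > d$end_residue))
    stop("domains need 1 <= start_residue <= end_residue", call. = FALSE)
  if (!is.null(protein_length) && any(d$end_residue > protein_length))
    stop("domain exceeds protein length", call. = FALSE)
  d
}

#' Tabulate a burden track with domain membership
#'
#' The tested, deterministic surface behind the burden plot: one row per
#' residue with the aggregated allele frequency, comma-joined names of
#' overlapping domains, and a highlight flag.
#'
#' @param track a [build_burden_track()] result.
#' @param domains a [domain_annotation()] data.frame (may be empty).
#' @param highlight_residue optional residue to flag (e.g. 77).
#' @return data.frame with `residue`, `value`, `domain`, `highlight`.
#' @export
burden_table <- function(track, domains = domain_annotation(character(),
                                                            numeric(),
                                                            numeric()),
                         highlight_residue = NA) {
  if (!is.na(highlight_residue) &&
      (highlight_residue < 1 || highlight_residue > track$protein_length))
    stop("highlight residue out of range", call. = FALSE)
  if (nrow(domains) && any(domains$end_residue > track$protein_length))
    stop("domain exceeds protein length", call. = FALSE)
  res <- seq_len(track$protein_length)
  dom <- vapply(res, function(r) {
    hit <- domains$name[domains$start_residue <= r & r <= domains$end_residue]
    paste(hit, collapse = ",")
  }, character(1))
  data.frame(residue = res, value = track$per_residue_af, domain = dom,
             highlight = !is.na(highlight_residue) & res == highlight_residue,
             stringsAsFactors = FALSE)
}

#' Plot a burden track and write its TSV
#'
#' Draws per-residue allele-frequency needles with shaded domain
#' intervals and an arrow at the highlighted residue; writes the
#' [burden_table()] TSV alongside. The TSV is the tested surface; the
#' figure is presentation only.
#'
#' @inheritParams burden_table
#' @param tsv_path optional path for the TSV.
#' @return the [burden_table()] data.frame, invisibly.
#' @export
plot_burden_track <- function(track, domains = domain_annotation(character(),
                                                                 numeric(),
                                                                 numeric()),
                              highlight_residue = NA, tsv_path = NULL) {
  tab <- burden_table(track, domains, highlight_residue)
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  ymax <- max(tab$value, 1e-4)
  graphics::plot(NA, xlim = c(1, track$protein_length), ylim = c(0, ymax * 1.15),
                 xlab = "residue", ylab = paste0(track$db, " allele frequency (",
                                                 track$aggregation, ")"),
                 main = "coding-variant burden along protein")
  if (nrow(domains))
    graphics::rect(domains$start_residue, 0, domains$end_residue, ymax * 1.15,
                   col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::segments(tab$residue, 0, tab$residue, tab$value)
  if (!is.na(highlight_residue))
    graphics::arrows(highlight_residue, ymax * 1.1, highlight_residue,
                     tab$value[highlight_residue] + ymax * 0.02,
                     length = 0.08, col = "red")
  invisible(tab)
}
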