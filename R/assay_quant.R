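## Bench-side quantifications as pure functions: relative qPCR
## expression, immunofluorescence ratios, secretion normalization, and
## the murine colitis disease-activity / histology composite scores.

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-((Ct_target - Ct_ref)_test - (Ct_target - Ct_ref)_control)`
#' with amplification efficiency fixed at 2 (perfect doubling per
#' cycle). Ct values are PCR cycle thresholds; a warning is issued for
#' values outside the usual 5-40 cycle range.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in
#'   the test sample.
#' @param ct_target_ctrl,ct_ref_ctrl same in the control/calibrator.
#' @return fold change (positive).
#' @examples
#' ddct_fold_change(20, 18, 24, 18)  # ddCt = -4 -> fold 16
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  if (any(cts < 5 | cts > 40))
    warning("Ct value outside the typical 5-40 cycle range")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Membranous-to-total fluorescence intensity ratio
#'
#' @param membrane_intensity,total_intensity summed fluorescence of the
#'   membranous compartment and the whole cell; `total_intensity > 0`.
#' @param clamp when the membrane signal exceeds the total (segmentation
#'   noise), clamp the ratio to 1 instead of returning > 1; a warning is
#'   issued either way.
#' @return ratio in `[0, 1]` for valid inputs.
#' @export
membrane_total_ratio <- function(membrane_intensity, total_intensity,
                                 clamp = FALSE) {
  if (!is.finite(total_intensity) || total_intensity <= 0)
    stop("total_intensity must be positive", call. = FALSE)
  if (membrane_intensity < 0)
    stop("membrane_intensity must be non-negative", call. = FALSE)
  r <- membrane_intensity / total_intensity
  if (r > 1) {
    warning("membrane intensity exceeds total intensity")
    if (clamp) r <- 1
  }
  r
}

#' Normalize secreted hormone to total protein content
#'
#' ELISA hormone concentration divided by total protein (Bradford) of
#' the same well, correcting for cell density. With inputs in pM and
#' micrograms the result is pM per microgram.
#'
#' @param hormone_conc measured hormone concentration (>= 0).
#' @param total_protein total protein mass (> 0).
#' @return normalized secretion.
#' @export
normalize_secretion <- function(hormone_conc, total_protein) {
  if (!is.finite(total_protein) || total_protein <= 0)
    stop("total_protein must be positive", call. = FALSE)
  if (hormone_conc < 0)
    stop("hormone_conc must be non-negative", call. = FALSE)
  hormone_conc / total_protein
}

#' Subscale configuration for colitis scores
#'
#' Ranges default to 0-4 per subscale, a common convention for
#' DSS-colitis scoring; they are configuration because published scoring
#' sheets vary.
#'
#' @param dai_subscales named list of `c(min, max)` for the
#'   disease-activity-index components (stool consistency, blood in
#'   stool, weight change).
#' @param histology_components named list of `c(min, max)` for the
#'   Neurath-style histology components.
#' @param involvement_range `c(min, max)` for the Cooper involvement
#'   multiplier.
#' @return list of class `"score_config"`.
#' @export
score_config <- function(dai_subscales = list(stool_consistency = c(0, 4),
                                              blood = c(0, 4),
                                              weight_change = c(0, 4)),
                         histology_components = list(inflammation = c(0, 4),
                                                     damage = c(0, 4)),
                         involvement_range = c(0, 4)) {
  ranges <- c(dai_subscales, histology_components,
              list(involvement = involvement_range))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("subscale ", nm, " needs min <= max", call. = FALSE)
  }
  structure(list(dai_subscales = dai_subscales,
                 histology_components = histology_components,
                 involvement_range = involvement_range),
            class = "score_config")
}

check_range <- function(value, range, what) {
  if (!is.finite(value) || value < range[1] || value > range[2])
    stop(what, " = ", value, " outside configured range [",
         range[1], ", ", range[2], "]", call. = FALSE)
  value
}

#' Disease activity index: sum of configured subscores
#'
#' DAI = stool-consistency + blood-in-stool + weight-change subscores,
#' each validated against its configured range.
#'
#' @param subscores named numeric vector matching
#'   `config$dai_subscales` (order is matched by name when named,
#'   position otherwise).
#' @param config a [score_config()].
#' @return total score.
#' @export
dai_score <- function(subscores, config = score_config()) {
  scales <- config$dai_subscales
  if (length(subscores) != length(scales))
    stop("expected ", length(scales), " DAI subscores", call. = FALSE)
  if (!is.null(names(subscores)) && all(nzchar(names(subscores))))
    subscores <- subscores[names(scales)]
  for (k in seq_along(scales))
    check_range(subscores[[k]], scales[[k]], names(scales)[k])
  sum(subscores)
}

#' Composite histology score: Neurath component sum times involvement
#'
#' `(sum of histology components) * involvement`, the composite used for
#' DSS-colitis severity (component sum per Neurath, multiplied by a
#' Cooper-style involvement score).
#'
#' @param components numeric vector matching
#'   `config$histology_components`.
#' @param involvement involvement multiplier.
#' @param config a [score_config()].
#' @return composite score.
#' @export
histology_score <- function(components, involvement,
                            config = score_config()) {
  scales <- config$histology_components
  if (length(components) != length(scales))
    stop("expected ", length(scales), " histology components", call. = FALSE)
  if (!is.null(names(components)) && all(nzchar(names(components))))
    components <- components[names(scales)]
  for (k in seq_along(scales))
    check_range(components[[k]], scales[[k]], names(scales)[k])
  check_range(involvement, config$involvement_range, "involvement")
  sum(components) * involvement
}
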