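#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual. Founders have
#' both parent ids missing (`NA`); every non-founder must name both
#' parents, and both must be rows of the pedigree. The structure must be
#' acyclic (no individual is its own ancestor).
#'
#' @param sample_id character vector of unique individual ids.
#' @param father_id,mother_id character vectors; `NA` for founders.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affected `"affected"`, `"unaffected"` or `"unknown"`.
#' @param family_id single family identifier.
#' @return a `data.frame` of class `c("pedigree", "data.frame")`.
#' @examples
#' trio <- pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
#'                  sex = c("male", "female", "female"),
#'                  affected = c("unaffected", "unaffected", "affected"))
#' @export
pedigree <- function(sample_id, father_id = NA_character_,
                     mother_id = NA_character_, sex = "unknown",
                     affected = "unknown", family_id = "FAM1") {
  n <- length(sample_id)
  ped <- data.frame(
    family_id = rep_len(as.character(family_id), n),
    sample_id = as.character(sample_id),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(as.character(sex), n),
    affected = rep_len(as.character(affected), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, the founder rule (both parents present or both
#' missing), referential integrity of parent ids, sex/affection levels,
#' and acyclicity (by topological elimination of founders).
#'
#' @param ped a pedigree data.frame.
#' @return `ped`, invisibly, or an error.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("sample_id", "father_id", "mother_id",
                  "sex", "affected") %in% names(ped)))
  if (anyDuplicated(ped$sample_id))
    stop("duplicate sample_id in pedigree: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]),
               collapse = ", "), call. = FALSE)
  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half))
    stop("individuals must have both parents or neither: ",
         paste(ped$sample_id[half], collapse = ", "), call. = FALSE)
  parents <- c(ped$father_id, ped$mother_id)
  unknown <- setdiff(stats::na.omit(parents), ped$sample_id)
  if (length(unknown))
    stop("parent id not present in pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!all(ped$sex %in% c("male", "female", "unknown")))
    stop("sex must be male/female/unknown", call. = FALSE)
  if (!all(ped$affected %in% c("affected", "unaffected", "unknown")))
    stop("affected must be affected/unaffected/unknown", call. = FALSE)
  ## topological sort: repeatedly remove individuals whose parents are
  ## all removed; leftovers indicate a cycle (e.g. self-ancestry)
  remaining <- ped$sample_id
  resolved <- character()
  repeat {
    idx <- match(remaining, ped$sample_id)
    ok <- (is.na(ped$father_id[idx]) | ped$father_id[idx] %in% resolved) &
      (is.na(ped$mother_id[idx]) | ped$mother_id[idx] %in% resolved)
    if (!any(ok)) break
    resolved <- c(resolved, remaining[ok])
    remaining <- remaining[!ok]
    if (!length(remaining)) break
  }
  if (length(remaining))
    stop("pedigree contains a cycle involving: ",
         paste(remaining, collapse = ", "), call. = FALSE)
  invisible(ped)
}

#' Affected / unaffected member ids
#' @param ped a pedigree.
#' @return character vector of sample ids.
#' @export
affected_ids <- function(ped) ped$sample_id[ped$affected == "affected"]

#' @rdname affected_ids
#' @export
unaffected_ids <- function(ped) ped$sample_id[ped$affected == "unaffected"]

#' Founder ids (both parents missing)
#' @param ped a pedigree.
#' @return character vector of sample ids.
#' @export
founder_ids <- function(ped) ped$sample_id[is.na(ped$father_id)]

#' Offspring ids: non-founders with no children of their own
#' @param ped a pedigree.
#' @return character vector of sample ids.
#' @export
offspring_ids <- function(ped) {
  nonfounder <- ped$sample_id[!is.na(ped$father_id)]
  has_child <- ped$sample_id %in% c(ped$father_id, ped$mother_id)
  setdiff(nonfounder, ped$sample_id[has_child])
}

ped_row <- function(ped, id) {
  i <- match(id, ped$sample_id)
  if (is.na(i)) stop("unknown individual: ", id, call. = FALSE)
  ped[i, , drop = FALSE]
}
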