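#' @rdname DiameterProfile-class
#' @param artery,region,diameters,plaqueSpan,proximalRef,distalRef See slot
#'   descriptions.
#' @return A `DiameterProfile`.
#' @examples
#' p <- diameterProfile("LAD", "mid",
#'                      diameters = c(4, 4, 4.4, 4, 4),
#'                      plaqueSpan = 3, proximalRef = 1:2, distalRef = 4:5)
#' remodelingIndex(p)
#' @export
diameterProfile <- function(artery, region, diameters, plaqueSpan,
                            proximalRef, distalRef) {
  new("DiameterProfile", artery = artery, region = region,
      diameters = as.numeric(diameters),
      plaqueSpan = as.integer(plaqueSpan),
      proximalRef = as.integer(proximalRef),
      distalRef = as.integer(distalRef))
}

#' Remodeling index of a coronary segment
#'
#' Ratio of the maximum outer diameter over the plaque span to the reference
#' diameter, where the reference is the mean of the mean diameters of the
#' segments directly proximal and distal to the plaque. A segment shows
#' positive remodeling when the index strictly exceeds 1.1 (an outer diameter
#' at least 10% greater than the reference); an index of exactly 1.1 is not
#' positive remodeling.
#'
#' @param profile A [DiameterProfile-class].
#' @return The remodeling index (unitless, > 0).
#' @examples
#' p <- diameterProfile("LAD", "proximal", c(3, 3, 4.8, 5, 5),
#'                      plaqueSpan = 3, proximalRef = 1:2, distalRef = 4:5)
#' remodelingIndex(p)  # 4.8 / mean(c(3, 5)) = 1.2
#' @export
remodelingIndex <- function(profile) {
  stopifnot(is(profile, "DiameterProfile"))
  validObject(profile)
  d <- profile@diameters
  ref <- mean(c(mean(d[profile@proximalRef]), mean(d[profile@distalRef])))
  max(d[profile@plaqueSpan]) / ref
}

#' Positive-remodeling threshold on the remodeling index
#'
#' Strict: `index > 1.1`.
#'
#' @param index Remodeling index (or vector thereof).
#' @param threshold PR threshold, default 1.1.
#' @return Logical.
#' @export
isPositiveRemodeling <- function(index, threshold = 1.1) index > threshold

#' Patient-level positive-remodeling label
#'
#' Aggregates per-segment remodeling indices into segment-level PR calls
#' (index strictly greater than 1.1) and a patient-level label: a patient has
#' PR if at least one segment of the LAD, LCX, or RCA (proximal, mid, or
#' distal) is PR-positive. Left main segments, if supplied, contribute no
#' patient-level PR.
#'
#' @param segments Either a list of [DiameterProfile-class] objects or a data
#'   frame with columns `artery`, `region`, and `remodeling_index`.
#' @param threshold PR threshold on the index (strict), default 1.1.
#' @return A list with `segments` (data frame: `artery`, `region`,
#'   `remodeling_index`, `pr`) and `pr_patient` (logical).
#' @examples
#' seg <- data.frame(artery = c("LAD", "LCX"), region = c("mid", "mid"),
#'                   remodeling_index = c(1.0, 1.15))
#' patientLabel(seg)$pr_patient  # TRUE
#' @export
patientLabel <- function(segments, threshold = 1.1) {
  if (is.list(segments) && !is.data.frame(segments) &&
      all(vapply(segments, is, TRUE, "DiameterProfile"))) {
    segments <- do.call(rbind, lapply(segments, function(p)
      data.frame(artery = p@artery, region = p@region,
                 remodeling_index = remodelingIndex(p))))
  }
  stopifnot(is.data.frame(segments),
            all(c("artery", "region", "remodeling_index") %in% names(segments)))
  if (nrow(segments) == 0L) stop("at least one segment is required")
  ids <- paste(segments$artery, segments$region)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate segment id: %s", ids[duplicated(ids)][1]))
  segments$pr <- isPositiveRemodeling(segments$remodeling_index, threshold)
  prPatient <- any(segments$pr[segments$artery %in% PR_ARTERIES])
  list(segments = segments, pr_patient = prPatient)
}
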