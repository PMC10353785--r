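#' Cell phase labels
#'
#' The simulator tracks six phases. Premitotic, postmitotic and quiescent
#' cells are alive; apoptotic cells shrink toward removal; necrosis is split
#' into an early (oncotic, fluid-absorbing and swelling) stage and a late
#' (post-rupture, shrinking) stage so that the two-stage necrotic debris
#' dynamics of the core are represented.
#'
#' @return `phaseLevels()` returns the six labels in their integer coding
#'   order.
#' @export
phaseLevels <- function() {
  c("PREMITOTIC", "POSTMITOTIC", "QUIESCENT",
    "APOPTOTIC", "EARLY_NECROTIC", "LATE_NECROTIC")
}

#' @rdname phaseLevels
#' @format Integer phase codes usable wherever a phase vector is expected.
#' @export
PREMITOTIC <- 1L
#' @rdname phaseLevels
#' @export
POSTMITOTIC <- 2L
#' @rdname phaseLevels
#' @export
QUIESCENT <- 3L
#' @rdname phaseLevels
#' @export
APOPTOTIC <- 4L
#' @rdname phaseLevels
#' @export
EARLY_NECROTIC <- 5L
#' @rdname phaseLevels
#' @export
LATE_NECROTIC <- 6L

#' Which phase codes are alive / dead / necrotic
#'
#' @param phase integer vector of phase codes.
#' @return logical vector.
#' @export
isLiving <- function(phase) phase <= QUIESCENT

#' @rdname isLiving
#' @export
isNecrotic <- function(phase) phase == EARLY_NECROTIC | phase == LATE_NECROTIC

#' Convert phase codes to labels and back
#'
#' @param phase integer codes (1..6).
#' @param label character labels from [phaseLevels()].
#' @return character labels, or integer codes.
#' @export
phaseLabel <- function(phase) phaseLevels()[phase]

#' @rdname phaseLabel
#' @export
phaseCode <- function(label) {
  code <- match(label, phaseLevels())
  if (anyNA(code)) {
    bad <- unique(label[is.na(code)])
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  }
  as.integer(code)
}
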