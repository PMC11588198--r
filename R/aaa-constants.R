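#' Heart-sound state order used throughout the package
#'
#' All posterior matrices, frame-label vectors and confusion layouts use this
#' fixed ordering of the five frame states.
#'
#' @format Character vector of length 5.
#' @export
PCG_STATES <- c("S1", "systole", "S2", "diastole", "murmur")

#' Standard auscultation sites
#'
#' The four standard chest positions: aortic (AV), pulmonic (PV),
#' tricuspid (TV) and mitral (MV) valve points.
#'
#' @format Character vector of length 4.
#' @export
PCG_SITES <- c("AV", "PV", "TV", "MV")

# frame grid constants (seconds)
FRAME_STEP <- 0.020
FRAME_LEN <- 0.050

state_factor <- function(x) factor(x, levels = PCG_STATES)

`%||%` <- function(a, b) if (is.null(a)) b else a
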