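#' Construct breath phase boundaries
#'
#' Phase triples used to gate pressure fusion: for each breath, the time the
#' inspiratory limb is pneumatically connected to the common line
#' (`[t_insp_start, t_insp_end)`) and the time the expiratory limb is
#' (`[t_insp_end, t_exp_end)`). Usually produced from flow-based
#' segmentation via [phases_from_breaths()].
#'
#' @param t_insp_start,t_insp_end,t_exp_end Numeric vectors of equal length,
#'   seconds; per breath `t_insp_start < t_insp_end < t_exp_end`, and breaths
#'   must be time-ordered and non-overlapping.
#' @return A `breath_phases` data frame.
#' @export
breath_phases <- function(t_insp_start, t_insp_end, t_exp_end) {
  ph <- data.frame(t_insp_start = as.numeric(t_insp_start),
                   t_insp_end = as.numeric(t_insp_end),
                   t_exp_end = as.numeric(t_exp_end))
  if (nrow(ph) == 0L) stop("argument error: no phases given")
  ok <- ph$t_insp_start < ph$t_insp_end & ph$t_insp_end < ph$t_exp_end
  if (!all(ok)) {
    stop("argument error: phase triple ", which(!ok)[1L],
         " violates t_insp_start < t_insp_end < t_exp_end")
  }
  if (nrow(ph) > 1L &&
      any(ph$t_insp_start[-1L] < ph$t_exp_end[-nrow(ph)] - 1e-9)) {
    stop("argument error: phases overlap or are out of order")
  }
  class(ph) <- c("breath_phases", "data.frame")
  ph
}

#' Phase triples from a segmented breath table
#'
#' @param breaths A breath table from [segment_breaths()] or
#'   [analyze_breaths()] (columns `t_start`, `t_insp_end`, `t_end`).
#' @return A [breath_phases()] object.
#' @export
phases_from_breaths <- function(breaths) {
  breath_phases(breaths$t_start, breaths$t_insp_end, breaths$t_end)
}

#' Fuse dual-limb pressure recordings into one airway pressure waveform
#'
#' A two-sensor circuit places one barometric sensor on the inspiratory limb
#' and one on the expiratory limb, isolated from each other by a three-way
#' valve; neither sensor alone sees airway pressure over the whole cycle.
#' Fusion reconstructs the common-line pressure by taking the inspiratory-limb
#' sample during each inspiration (`[t_insp_start, t_insp_end)`) and the
#' expiratory-limb sample during the expiration (`[t_insp_end, t_exp_end)`).
#' Samples outside every phase (before the first detected breath, after the
#' last) fall back to the per-sample maximum of the two limbs, which is also
#' the global rule when no phases are supplied (the limb connected to the
#' common line is the one seeing the higher pressure). The switch at phase
#' boundaries is instantaneous — no cross-fade — so any discontinuity is
#' visible as a diagnostic of segmentation quality.
#'
#' @param insp,exp Baseline-corrected pressure [waveform_trace()] objects
#'   (cmH2O gauge) on the identical time grid (see [resample_align()]).
#' @param phases Optional [breath_phases()]; when `NULL` the max rule is used
#'   throughout.
#' @return A pressure [waveform_trace()] labelled `"fused-common"`.
#' @export
fuse_pressures <- function(insp, exp, phases = NULL) {
  stopifnot(inherits(insp, "waveform_trace"), inherits(exp, "waveform_trace"))
  if (insp$channel != "pressure" || exp$channel != "pressure") {
    stop("argument error: fuse_pressures expects pressure traces")
  }
  if (length(insp$t) != length(exp$t) ||
      max(abs(insp$t - exp$t)) > 1e-9) {
    stop("alignment error: limb traces are not on the same time grid; ",
         "run resample_align first")
  }
  tt <- insp$t
  fused <- pmax(insp$v, exp$v)
  if (!is.null(phases)) {
    if (!inherits(phases, "breath_phases")) phases <- phases_from_breaths(phases)
    if (min(phases$t_insp_start) < tt[1L] - 1e-9 ||
        max(phases$t_exp_end) > tt[length(tt)] + 1e-9) {
      stop("argument error: phases extend beyond trace support")
    }
    for (i in seq_len(nrow(phases))) {
      ii <- tt >= phases$t_insp_start[i] & tt < phases$t_insp_end[i]
      ei <- tt >= phases$t_insp_end[i] & tt < phases$t_exp_end[i]
      fused[ii] <- insp$v[ii]
      fused[ei] <- exp$v[ei]
    }
  }
  waveform_trace(tt, fused, channel = "pressure", units = "cmH2O",
                 source_label = "fused-common",
                 nominal_rate = insp$nominal_rate)
}
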