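## Closed-form assay metrics: ddCT relative expression for qPCR and the
## scratch-closure percentage of a wound-healing assay.

#' Relative expression by the ddCT method
#'
#' \eqn{\Delta CT = CT_{target} - CT_{reference}} per condition,
#' \eqn{\Delta\Delta CT = \Delta CT_{treated} - \Delta CT_{control}}, fold
#' change \eqn{= 2^{-\Delta\Delta CT}} (perfect amplification doubling
#' assumed, as in the classic method; the reference is the housekeeping
#' gene).  Vectorised over replicates.
#'
#' @param ctTargetTreated,ctReferenceTreated cycle thresholds of target and
#'   housekeeping gene in the treated condition.
#' @param ctTargetControl,ctReferenceControl same for the control
#'   condition.
#' @return Positive x-fold change(s), 1 meaning no change.
#' @examples
#' ddctFoldChange(20, 15, 22, 15)  # ddCT = -2 -> 4-fold
#' @export
ddctFoldChange <- function(ctTargetTreated, ctReferenceTreated,
                           ctTargetControl, ctReferenceControl) {
  ct <- c(ctTargetTreated, ctReferenceTreated,
          ctTargetControl, ctReferenceControl)
  if (!is.numeric(ct) || any(!is.finite(ct)))
    stop("all CT values must be finite")
  if (any(ct < 0 | ct > 45))
    warning("CT value outside the usual 0-45 cycle range")
  ddct <- (ctTargetTreated - ctReferenceTreated) -
    (ctTargetControl - ctReferenceControl)
  2^(-ddct)
}

#' Scratch (wound) closure fraction
#'
#' \eqn{(x - y)/x} where x is the initial distance between the wound edges
#' and y the distance that remained cell-free; multiply by 100 for the
#' percentage.  Scale-invariant in the measurement unit.  y > x yields a
#' negative closure with a warning (the wound widened).
#'
#' @param x initial wound-edge distance (> 0).
#' @param y remaining cell-free distance (same units).
#' @return Closure fraction(s); 1 = fully closed, 0 = unchanged.
#' @examples
#' scratchClosure(100, 25)  # 0.75, i.e. 75 percent closed
#' @export
scratchClosure <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || any(!is.finite(c(x, y))))
    stop("'x' and 'y' must be finite numbers")
  if (any(x <= 0)) stop("'x' must be > 0")
  if (any(y < 0)) stop("'y' must be >= 0")
  if (any(y > x)) warning("y > x: closure reported negative")
  (x - y) / x
}
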