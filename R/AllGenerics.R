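#' @rdname PolysomeProfile-class
#' @param x,object a `PolysomeProfile` or `PeakSet`.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname PolysomeProfile-class
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname PeakSet-class
#' @param x a `PeakSet`.
#' @export
setGeneric("peakHeights", function(x) standardGeneric("peakHeights"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakPositions", function(x) standardGeneric("peakPositions"))

#' @rdname BufferingResult-class
#' @param x a `BufferingResult`.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname BufferingResult-class
#' @export
setGeneric("categoryFractions", function(x) standardGeneric("categoryFractions"))

#' @rdname BufferingResult-class
#' @export
setGeneric("foldChangeMedians", function(x) standardGeneric("foldChangeMedians"))

#' @export
setMethod("positions", "PolysomeProfile", function(x) x@position)

#' @export
setMethod("absorbance", "PolysomeProfile", function(x) x@absorbance)

#' @export
setMethod("peakHeights", "PeakSet",
          function(x) setNames(x@height, x@species))

#' @export
setMethod("peakPositions", "PeakSet",
          function(x) setNames(x@position, x@species))

#' @export
setMethod("categories", "BufferingResult", function(x) x@categories)

#' @export
setMethod("categoryFractions", "BufferingResult", function(x) x@fractions)

#' @export
setMethod("foldChangeMedians", "BufferingResult", function(x) x@medians)

setMethod("show", "PolysomeProfile", function(object) {
  cat(sprintf("PolysomeProfile '%s': %d points over [%.3g, %.3g]%s\n",
              object@label, length(object@position),
              if (length(object@position)) min(object@position) else NA,
              if (length(object@position)) max(object@position) else NA,
              if (object@smoothed)
                sprintf(" (Savitzky-Golay window %d, order %d)",
                        object@window, object@polyorder)
              else " (raw)"))
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:\n")
  for (i in seq_along(object@species)) {
    if (object@detected[i])
      cat(sprintf("  %s: position %.4g, height %.4g\n",
                  object@species[i], object@position[i], object@height[i]))
    else
      cat(sprintf("  %s: not detected\n", object@species[i]))
  }
})

setMethod("show", "BufferingResult", function(object) {
  cat(sprintf("BufferingResult: %d matched monosomic genes, cutoff %.2f\n",
              length(object@categories), object@cutoff))
  fr <- object@fractions
  cat(paste(sprintf("  %-10s %5.1f%%", names(fr), 100 * fr), collapse = "\n"),
      "\n")
  m <- object@medians
  cat(sprintf("  medians (monosomic): mRNA %.3f, protein %.3f\n",
              m["mrna", "monosomic"], m["protein", "monosomic"]))
})
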