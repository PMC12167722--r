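# Generics, accessors and show methods.

#' Number of cells
#' @param x a Tiling or TissueFrame.
#' @return Integer count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "Tiling", function(x) length(x@cells))

#' @rdname nCells
#' @export
setMethod("nCells", "TissueFrame", function(x) nrow(x@cells))

#' Cell identifiers
#' @param x a Tiling or TissueFrame.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellIds
#' @export
setMethod("cellIds", "Tiling", function(x) x@ids)

#' @rdname cellIds
#' @export
setMethod("cellIds", "TissueFrame", function(x) x@cells$id)

#' Cell table of a frame
#' @param x a TissueFrame.
#' @return data.frame with id, x, y, area_px, outermost.
#' @export
cellTable <- function(x) {
  stopifnot(is(x, "TissueFrame"))
  x@cells
}

#' Adjacency table of a frame
#' @param x a TissueFrame.
#' @return data.frame with i, k, omega, contact_kind (undirected, i < k).
#' @export
adjacencyTable <- function(x) {
  stopifnot(is(x, "TissueFrame"))
  x@adjacency
}

#' Half-link table of a HalfLinkSet
#' @param x a HalfLinkSet.
#' @export
linkTable <- function(x) {
  stopifnot(is(x, "HalfLinkSet"))
  x@links
}

#' Tensor matrix of a TextureTensor or StrainRates slot
#' @param x a TextureTensor.
#' @return 2x2 numeric matrix.
#' @export
tensorMatrix <- function(x) {
  stopifnot(is(x, "TextureTensor"))
  x@M
}

setMethod("show", "Tiling", function(object) {
  cat("Tiling with", length(object@cells), "cells and",
      nrow(object@vertices), "vertices\n")
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("  bounding box: x [%.1f, %.1f], y [%.1f, %.1f] px\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]))
})

setMethod("show", "TissueFrame", function(object) {
  cat(sprintf("TissueFrame %d (t = %g min): %d cells (%d outermost), %d neighbor pairs\n",
              object@frameIndex, object@time, nrow(object@cells),
              sum(object@cells$outermost), nrow(object@adjacency)))
  if (!is.null(object@labelImage))
    cat(sprintf("  label image %d x %d px, pixel size %g um/px\n",
                nrow(object@labelImage), ncol(object@labelImage),
                object@pixelSize))
})

setMethod("show", "HalfLinkSet", function(object) {
  cat(sprintf("HalfLinkSet roi %d frame %d: N_h = %d over N_c = %d cells%s\n",
              object@roiId, object@frameIndex, object@nH, object@nC,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "TextureTensor", function(object) {
  cat(sprintf("TextureTensor %s (roi %d, frame %d; N_c = %d, N_h = %d) [px^2]\n",
              object@variant, object@roiId, object@frameIndex,
              object@nC, object@nH))
  print(signif(object@M, 5))
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf("VelocityField (%s): %d x %d vectors, spacing %g px, %d masked\n",
              object@source, nrow(object@vx), ncol(object@vx),
              object@spacing, sum(!object@valid)))
})

setMethod("show", "Lineage", function(object) {
  cat(sprintf("Lineage over %d interval(s): %d divisions, %d apoptoses\n",
              length(object@maps), nrow(object@divisions),
              nrow(object@apoptoses)))
})

setMethod("show", "SyntheticScene", function(object) {
  ev <- table(factor(object@events$kind, c("T1", "division", "apoptosis")))
  cat(sprintf("SyntheticScene: %d frames (dt = %g min), %d cells at t0; events: %d T1, %d division, %d apoptosis\n",
              length(object@frames), object@dt, nCells(object@frames[[1]]),
              ev["T1"], ev["division"], ev["apoptosis"]))
})

setMethod("show", "StrainRates", function(object) {
  cat(sprintf("StrainRates roi %d interval %d (dt = %g min, rule %s, closure %s)\n",
              object@roiId, object@interval, object@dt, object@rule,
              object@closure))
  tr <- function(m) m[1, 1] + m[2, 2]
  cat(sprintf("  Tr G = %.3e, Tr S = %.3e, Tr R = %.3e, Tr D = %.3e, Tr A = %.3e [1/min]\n",
              tr(object@G), tr(object@S), tr(object@R), tr(object@D),
              tr(object@A)))
  cat(sprintf("  closure residual norm = %.3e\n", frob(object@residual)))
})
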