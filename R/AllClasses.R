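#' @import methods
NULL

#' TernaryVector: site-major charge encoding of an RNA sequence
#'
#' A sequence of length \eqn{n} is encoded as \eqn{3n} partial charges laid
#' out site-major: the \eqn{n} First-site charges, then the \eqn{n}
#' Second-site charges, then the \eqn{n} Third-site charges. "Ternary" refers
#' to the three hydrogen-bonding sites per base, not to a 3-D vector.
#'
#' @slot sequence the normalized RNA sequence (A/C/G/U).
#' @slot elements numeric vector of length \code{3 * n}, site-major.
#' @slot n sequence length in nucleotides.
#' @export
setClass("TernaryVector",
  representation(sequence = "character", elements = "numeric", n = "integer"))

setValidity("TernaryVector", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || nchar(object@sequence) != object@n)
    msg <- c(msg, "sequence must be a single string of length n")
  if (length(object@elements) != 3L * object@n)
    msg <- c(msg, "elements must have length 3*n")
  if (length(msg)) msg else TRUE
})

#' TorusStructure: 3-D coordinates of the charged sites on a circle
#'
#' The backbone is a circle of radius \eqn{R = n d / (2\pi)} (arc spacing
#' \eqn{d} = 12.9 angstrom between adjacent base anchors) in the z = 0 plane.
#' Each base extends along a straight segment from its anchor, tilted by
#' \code{angle} degrees out of the torus plane: 0 (Structure A, in-plane
#' radial), 90 (Structure B, perpendicular) or 45 (Structure C).
#'
#' @slot structure label "A", "B" or "C".
#' @slot sequence the normalized RNA sequence.
#' @slot n sequence length (nt).
#' @slot radius backbone circle radius (angstrom).
#' @slot angle tilt of the base segment out of the torus plane (degrees).
#' @slot sites data.frame with one row per charged site: \code{site} (1..3),
#'   \code{pos} (1..n), \code{base}, \code{charge}, \code{x}, \code{y},
#'   \code{z} (angstrom).
#' @export
setClass("TorusStructure",
  representation(structure = "character", sequence = "character",
                 n = "integer", radius = "numeric", angle = "numeric",
                 sites = "data.frame"))

setValidity("TorusStructure", function(object) {
  msg <- character()
  if (!object@structure %in% c("A", "B", "C"))
    msg <- c(msg, "structure must be one of A, B, C")
  if (nrow(object@sites) != 3L * object@n)
    msg <- c(msg, "sites must have 3*n rows")
  need <- c("site", "pos", "base", "charge", "x", "y", "z")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns", paste(need, collapse = ", ")))
  if (object@structure == "A" && nrow(object@sites) &&
      any(abs(object@sites$z) > 0))
    msg <- c(msg, "Structure A sites must all have z = 0")
  if (length(msg)) msg else TRUE
})

#' TorusLattice: the 11 x 11 x 11 evaluation grid of a structure
#'
#' Eleven equally spaced values per axis spanning the axis-aligned bounding
#' box of the structure's sites, indexed a = -5..5 (value at index a is
#' min + (a+5)(max-min)/10). A degenerate axis (max = min, e.g. z for
#' Structure A) keeps its 11 identical values.
#'
#' @slot points numeric matrix 1331 x 3 (columns x, y, z, angstrom).
#' @slot bounds numeric matrix 2 x 3 (rows min, max; columns x, y, z).
#' @export
setClass("TorusLattice",
  representation(points = "matrix", bounds = "matrix"))

setValidity("TorusLattice", function(object) {
  msg <- character()
  if (!identical(dim(object@points), c(1331L, 3L)))
    msg <- c(msg, "points must be a 1331 x 3 matrix")
  if (!identical(dim(object@bounds), c(2L, 3L)))
    msg <- c(msg, "bounds must be a 2 x 3 matrix")
  if (length(msg)) msg else TRUE
})

#' ScoreVector: a 3-element sequence score
#'
#' For VS and Sum the three values are per-site scores (First, Second,
#' Third); for EV_C and EV_S they are the x/y/z components of an electric
#' field in proportional (arbitrary) units.
#'
#' @slot method one of "VS", "Sum", "EV_C", "EV_S".
#' @slot structure "A", "B", "C", or NA for the structure-free methods.
#' @slot values numeric triple.
#' @export
setClass("ScoreVector",
  representation(method = "character", structure = "character",
                 values = "numeric"))

setValidity("ScoreVector", function(object) {
  msg <- character()
  if (!object@method %in% c("VS", "Sum", "EV_C", "EV_S"))
    msg <- c(msg, "method must be VS, Sum, EV_C or EV_S")
  if (!(is.na(object@structure) || object@structure %in% c("A", "B", "C")))
    msg <- c(msg, "structure must be A, B, C or NA")
  if (length(object@values) != 3L)
    msg <- c(msg, "values must have length 3")
  if (length(msg)) msg else TRUE
})

#' AxisRegression: one pairwise axis regression
#'
#' Ordinary least squares of one score/SMEL axis on another, with or without
#' an intercept. \code{signedFit} is sign(slope) * r-squared, the signed fit
#' statistic used to report anticorrelated axes.
#'
#' @slot axisPair "x-y", "y-z" or "z-x" (first component is the predictor).
#' @slot slope,se,pValue slope estimate, its standard error, and the p-value
#'   of the slope t-test.
#' @slot r2 coefficient of determination (uncentered when through origin).
#' @slot signedFit sign(slope) * r2.
#' @slot n number of points.
#' @slot throughOrigin TRUE if the intercept was forced to zero.
#' @export
setClass("AxisRegression",
  representation(axisPair = "character", slope = "numeric", se = "numeric",
                 pValue = "numeric", r2 = "numeric", signedFit = "numeric",
                 n = "integer", throughOrigin = "logical"))

setValidity("AxisRegression", function(object) {
  msg <- character()
  if (!object@axisPair %in% c("x-y", "y-z", "z-x"))
    msg <- c(msg, "axisPair must be x-y, y-z or z-x")
  if (!is.na(object@se) && object@se < 0)
    msg <- c(msg, "standard error must be >= 0")
  if (!is.na(object@signedFit) && abs(object@signedFit) > 1 + 1e-12)
    msg <- c(msg, "|signedFit| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TernaryVector", function(object) {
  cat(sprintf("TernaryVector: %d nt, %d elements (site-major)\n",
              object@n, length(object@elements)))
  cat("  sequence:", substr(object@sequence, 1, 40),
      if (object@n > 40) "..." else "", "\n")
})

setMethod("show", "TorusStructure", function(object) {
  cat(sprintf(
    "TorusStructure %s: %d nt, radius %.4f A, tilt %g deg, %d charged sites\n",
    object@structure, object@n, object@radius, object@angle,
    nrow(object@sites)))
})

setMethod("show", "TorusLattice", function(object) {
  b <- object@bounds
  cat("TorusLattice: 11 x 11 x 11 grid\n")
  for (i in 1:3)
    cat(sprintf("  %s: [%.4f, %.4f]\n", c("x", "y", "z")[i], b[1, i], b[2, i]))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector %s%s: (%.6g, %.6g, %.6g)\n", object@method,
              if (is.na(object@structure)) "" else
                paste0("_", object@structure),
              object@values[1], object@values[2], object@values[3]))
})

setMethod("show", "AxisRegression", function(object) {
  cat(sprintf(
    "AxisRegression %s%s: slope %.4g (SE %.3g), p %.3g, signed fit %.3g, n %d\n",
    object@axisPair, if (object@throughOrigin) " (through origin)" else "",
    object@slope, object@se, object@pValue, object@signedFit, object@n))
})
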