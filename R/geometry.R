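# Geometry constants (angstrom): arc spacing between adjacent base anchors,
# base segment length, spacing between adjacent sites of one base.
.BASE_SPACING <- 12.9
.BASE_LENGTH <- 8.6
.SITE_SPACING <- 2.385

# Site offsets along the base segment, centered on the 8.6 A base length:
# midpoint 4.3, +/- 2.385. First site innermost by default.
.SITE_OFFSETS <- c(1.915, 4.300, 6.685)

.structureAngle <- function(structure) {
  switch(structure, A = 0, B = 90, C = 45,
         stop("structure must be one of A, B, C"))
}

#' Build the torus-model structure of a sequence
#'
#' Lays the sequence on a circle: base j is anchored at angle
#' \eqn{2\pi(j-1)/n} on a circle of radius \eqn{R = n \cdot 12.9/(2\pi)}
#' angstrom (12.9 angstrom of arc between adjacent anchors) in the z = 0
#' plane, with base 1 on the +x axis and the origin at the circle centre.
#' The three charged sites of each base lie on a straight segment from the
#' anchor at offsets 1.915, 4.300 and 6.685 angstrom (the 8.6 angstrom base
#' segment centered on the 2 x 2.385 angstrom site span). The segment
#' direction is the outward radial unit vector tilted \code{angle} degrees
#' toward +z: 0 for Structure A (in-plane), 90 for Structure B
#' (perpendicular to the torus plane), 45 for Structure C.
#'
#' @param sequence RNA string, length >= 2 (a one-base "circle" is
#'   degenerate and rejected).
#' @param structure "A", "B" or "C".
#' @param angle tilt in degrees; defaults to the structure's convention
#'   (0/90/45). Overriding it interpolates between the structures.
#' @param firstSiteInnermost if FALSE, the site order along the base segment
#'   is reversed (Third site innermost). The figure conventions do not pin
#'   this down; innermost-First is the default gauge.
#' @return A \linkS4class{TorusStructure}.
#' @examples
#' st <- buildStructure("GCAU", "A")
#' torusRadius(st)  # 4 * 12.9 / (2*pi)
#' @export
buildStructure <- function(sequence, structure = c("A", "B", "C"),
                           angle = NULL, firstSiteInnermost = TRUE) {
  structure <- match.arg(structure)
  s <- normalizeRNA(sequence)
  n <- nchar(s)
  if (n < 2L) stop("sequence must have length >= 2")
  if (is.null(angle)) angle <- .structureAngle(structure)
  a <- angle * pi / 180

  R <- n * .BASE_SPACING / (2 * pi)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  # radial unit vector per base; tilt it by `a` toward +z
  ux <- cos(theta) * cos(a)
  uy <- sin(theta) * cos(a)
  uz <- rep(sin(a), n)

  offsets <- if (firstSiteInnermost) .SITE_OFFSETS else rev(.SITE_OFFSETS)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(bases, .AUHB$base)
  chargeBySite <- rbind(.AUHB$e1[idx], .AUHB$e2[idx], .AUHB$e3[idx])

  site <- rep(1:3, each = n)
  pos <- rep(seq_len(n), times = 3)
  off <- offsets[site]
  sites <- data.frame(
    site = site, pos = pos, base = bases[pos],
    charge = as.numeric(t(chargeBySite)),
    x = R * cos(theta)[pos] + off * ux[pos],
    y = R * sin(theta)[pos] + off * uy[pos],
    z = off * uz[pos],
    stringsAsFactors = FALSE)
  if (structure == "A") sites$z <- 0  # exact in-plane

  new("TorusStructure", structure = structure, sequence = s,
      n = as.integer(n), radius = R, angle = angle, sites = sites)
}

#' @rdname accessors
#' @export
setMethod("siteCoordinates", "TorusStructure", function(x)
  as.matrix(x@sites[, c("x", "y", "z")]))

#' @rdname accessors
#' @export
setMethod("siteCharges", "TorusStructure", function(x) x@sites$charge)

#' @rdname accessors
#' @export
setMethod("structureLabel", "TorusStructure", function(x) x@structure)

#' @rdname accessors
#' @export
setMethod("torusRadius", "TorusStructure", function(x) x@radius)

#' @rdname accessors
#' @export
setMethod("rnaSequence", "TorusStructure", function(x) x@sequence)

#' Build the 11 x 11 x 11 evaluation lattice of a structure
#'
#' Takes the axis-aligned bounding box of the structure's charged sites and
#' divides each axis into 10 equal parts, giving 11 grid values per axis
#' (indices -5..5; index a maps to min + (a+5)(max-min)/10) and 1331 points
#' in total. A degenerate axis (max = min, e.g. z for Structure A) keeps its
#' 11 identical values; the constant multiplicity is absorbed by the
#' proportional form of the field scores.
#'
#' @param structure a \linkS4class{TorusStructure}.
#' @return A \linkS4class{TorusLattice}.
#' @export
buildLattice <- function(structure) {
  stopifnot(is(structure, "TorusStructure"))
  xyz <- siteCoordinates(structure)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  axes <- lapply(1:3, function(i) lo[i] + (0:10) * (hi[i] - lo[i]) / 10)
  g <- expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  bounds <- rbind(min = lo, max = hi)
  colnames(bounds) <- c("x", "y", "z")
  new("TorusLattice", points = as.matrix(g), bounds = bounds)
}

#' @rdname accessors
#' @export
setMethod("latticePoints", "TorusLattice", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("latticeBounds", "TorusLattice", function(x) x@bounds)

#' Export a structure as an XYZ-like TSV
#'
#' One row per charged site: site index, base position, base, charge and
#' x/y/z coordinates — convenient for visual inspection.
#'
#' @param structure a \linkS4class{TorusStructure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportStructure <- function(structure, path) {
  stopifnot(is(structure, "TorusStructure"))
  df <- structure@sites
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "site" &
    names(df) != "pos"
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
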