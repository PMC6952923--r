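#' Vector-size score (VS)
#'
#' Per-site Euclidean norm of the ternary vector: component i is
#' \eqn{\sqrt{\sum_j e_{ij}^2}}. Order-free (permutation invariant) and
#' always non-negative.
#'
#' @param v a \linkS4class{TernaryVector} or an RNA string.
#' @return A \linkS4class{ScoreVector} with method "VS".
#' @examples
#' scoreValues(scoreVS("A"))   # 0.417 0.514 0.228
#' @export
scoreVS <- function(v) {
  if (is.character(v)) v <- ternaryVector(v)
  m <- siteMatrix(v)
  new("ScoreVector", method = "VS", structure = NA_character_,
      values = sqrt(rowSums(m^2)))
}

#' Charge-sum score (Sum)
#'
#' Per-site sum of charges: component i is \eqn{\sum_j e_{ij}}. Linear in
#' the sequence and permutation invariant.
#'
#' @inheritParams scoreVS
#' @return A \linkS4class{ScoreVector} with method "Sum".
#' @examples
#' scoreValues(scoreSum("AU"))   # -0.089 -0.106 -0.243
#' @export
scoreSum <- function(v) {
  if (is.character(v)) v <- ternaryVector(v)
  m <- siteMatrix(v)
  new("ScoreVector", method = "Sum", structure = NA_character_,
      values = rowSums(m))
}

#' Electric field of a structure at one point
#'
#' Point-charge field in proportional form (no physical prefactors): the sum
#' over all 3n charged sites of charge times displacement over distance
#' cubed, where displacement points from the site to the evaluation point.
#' Sites closer than 1e-9 angstrom to the point are skipped (their
#' contribution would be singular) and counted in a warning.
#'
#' @param structure a \linkS4class{TorusStructure}.
#' @param point numeric xyz triple (angstrom).
#' @return Numeric xyz field triple (arbitrary units).
#' @export
fieldAtPoint <- function(structure, point) {
  stopifnot(is(structure, "TorusStructure"), length(point) == 3L)
  xyz <- siteCoordinates(structure)
  q <- siteCharges(structure)
  disp <- cbind(point[1] - xyz[, 1], point[2] - xyz[, 2], point[3] - xyz[, 3])
  d2 <- rowSums(disp^2)
  ok <- d2 >= 1e-18   # (1e-9 A)^2
  if (!all(ok))
    warning(sprintf("%d site(s) coincide with the evaluation point; skipped",
                    sum(!ok)))
  w <- q[ok] / d2[ok]^1.5
  colSums(disp[ok, , drop = FALSE] * w)
}

#' Centre electric-field score (EV_C)
#'
#' The field of the structure evaluated at the torus centre (the origin), in
#' proportional units. For Structure A all charges lie in the z = 0 plane,
#' so the z component vanishes.
#'
#' @param structure a \linkS4class{TorusStructure}.
#' @return A \linkS4class{ScoreVector} with method "EV_C".
#' @export
scoreEVC <- function(structure) {
  new("ScoreVector", method = "EV_C", structure = structureLabel(structure),
      values = fieldAtPoint(structure, c(0, 0, 0)))
}

#' Lattice-summed electric-field score (EV_S)
#'
#' The field of the structure summed over all 1331 points of its
#' 11 x 11 x 11 bounding-box lattice, in proportional units. Lattice points
#' that coincide with a charged site skip that single charge contribution
#' (with a warning).
#'
#' @param structure a \linkS4class{TorusStructure}.
#' @param lattice optional \linkS4class{TorusLattice}; built from the
#'   structure when missing.
#' @return A \linkS4class{ScoreVector} with method "EV_S".
#' @export
scoreEVS <- function(structure, lattice = NULL) {
  stopifnot(is(structure, "TorusStructure"))
  if (is.null(lattice)) lattice <- buildLattice(structure)
  pts <- latticePoints(lattice)
  xyz <- siteCoordinates(structure)
  q <- siteCharges(structure)
  total <- c(0, 0, 0)
  skipped <- 0L
  for (s in seq_along(q)) {
    disp <- cbind(pts[, 1] - xyz[s, 1], pts[, 2] - xyz[s, 2],
                  pts[, 3] - xyz[s, 3])
    d2 <- rowSums(disp^2)
    ok <- d2 >= 1e-18
    skipped <- skipped + sum(!ok)
    w <- q[s] / d2[ok]^1.5
    total <- total + colSums(disp[ok, , drop = FALSE] * w)
  }
  if (skipped > 0L)
    warning(sprintf(
      "%d site/lattice-point coincidence(s) skipped in EV_S sum", skipped))
  new("ScoreVector", method = "EV_S", structure = structureLabel(structure),
      values = unname(total))
}

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreVector", function(x) unname(x@values))

#' @rdname accessors
#' @export
setMethod("scoreMethod", "ScoreVector", function(x)
  if (is.na(x@structure)) x@method else paste(x@method, x@structure,
                                              sep = "_"))

#' Score a set of sequences with one or more methods
#'
#' Computes the chosen score vectors for every sequence. VS and Sum are
#' structure-free; EV_C and EV_S are computed once per requested structure.
#'
#' @param sequences named character vector of RNA sequences, or a
#'   \code{Biostrings::RNAStringSet} (names become ids; unnamed input gets
#'   seq1, seq2, ...).
#' @param methods subset of c("VS", "Sum", "EV_C", "EV_S").
#' @param structures subset of c("A", "B", "C") used for EV_C/EV_S.
#' @return A data.frame with columns id, sequence, method, structure
#'   (NA for VS/Sum), v1, v2, v3.
#' @export
scoreTable <- function(sequences, methods = c("VS", "Sum", "EV_C", "EV_S"),
                       structures = c("A", "B", "C")) {
  methods <- match.arg(methods, several.ok = TRUE)
  structures <- match.arg(structures, several.ok = TRUE)
  seqs <- .asSequenceVector(sequences)
  ids <- names(seqs)

  rows <- list()
  needStruct <- any(c("EV_C", "EV_S") %in% methods)
  for (i in seq_along(seqs)) {
    tv <- ternaryVector(seqs[[i]])
    if ("VS" %in% methods) {
      v <- scoreValues(scoreVS(tv))
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], sequence = seqs[[i]], method = "VS",
        structure = NA_character_, v1 = v[1], v2 = v[2], v3 = v[3])
    }
    if ("Sum" %in% methods) {
      v <- scoreValues(scoreSum(tv))
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], sequence = seqs[[i]], method = "Sum",
        structure = NA_character_, v1 = v[1], v2 = v[2], v3 = v[3])
    }
    if (needStruct) {
      for (st in structures) {
        ts <- buildStructure(seqs[[i]], st)
        if ("EV_C" %in% methods) {
          v <- scoreValues(scoreEVC(ts))
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[i], sequence = seqs[[i]], method = "EV_C",
            structure = st, v1 = v[1], v2 = v[2], v3 = v[3])
        }
        if ("EV_S" %in% methods) {
          v <- scoreValues(scoreEVS(ts))
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[i], sequence = seqs[[i]], method = "EV_S",
            structure = st, v1 = v[1], v2 = v[2], v3 = v[3])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.asSequenceVector <- function(sequences) {
  if (is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (!is.character(sequences) || !length(sequences))
    stop("sequences must be a nonempty character vector or XStringSet")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  vapply(sequences, normalizeRNA, character(1), warnT = FALSE)
}

#' Duplicate / uniqueness analysis of score vectors
#'
#' Rounds score triples to \code{digits} decimal places and counts how many
#' entries share their (rounded) value with at least one other entry. A
#' value shared by k > 1 entries contributes k to the duplicate count and 0
#' to the unique count, so duplicate + unique = total.
#'
#' @param values a numeric matrix or data.frame of score triples (one row
#'   per sequence; columns v1, v2, v3 or any 3 numeric columns), or a
#'   character vector (e.g. sequences, for the reference row).
#' @param digits rounding precision before comparison (default 10, so
#'   floating-point noise does not split true duplicates).
#' @return Named list with \code{nDuplicate}, \code{nUnique},
#'   \code{pctUnique} (rounded to integer percent).
#' @examples
#' duplicateAnalysis(rbind(c(1, 2, 3), c(1, 2, 3), c(4, 5, 6)))
#' @export
duplicateAnalysis <- function(values, digits = 10) {
  if (is.character(values)) {
    key <- values
  } else {
    m <- as.matrix(values)
    if (!nrow(m)) stop("values must be nonempty")
    key <- apply(round(m, digits), 1, paste, collapse = "|")
  }
  if (!length(key)) stop("values must be nonempty")
  tab <- table(key)
  nDup <- sum(tab[tab > 1L])
  nUni <- sum(tab == 1L)
  list(nDuplicate = as.integer(nDup), nUnique = as.integer(nUni),
       pctUnique = as.integer(round(100 * nUni / length(key))))
}

#' Duplicate summary across methods
#'
#' Runs \code{\link{duplicateAnalysis}} per method/structure of a score
#' table, plus a reference row counting duplicated sequences themselves.
#'
#' @param scores a score table from \code{\link{scoreTable}}.
#' @param digits rounding precision passed on.
#' @return data.frame with columns method, structure, nDuplicate, nUnique,
#'   pctUnique; the last row (method "sequence") is the sequence reference.
#' @export
duplicateSummary <- function(scores, digits = 10) {
  groups <- unique(scores[, c("method", "structure")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- scores$method == g$method &
      (is.na(g$structure) | scores$structure %in% g$structure)
    if (is.na(g$structure)) sel <- scores$method == g$method &
        is.na(scores$structure)
    d <- duplicateAnalysis(scores[sel, c("v1", "v2", "v3")], digits)
    data.frame(method = g$method, structure = g$structure,
               nDuplicate = d$nDuplicate, nUnique = d$nUnique,
               pctUnique = d$pctUnique)
  })
  seqs <- unique(scores[, c("id", "sequence")])
  d <- duplicateAnalysis(seqs$sequence)
  out <- rbind(do.call(rbind, rows),
               data.frame(method = "sequence", structure = NA_character_,
                          nDuplicate = d$nDuplicate, nUnique = d$nUnique,
                          pctUnique = d$pctUnique))
  rownames(out) <- NULL
  out
}
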