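#' Score Multiplication Expression Level (SMEL)
#'
#' Multiplies a score vector elementwise by an expression value x (fold
#' change or log2 fold change). The result is an exact scalar multiple of
#' the score, so through-origin regressions of SMEL components inherit the
#' score geometry weighted by x.
#'
#' @param score a \linkS4class{ScoreVector}.
#' @param x a finite expression value.
#' @return A \linkS4class{ScoreVector} with the same method/structure and
#'   values \code{scoreValues(score) * x}.
#' @export
smel <- function(score, x) {
  stopifnot(is(score, "ScoreVector"), is.numeric(x), length(x) == 1L)
  if (!is.finite(x)) stop("expression value x must be finite")
  new("ScoreVector", method = score@method, structure = score@structure,
      values = score@values * x)
}

#' SMEL table for a disease panel
#'
#' Joins a score table with an expression table and multiplies each score
#' triple by the chosen expression value. FC and log2FC are parallel tracks;
#' one is chosen per call and never mixed.
#'
#' @param scores score table from \code{\link{scoreTable}}.
#' @param expression data.frame with columns \code{mirna_id},
#'   \code{disease}, \code{fc}, \code{log2fc} (see
#'   \code{\link{readExpression}}).
#' @param expressionType "log2fc" or "fc".
#' @return data.frame with columns id, disease, method, structure, x, s1,
#'   s2, s3 (the SMEL triple). Expression rows with no scored sequence are
#'   dropped with a warning.
#' @export
smelTable <- function(scores, expression,
                      expressionType = c("log2fc", "fc")) {
  expressionType <- match.arg(expressionType)
  expression <- completeExpression(expression)
  hit <- expression$mirna_id %in% scores$id
  if (!all(hit)) {
    warning(sprintf("%d expression row(s) without a scored sequence dropped",
                    sum(!hit)))
    expression <- expression[hit, , drop = FALSE]
  }
  if (!nrow(expression)) stop("no expression rows match the score table")
  groups <- unique(scores[, c("method", "structure")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    m <- groups$method[g]; st <- groups$structure[g]
    sel <- scores$method == m &
      (if (is.na(st)) is.na(scores$structure) else
         !is.na(scores$structure) & scores$structure == st)
    sub <- scores[sel, ]
    j <- match(expression$mirna_id, sub$id)
    x <- expression[[expressionType]]
    data.frame(id = expression$mirna_id, disease = expression$disease,
               method = m, structure = st, x = x,
               s1 = sub$v1[j] * x, s2 = sub$v2[j] * x, s3 = sub$v3[j] * x)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.AXIS_PAIRS <- c("x-y", "y-z", "z-x")
.axisColumns <- function(axisPair, prefix = "v") {
  i <- switch(axisPair, "x-y" = c(1, 2), "y-z" = c(2, 3), "z-x" = c(3, 1),
              stop("axisPair must be x-y, y-z or z-x"))
  paste0(prefix, i)
}

#' Pairwise axis regression
#'
#' Ordinary least squares of b on a, with or without an intercept. Reports
#' the slope, its standard error, the p-value of the slope t-test, r-squared
#' and the signed fit statistic sign(slope) * r-squared. Through-origin fits
#' use the uncentered r-squared (1 - RSS / sum(b^2)).
#'
#' @param a predictor values (first axis of the pair).
#' @param b response values (second axis of the pair).
#' @param throughOrigin force a zero intercept (the SMEL convention: SMEL is
#'   a scalar multiple of the score, so its regressions pass through the
#'   origin; raw score regressions keep the intercept).
#' @param axisPair label "x-y", "y-z" or "z-x" carried on the result.
#' @return An \linkS4class{AxisRegression}.
#' @examples
#' r <- pairwiseRegression(1:10, 2 * (1:10), throughOrigin = TRUE)
#' slopeEstimate(r)   # 2
#' @export
pairwiseRegression <- function(a, b, throughOrigin = FALSE,
                               axisPair = "x-y") {
  if (!axisPair %in% .AXIS_PAIRS) stop("axisPair must be x-y, y-z or z-x")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("at least 3 points are required")
  if (stats::var(a) == 0) stop("zero-variance predictor")
  fit <- if (throughOrigin) stats::lm(b ~ a + 0) else stats::lm(b ~ a)
  sm <- summary(fit)
  co <- sm$coefficients["a", ]
  slope <- unname(co["Estimate"])
  r2 <- sm$r.squared
  new("AxisRegression", axisPair = axisPair, slope = slope,
      se = unname(co["Std. Error"]), pValue = unname(co["Pr(>|t|)"]),
      r2 = r2, signedFit = sign(slope) * r2, n = n,
      throughOrigin = throughOrigin)
}

#' @rdname accessors
#' @export
setMethod("slopeEstimate", "AxisRegression", function(x) x@slope)

#' @rdname accessors
#' @export
setMethod("slopeSE", "AxisRegression", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("pValue", "AxisRegression", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("signedFit", "AxisRegression", function(x) x@signedFit)

#' @rdname accessors
#' @export
setMethod("axisPair", "AxisRegression", function(x) x@axisPair)

# An axis is degenerate when its values are numerically all zero (e.g. the
# z components of Structure A field scores); regressions on it carry no
# information and are reported NA.
.axisDegenerate <- function(v, scale) {
  max(abs(v)) <= 1e-12 * max(scale, 1e-300)
}

#' Axis-pair regression table for scores or SMEL
#'
#' Runs the three cyclic axis-pair regressions (x-y, y-z, z-x: first
#' component predicts the second) for every method/structure group of a
#' score table, or for every method/structure/disease group of a SMEL
#' table. Axis pairs involving a degenerate (all-zero) component — the z
#' axis of Structure A field scores — are reported as NA rows.
#'
#' @param tab a score table (columns v1..v3) or SMEL table (columns s1..s3).
#' @param throughOrigin zero-intercept fits (default FALSE for raw scores;
#'   use TRUE for SMEL).
#' @param uniqueOnly drop duplicate score triples (rounded to 10 decimals)
#'   within each group before regressing.
#' @param byDisease split by disease column (for SMEL tables).
#' @return data.frame with columns method, structure, (disease,) axis_pair,
#'   slope, se, p, r2, signed_fit, n.
#' @export
regressionTable <- function(tab, throughOrigin = FALSE, uniqueOnly = FALSE,
                            byDisease = "disease" %in% names(tab)) {
  prefix <- if ("s1" %in% names(tab)) "s" else "v"
  cols <- paste0(prefix, 1:3)
  stopifnot(all(cols %in% names(tab)))
  keys <- c("method", "structure", if (byDisease) "disease")
  groups <- unique(tab[, keys, drop = FALSE])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(tab))
    for (k in keys) {
      gv <- groups[[k]][g]
      sel <- sel & (if (is.na(gv)) is.na(tab[[k]]) else
                      !is.na(tab[[k]]) & tab[[k]] == gv)
    }
    sub <- tab[sel, cols, drop = FALSE]
    if (uniqueOnly) sub <- unique(round(sub, 10))
    scale <- max(abs(as.matrix(sub)))
    for (ap in .AXIS_PAIRS) {
      cc <- .axisColumns(ap, prefix)
      a <- sub[[cc[1]]]; b <- sub[[cc[2]]]
      base <- groups[g, , drop = FALSE]
      row <- data.frame(base, axis_pair = ap, slope = NA_real_,
                        se = NA_real_, p = NA_real_, r2 = NA_real_,
                        signed_fit = NA_real_, n = nrow(sub),
                        row.names = NULL)
      if (!.axisDegenerate(a, scale) && !.axisDegenerate(b, scale)) {
        r <- pairwiseRegression(a, b, throughOrigin = throughOrigin,
                                axisPair = ap)
        row$slope <- r@slope; row$se <- r@se; row$p <- r@pValue
        row$r2 <- r@r2; row$signed_fit <- r@signedFit; row$n <- r@n
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two regression slopes by k-sigma intervals
#'
#' Two slopes differ significantly at level k when the intervals
#' slope +/- k * SE do not overlap. Significance is monotone non-increasing
#' in k.
#'
#' @param r1,r2 \linkS4class{AxisRegression} objects for the same axis pair.
#' @param k sigma multiplier (1, 2 or 3).
#' @return TRUE if the intervals are disjoint (significant difference).
#' @export
compareSlopes <- function(r1, r2, k) {
  stopifnot(is(r1, "AxisRegression"), is(r2, "AxisRegression"))
  if (r1@axisPair != r2@axisPair)
    stop("axis pairs differ: ", r1@axisPair, " vs ", r2@axisPair)
  if (!k %in% c(1, 2, 3)) stop("k must be 1, 2 or 3")
  (r1@slope + k * r1@se < r2@slope - k * r2@se) ||
    (r2@slope + k * r2@se < r1@slope - k * r1@se)
}

#' Disease discrimination by slope intervals
#'
#' For every method/structure and axis pair, regresses each disease's SMEL
#' points (through the origin by default), tests every disease pair for
#' non-overlapping slope +/- k*SE intervals, and marks the axis pair "o"
#' when every pair differs significantly, "x" otherwise, and NA when the
#' axis pair is undefined for the method/structure (degenerate component,
#' e.g. the z axis of Structure A field scores).
#'
#' @param smelTab SMEL table from \code{\link{smelTable}} (needs >= 2
#'   diseases, each with >= 3 points).
#' @param k sigma multiplier (1, 2 or 3), may be a vector.
#' @param throughOrigin passed to the per-disease regressions.
#' @param axisPairs subset of c("x-y", "y-z", "z-x").
#' @return list with \code{decisions} (method, structure, axis_pair, k,
#'   mark) and \code{pairwise} (one row per disease pair and axis pair and
#'   k with the boolean verdict and both slopes/SEs).
#' @export
diseaseDiscrimination <- function(smelTab, k = 2, throughOrigin = TRUE,
                                  axisPairs = .AXIS_PAIRS) {
  stopifnot(all(axisPairs %in% .AXIS_PAIRS))
  diseases <- unique(smelTab$disease)
  if (length(diseases) < 2L) stop("need at least 2 diseases")
  reg <- regressionTable(smelTab, throughOrigin = throughOrigin,
                         byDisease = TRUE)
  groups <- unique(reg[, c("method", "structure")])
  decisions <- list(); pairwise <- list()
  dpairs <- utils::combn(as.character(diseases), 2)
  for (g in seq_len(nrow(groups))) {
    m <- groups$method[g]; st <- groups$structure[g]
    sel <- reg$method == m &
      (if (is.na(st)) is.na(reg$structure) else
         !is.na(reg$structure) & reg$structure == st)
    sub <- reg[sel, ]
    for (ap in axisPairs) {
      rows <- sub[sub$axis_pair == ap, ]
      for (kk in k) {
        if (anyNA(rows$slope)) {
          mark <- NA_character_
        } else {
          allSig <- TRUE
          for (p in seq_len(ncol(dpairs))) {
            r1 <- rows[rows$disease == dpairs[1, p], ]
            r2 <- rows[rows$disease == dpairs[2, p], ]
            sig <- (r1$slope + kk * r1$se < r2$slope - kk * r2$se) ||
              (r2$slope + kk * r2$se < r1$slope - kk * r1$se)
            pairwise[[length(pairwise) + 1L]] <- data.frame(
              method = m, structure = st, axis_pair = ap, k = kk,
              disease1 = dpairs[1, p], disease2 = dpairs[2, p],
              slope1 = r1$slope, se1 = r1$se, slope2 = r2$slope,
              se2 = r2$se, significant = sig)
            if (!sig) allSig <- FALSE
          }
          mark <- if (allSig) "o" else "x"
        }
        decisions[[length(decisions) + 1L]] <- data.frame(
          method = m, structure = st, axis_pair = ap, k = kk, mark = mark)
      }
    }
  }
  list(decisions = do.call(rbind, decisions),
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL)
}

#' Descending-gap fold-change outlier filter
#'
#' Sorts the FC values in descending order and scans from the largest:
#' while a value is at least twice the next smaller one, it (and everything
#' larger, already removed) is an outlier; the scan stops at the first gap
#' smaller than 2x. Applied to FC data only — log2FC is never filtered.
#'
#' @param fc positive fold-change values.
#' @param scanAll if TRUE, the scan does not stop at the first failing gap:
#'   every value lying above some 2x gap further down the sorted list is
#'   also removed (the alternative, more aggressive reading).
#' @return list with \code{kept} and \code{removed} (values, in the input
#'   order for \code{kept} and descending order for \code{removed}).
#' @examples
#' filterFCOutliers(c(1000, 10, 9, 8))$removed   # 1000
#' @export
filterFCOutliers <- function(fc, scanAll = FALSE) {
  if (!length(fc)) return(list(kept = fc, removed = fc))
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("all FC values must be positive and finite")
  ord <- order(fc, decreasing = TRUE)
  v <- fc[ord]
  nRemove <- 0L
  if (length(v) > 1L) {
    gaps <- v[-length(v)] >= 2 * v[-1]
    if (scanAll) {
      lastGap <- if (any(gaps)) max(which(gaps)) else 0L
      nRemove <- lastGap
    } else {
      firstFail <- which(!gaps)
      nRemove <- if (length(firstFail)) firstFail[1] - 1L else
        sum(gaps)
    }
  }
  removedIdx <- ord[seq_len(nRemove)]
  keep <- rep(TRUE, length(fc))
  keep[removedIdx] <- FALSE
  list(kept = fc[keep], removed = v[seq_len(nRemove)])
}

#' Complete an expression table
#'
#' Ensures each row has both FC and log2FC: when only one is present the
#' other is derived (fc = 2^log2fc, log2fc = log2(fc)). Rows with neither
#' value are an error, reported by row number.
#'
#' @param expression data.frame with columns mirna_id, disease, fc, log2fc
#'   (fc/log2fc may be NA, not both).
#' @return The completed data.frame.
#' @export
completeExpression <- function(expression) {
  need <- c("mirna_id", "disease")
  if (!all(need %in% names(expression)))
    stop("expression table must have columns mirna_id, disease")
  if (!"fc" %in% names(expression)) expression$fc <- NA_real_
  if (!"log2fc" %in% names(expression)) expression$log2fc <- NA_real_
  expression$fc <- as.numeric(expression$fc)
  expression$log2fc <- as.numeric(expression$log2fc)
  both <- is.na(expression$fc) & is.na(expression$log2fc)
  if (any(both))
    stop("rows with neither fc nor log2fc: ",
         paste(which(both), collapse = ", "))
  if (any(!is.na(expression$fc) & expression$fc <= 0))
    stop("fc values must be positive")
  fillLog <- is.na(expression$log2fc)
  expression$log2fc[fillLog] <- log2(expression$fc[fillLog])
  fillFc <- is.na(expression$fc)
  expression$fc[fillFc] <- 2^expression$log2fc[fillFc]
  expression
}
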