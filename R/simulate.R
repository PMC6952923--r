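#' Specification for a synthetic study panel
#'
#' Defines the conditions of a simulated disease expression study:
#' mature-length RNA sequences and, per disease, a set of records with
#' log2FC drawn from a normal distribution and FC = 2^log2FC, optionally
#' with injected extreme FC outliers (heavy right tail), plus a
#' slope-separation factor that biases each disease toward miRNAs with a
#' high second/first-site score ratio so that disease panels acquire
#' distinct SMEL regression slopes.
#'
#' @param nMirna number of simulated miRNA sequences in the pool.
#' @param lengthRange inclusive sequence length bounds (nt).
#' @param baseComposition sampling probabilities for A, C, G, U (sum 1).
#' @param diseases character vector of disease labels.
#' @param nPerDisease records per disease (recycled).
#' @param log2fcMean,log2fcSd per-disease normal parameters of log2FC
#'   (recycled; sd > 0).
#' @param slopeSeparation per-disease factor (recycled): 0 samples miRNAs
#'   uniformly; positive/negative values weight sampling toward miRNAs
#'   whose second-site VS score is high/low relative to the first, pulling
#'   the disease's SMEL slopes apart.
#' @param outlierRate probability that a record's FC is multiplied by
#'   \code{outlierMagnitude} (FC track only; the log2FC track stays
#'   symmetric, which is exactly the pathology the FC outlier filter
#'   addresses).
#' @param outlierMagnitude multiplicative size of an injected FC outlier.
#' @param seed mandatory integer seed.
#' @return A validated list of class \code{SimSpec}.
#' @export
simSpec <- function(nMirna = 300,
                    lengthRange = c(18, 25),
                    baseComposition = c(A = 0.25, C = 0.25, G = 0.25,
                                        U = 0.25),
                    diseases = c("AD", "COPD", "ST", "TB"),
                    nPerDisease = 80,
                    log2fcMean = 0,
                    log2fcSd = 1.5,
                    slopeSeparation = 0,
                    outlierRate = 0.02,
                    outlierMagnitude = 50,
                    seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop("seed is mandatory")
  stopifnot(nMirna >= 1, length(lengthRange) == 2L,
            lengthRange[1] >= 1, lengthRange[2] >= lengthRange[1],
            length(baseComposition) == 4L, all(baseComposition >= 0),
            abs(sum(baseComposition) - 1) < 1e-8,
            length(diseases) >= 1, all(nPerDisease >= 1),
            all(log2fcSd > 0), outlierRate >= 0, outlierRate <= 1,
            outlierMagnitude > 0)
  nd <- length(diseases)
  spec <- list(
    nMirna = as.integer(nMirna),
    lengthRange = as.integer(lengthRange),
    baseComposition = stats::setNames(as.numeric(baseComposition),
                                      c("A", "C", "G", "U")),
    diseases = as.character(diseases),
    nPerDisease = rep_len(as.integer(nPerDisease), nd),
    log2fcMean = rep_len(as.numeric(log2fcMean), nd),
    log2fcSd = rep_len(as.numeric(log2fcSd), nd),
    slopeSeparation = rep_len(as.numeric(slopeSeparation), nd),
    outlierRate = as.numeric(outlierRate),
    outlierMagnitude = as.numeric(outlierMagnitude),
    seed = as.integer(seed))
  class(spec) <- "SimSpec"
  spec
}

#' Simulate mature miRNA sequences
#'
#' Draws \code{nMirna} sequences with lengths uniform on
#' \code{lengthRange} and bases i.i.d. from \code{baseComposition}.
#' Reproducible for a fixed seed.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return Named character vector (ids \code{mir-sim-0001}, ...).
#' @export
simulateSequences <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  lens <- sample(seq(spec$lengthRange[1], spec$lengthRange[2]),
                 spec$nMirna, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                 prob = spec$baseComposition), collapse = ""), character(1))
  names(seqs) <- sprintf("mir-sim-%04d", seq_len(spec$nMirna))
  seqs
}

#' Simulate per-disease expression records
#'
#' For each disease d: sample \code{nPerDisease[d]} miRNAs from the pool
#' with weights \eqn{\exp(sep_d \cdot z)} where z is the standardized
#' second/first-site VS score ratio of each sequence (sep = 0 is uniform
#' sampling), draw log2FC ~ Normal(mean_d, sd_d), set FC = 2^log2FC, and
#' with probability \code{outlierRate} multiply FC by
#' \code{outlierMagnitude} (FC track only).
#'
#' @param spec a \code{\link{simSpec}}.
#' @param sequences named character vector from
#'   \code{\link{simulateSequences}}.
#' @return data.frame with columns mirna_id, disease, fc, log2fc.
#' @export
simulateExpression <- function(spec, sequences) {
  stopifnot(inherits(spec, "SimSpec"), length(sequences) >= 3)
  if (length(spec$diseases) < 2L) stop("need at least 2 diseases")
  set.seed(spec$seed + 1L)
  vs <- t(vapply(sequences, function(s) scoreValues(scoreVS(s)),
                 numeric(3)))
  ratio <- vs[, 2] / vs[, 1]
  z <- as.numeric(scale(ratio))
  if (all(!is.finite(z))) z <- rep(0, length(ratio))  # constant ratio pool
  rows <- list()
  for (d in seq_along(spec$diseases)) {
    nd <- spec$nPerDisease[d]
    w <- exp(spec$slopeSeparation[d] * z)
    pick <- sample(seq_along(sequences), nd,
                   replace = nd > length(sequences), prob = w)
    log2fc <- stats::rnorm(nd, spec$log2fcMean[d], spec$log2fcSd[d])
    fc <- 2^log2fc
    out <- stats::runif(nd) < spec$outlierRate
    fc[out] <- fc[out] * spec$outlierMagnitude
    rows[[d]] <- data.frame(mirna_id = names(sequences)[pick],
                            disease = spec$diseases[d],
                            fc = fc, log2fc = log2fc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full study (sequences + expression)
#'
#' @param spec a \code{\link{simSpec}}.
#' @return list with \code{sequences} (named character) and
#'   \code{expression} (data.frame).
#' @export
simulateStudy <- function(spec) {
  seqs <- simulateSequences(spec)
  list(sequences = seqs, expression = simulateExpression(spec, seqs))
}
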