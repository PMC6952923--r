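# Partial charges (elementary-charge units) at the three hydrogen-bonding
# sites (AUHB) of each nucleobase. Fixed constants of the method; the
# amino-group averaging is already baked into the First-site values.
.AUHB <- data.frame(
  base = c("A", "U", "G", "C"),
  e1   = c(0.417, -0.506, -0.490, 0.379),
  e2   = c(-0.514, 0.408, 0.414, -0.558),
  e3   = c(0.228, -0.471, 0.413, -0.476),
  stringsAsFactors = FALSE
)

#' Hydrogen-bonding-site charge table
#'
#' The per-nucleobase partial charges at the First, Second and Third
#' hydrogen-bonding sites that encode a base as a charge triple. These are
#' fixed constants of the method (elementary-charge units, used here as
#' dimensionless values).
#'
#' @return A data.frame with columns \code{base} (A, U, G, C) and \code{e1},
#'   \code{e2}, \code{e3} (charge at the First/Second/Third site).
#' @examples
#' chargeTable()
#' @export
chargeTable <- function() .AUHB

#' Normalize an RNA sequence string
#'
#' Uppercases, maps T to U (DNA-alphabet FASTA tolerance; one warning per
#' call), and rejects any other symbol (including ambiguity codes) naming the
#' offending character and its position.
#'
#' @param sequence a single character string.
#' @param warnT emit a warning when T is encountered (default TRUE).
#' @return The normalized A/C/G/U string.
#' @export
normalizeRNA <- function(sequence, warnT = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  s <- toupper(sequence)
  if (grepl("T", s, fixed = TRUE)) {
    if (warnT) warning("T normalized to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .AUHB$base)
  if (length(bad))
    stop(sprintf("invalid nucleobase symbol '%s' at position %d",
                 chars[bad[1]], bad[1]))
  s
}

#' Charge triple of one nucleobase
#'
#' @param base a single nucleobase code (A, C, G or U; lowercase accepted, T
#'   mapped to U).
#' @return Named numeric triple \code{(e1, e2, e3)}: the charge at the
#'   First, Second and Third hydrogen-bonding site.
#' @examples
#' chargeVector("A")   # c(e1 = 0.417, e2 = -0.514, e3 = 0.228)
#' @export
chargeVector <- function(base) {
  b <- normalizeRNA(base, warnT = FALSE)
  if (nchar(b) != 1L) stop("base must be a single character")
  row <- .AUHB[.AUHB$base == b, ]
  c(e1 = row$e1, e2 = row$e2, e3 = row$e3)
}

#' Ternary-vector encoding of a sequence
#'
#' Encodes an RNA sequence of length n as the 3n-element site-major charge
#' vector: all First-site charges in sequence order, then all Second-site,
#' then all Third-site charges.
#'
#' @param sequence RNA string (nonempty; T tolerated and mapped to U).
#' @return A \linkS4class{TernaryVector}.
#' @examples
#' tv <- ternaryVector("AU")
#' elementVector(tv)  # 0.417 -0.506 -0.514 0.408 0.228 -0.471
#' @export
ternaryVector <- function(sequence) {
  s <- normalizeRNA(sequence)
  n <- nchar(s)
  if (n == 0L) stop("sequence must be nonempty")
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .AUHB$base)
  new("TernaryVector", sequence = s,
      elements = c(.AUHB$e1[idx], .AUHB$e2[idx], .AUHB$e3[idx]),
      n = as.integer(n))
}

#' @rdname accessors
#' @export
setMethod("elementVector", "TernaryVector", function(x) x@elements)

#' @rdname accessors
#' @export
setMethod("rnaSequence", "TernaryVector", function(x) x@sequence)

# 3 x n matrix: row i is the site-i slice in sequence order.
#' @rdname accessors
#' @export
setMethod("siteMatrix", "TernaryVector", function(x) {
  m <- matrix(x@elements, nrow = 3L, ncol = x@n, byrow = TRUE)
  rownames(m) <- c("First", "Second", "Third")
  m
})

#' Export / read the charge table as TSV
#'
#' Writes the charge constants to a tab-separated file (machine-readable
#' documentation of the encoding) and reads such a file back. The round trip
#' is bit-exact.
#'
#' @param path file path.
#' @return \code{exportChargeTable} returns \code{path} invisibly;
#'   \code{readChargeTable} returns the data.frame.
#' @export
exportChargeTable <- function(path) {
  utils::write.table(.AUHB, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname exportChargeTable
#' @export
readChargeTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", rep("numeric", 3)),
                          stringsAsFactors = FALSE)
  df
}
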