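# Independent oracles, deliberately naive: plain scalar loops over the
# printed formulas, sharing no code with the package's vectorized paths.

# Table of charges typed independently of the package constants.
oracleCharges <- list(
  A = c(0.417, -0.514, 0.228),
  U = c(-0.506, 0.408, -0.471),
  G = c(-0.490, 0.414, 0.413),
  C = c(0.379, -0.558, -0.476))

# Electric field at point p: triple loop over the structure's site table.
bruteField <- function(struct, p) {
  df <- struct@sites
  out <- c(0, 0, 0)
  for (r in seq_len(nrow(df))) {
    dx <- p[1] - df$x[r]; dy <- p[2] - df$y[r]; dz <- p[3] - df$z[r]
    d2 <- dx * dx + dy * dy + dz * dz
    if (d2 < 1e-18) next
    den <- d2^1.5
    out <- out + df$charge[r] * c(dx, dy, dz) / den
  }
  out
}

# EV_S: quadruple loop, rebuilding the grid values from the bounding box
# (index a in -5..5 maps to min + (a+5)(max-min)/10).
bruteEVS <- function(struct) {
  df <- struct@sites
  lo <- c(min(df$x), min(df$y), min(df$z))
  hi <- c(max(df$x), max(df$y), max(df$z))
  out <- c(0, 0, 0)
  for (k in -5:5) for (l in -5:5) for (m in -5:5) {
    p <- c(lo[1] + (k + 5) * (hi[1] - lo[1]) / 10,
           lo[2] + (l + 5) * (hi[2] - lo[2]) / 10,
           lo[3] + (m + 5) * (hi[3] - lo[3]) / 10)
    out <- out + bruteField(struct, p)
  }
  out
}

# Textbook OLS: slope, slope SE, two-sided p of the slope t-test, r2.
bruteOLS <- function(a, b, throughOrigin = FALSE) {
  n <- length(a)
  if (throughOrigin) {
    slope <- sum(a * b) / sum(a * a)
    res <- b - slope * a
    df <- n - 1
    se <- sqrt(sum(res^2) / df / sum(a * a))
    r2 <- 1 - sum(res^2) / sum(b^2)
  } else {
    am <- mean(a); bm <- mean(b)
    sxx <- sum((a - am)^2)
    slope <- sum((a - am) * (b - bm)) / sxx
    inter <- bm - slope * am
    res <- b - inter - slope * a
    df <- n - 2
    se <- sqrt(sum(res^2) / df / sxx)
    r2 <- 1 - sum(res^2) / sum((b - bm)^2)
  }
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df)
  list(slope = slope, se = se, p = p, r2 = r2)
}

# Random RNA string.
randomSeq <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

# SMEL table built directly from given per-disease slopes: disease points
# (t, slope*t + noise, 0.5*t) for t = 1..n.
syntheticSmelTable <- function(slopes, n = 20, noise = 0,
                               method = "VS", structure = NA_character_) {
  rows <- lapply(seq_along(slopes), function(i) {
    t <- seq_len(n)
    data.frame(id = paste0("m", t), disease = names(slopes)[i],
               method = method, structure = structure, x = 1,
               s1 = t, s2 = slopes[i] * t + noise * stats::rnorm(n),
               s3 = 0.5 * t)
  })
  do.call(rbind, rows)
}
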