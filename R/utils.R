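# internal helpers shared across modules

# residual sum of squares of y on design X via rank-revealing QR
# X may be rank deficient (founder dosage columns sum to 1); the projection
# uses only the numerically independent columns, i.e. a pseudoinverse fit
.rss <- function(y, X) {
  qx <- qr(X)
  r <- qr.resid(qx, y)
  sum(r^2)
}

# LOD = (n/2) log10(RSS0/RSS1); guards the saturated / degenerate cases
.lod_from_rss <- function(rss0, rss1, n) {
  if (rss0 <= .Machine$double.eps * n) return(0)
  rss1 <- max(rss1, rss0 * 1e-12)
  (n / 2) * log10(rss0 / rss1)
}

# matricize a samples x founders x markers array to samples x (founders*markers)
.flatten_probs <- function(probs) {
  d <- dim(probs)
  matrix(probs, nrow = d[1], ncol = d[2] * d[3])
}

# interpolate between the cM and Mbp coordinate systems of one chromosome,
# extrapolating linearly at the ends (map positions are monotone)
.interp_pos <- function(from, to, x) {
  if (length(from) == 1L) return(rep(to[1], length(x)))
  slope_lo <- (to[2] - to[1]) / (from[2] - from[1])
  k <- length(from)
  slope_hi <- (to[k] - to[k - 1]) / (from[k] - from[k - 1])
  out <- approx(from, to, xout = x, rule = 2)$y
  lo <- x < from[1]
  hi <- x > from[k]
  out[lo] <- to[1] + (x[lo] - from[1]) * slope_lo
  out[hi] <- to[k] + (x[hi] - from[k]) * slope_hi
  out
}

cm_to_mbp <- function(map, chr, cM) {
  mm <- map[map$chr == chr, ]
  .interp_pos(mm$cM, mm$Mbp, cM)
}

mbp_to_cm <- function(map, chr, Mbp) {
  mm <- map[map$chr == chr, ]
  .interp_pos(mm$Mbp, mm$cM, Mbp)
}

.check_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chr", "cM", "Mbp") %in% names(map)))
  if (nrow(map) == 0L) stop("marker map is empty")
  for (ch in unique(map$chr)) {
    mm <- map[map$chr == ch, ]
    if (any(diff(mm$cM) <= 0) || any(diff(mm$Mbp) <= 0))
      stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  invisible(map)
}

# seeds derived from a master seed stay valid 32-bit integers
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9176) %% 2147483647L)
}
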