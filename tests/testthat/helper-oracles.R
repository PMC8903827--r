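# Independent oracles, deliberately coded apart from the package paths they
# check.

# sRGB (8-bit) -> CIELAB from the published equations: IEC 61966-2-1 transfer,
# sRGB primaries to XYZ (D65), CIE 1976 L*a*b* with the 2-degree observer
# D65 white.
oracle_srgb_to_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(m %*% lin)
  white <- c(0.95047, 1.00000, 1.08883)
  t <- xyz / white
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# Brute-force per-pixel ROI colorimetry: explicit loops, no vectorized reuse
# of the package's pixel plumbing.
oracle_roi_mean_lab <- function(img, mask) {
  acc <- c(0, 0, 0)
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        acc <- acc + oracle_srgb_to_lab(as.numeric(unclass(img)[i, j, ]))
        n <- n + 1L
      }
    }
  }
  acc / n
}

# Brute-force area-average downscale of a single channel: per output pixel,
# integrate the source over its pre-image rectangle.
oracle_box_resample <- function(ch, out_h, out_w) {
  in_h <- nrow(ch); in_w <- ncol(ch)
  sy <- in_h / out_h; sx <- in_w / out_w
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      y0 <- (i - 1) * sy; y1 <- i * sy
      x0 <- (j - 1) * sx; x1 <- j * sx
      tot <- 0
      for (r in (floor(y0) + 1):min(ceiling(y1), in_h)) {
        for (cc in (floor(x0) + 1):min(ceiling(x1), in_w)) {
          oy <- min(y1, r) - max(y0, r - 1)
          ox <- min(x1, cc) - max(x0, cc - 1)
          if (oy > 0 && ox > 0) tot <- tot + ch[r, cc] * oy * ox
        }
      }
      out[i, j] <- tot / (sy * sx)
    }
  }
  out
}

# Direct maximum-likelihood logistic regression: Bernoulli log-likelihood
# maximized with BFGS and an analytic gradient.
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    eta <- as.vector(X %*% b)
    -as.vector(t(X) %*% (y - stats::plogis(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  opt$par
}
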