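# Independent oracles used by the test suite. These deliberately do not call
# package internals: each re-derives the quantity from first principles.

# Exact 1-D total variation denoising, Condat's direct non-iterative
# algorithm (running taut-string with segment fusion). O(n) worst case for
# the sizes used here.
condat_tvd <- function(y, lam) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (lam <= 0) return(y)
  x <- numeric(n)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam; vmax <- y[1] + lam
  umin <- lam; umax <- -lam
  repeat {
    if (k == n) { x[k] <- vmin + umin; break }
    if (y[k + 1] + umin < vmin - lam) {        # negative jump ends a segment
      x[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]; vmax <- y[k] + 2 * lam
      umin <- lam; umax <- -lam
    } else if (y[k + 1] + umax > vmax + lam) { # positive jump ends a segment
      x[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lam; vmax <- y[k]
      umin <- lam; umax <- -lam
    } else {
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lam) { vmin <- vmin + (umin - lam) / (k - k0 + 1L); umin <- lam; km <- k }
      if (umax <= -lam) { vmax <- vmax + (umax + lam) / (k - k0 + 1L); umax <- -lam; kp <- k }
    }
    if (k == n) {
      if (umin < 0) {
        x[k0:km] <- vmin; k <- k0 <- km <- km + 1L
        vmin <- y[k]; umin <- lam; umax <- y[k] + lam - vmax
      } else if (umax > 0) {
        x[k0:kp] <- vmax; k <- k0 <- kp <- kp + 1L
        vmax <- y[k]; umax <- -lam; umin <- y[k] - lam - vmin
      } else { x[k0:n] <- vmin + umin / (k - k0 + 1L); break }
    }
  }
  x
}

tv_objective <- function(x, y, lam) 0.5 * sum((y - x)^2) + lam * sum(abs(diff(x)))

# Periodogram band-energy fractions (FFT oracle), band edges [lo, hi) in Hz
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lo & f < hi]) / sum(p)
}

# Explicit dense matrix of one periodized analysis level (rows = shifted
# filters, stride 2); stacking [G; H] must be orthogonal for even n.
dwt_level_matrix <- function(n, g, h) {
  stopifnot(n %% 2L == 0L)
  m <- n %/% 2L
  G <- matrix(0, m, n); H <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_along(g)) {
      col <- (2L * (i - 1L) + j - 1L) %% n + 1L
      G[i, col] <- G[i, col] + g[j]
      H[i, col] <- H[i, col] + h[j]
    }
  }
  list(G = G, H = H)
}

# Direct circular correlation + downsample-by-2 (brute-force definition of
# one analysis step), independent of the vectorized implementation.
direct_dwt_level <- function(s, filt) {
  n <- length(s)
  m <- n %/% 2L
  a <- numeric(m); d <- numeric(m)
  for (i in seq_len(m)) {
    for (j in seq_along(filt$g)) {
      v <- s[(2L * (i - 1L) + j - 1L) %% n + 1L]
      a[i] <- a[i] + filt$g[j] * v
      d[i] <- d[i] + filt$h[j] * v
    }
  }
  list(approx = a, detail = d)
}

# Mean of a normal truncated below at 0 (closed form)
truncnorm0_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

# Small labelled feature table with a prescribed 1-D separation, for
# classifier unit tests that do not need signal processing.
fake_feature_table <- function(delta_normal, delta_enceph) {
  part <- function(prefix, group, delta) {
    if (length(delta) == 0L) return(NULL)
    data.frame(epoch_id = sprintf("%s%03d", prefix, seq_along(delta)),
               group = group, delta_pct = delta)
  }
  df <- rbind(part("n", "normal", delta_normal),
              part("e", "encephalopathy", delta_enceph))
  df$theta_pct <- 10; df$alpha_pct <- 10; df$beta_pct <- 10
  df$residual_pct <- 0
  class(df) <- c("feature_table", class(df))
  df
}

# Small synthetic cohort shared by several test files
tiny_cohort <- function(n_per_group = 10L, seed = 420L, fs = 500,
                        duration_s = 2) {
  generate_cohort(generator_params(
    n_epochs = c(encephalopathy = n_per_group, normal = n_per_group),
    fs = fs, duration_s = duration_s, seed = seed))
}
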