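# Naive brute-force references for every encoder, written directly from the
# defining equations with explicit loops. They return plain data frames of
# events; expect_train_matches() compares them event-for-event against the
# package's spike_train output.

oracle_events <- function(t, ch, pol) {
  df <- data.frame(t = as.numeric(t), ch = as.integer(ch), pol = as.integer(pol))
  df[order(df$t, df$ch), , drop = FALSE]
}

expect_train_matches <- function(st, df) {
  expect_equal(st$times, df$t, tolerance = 1e-12)
  expect_equal(st$channels, df$ch)
  expect_equal(st$polarities, df$pol)
}

oracle_tbr <- function(sig, gamma) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  t <- c(); ch <- c(); pol <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    s <- sig$samples[c_i, ]
    v <- numeric(L - 1)
    for (i in seq_len(L - 1)) v[i] <- s[i + 1] - s[i]
    m <- sum(v) / length(v)
    st_dev <- sqrt(sum((v - m)^2) / length(v))
    thr <- m + gamma * st_dev
    for (i in seq_len(L - 1)) {
      if (abs(v[i]) > thr) {
        t <- c(t, i * dt); ch <- c(ch, c_i); pol <- c(pol, if (v[i] > 0) 1L else -1L)
      }
    }
  }
  oracle_events(t, ch, pol)
}

oracle_mw <- function(sig, window) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  t <- c(); ch <- c(); pol <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    s <- sig$samples[c_i, ]
    av <- numeric(L - 1)
    for (i in seq_len(L - 1)) av[i] <- abs(s[i + 1] - s[i])
    thr <- sum(av) / length(av)
    base_init <- sum(s[1:window]) / window
    for (i in seq_len(L)) {
      base <- if (i <= window) base_init else sum(s[(i - window):(i - 1)]) / window
      if (s[i] > base + thr) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i); pol <- c(pol, 1L)
      } else if (s[i] < base - thr) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i); pol <- c(pol, -1L)
      }
    }
  }
  oracle_events(t, ch, pol)
}

oracle_sf_threshold <- function(sig, gamma) {
  jumps <- numeric(nrow(sig$samples))
  for (c_i in seq_len(nrow(sig$samples))) {
    jumps[c_i] <- max(sig$samples[c_i, ]) - min(sig$samples[c_i, ])
  }
  (sum(jumps) / length(jumps)) / gamma
}

oracle_sf <- function(sig, gamma) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  thr <- oracle_sf_threshold(sig, gamma)
  t <- c(); ch <- c(); pol <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    s <- sig$samples[c_i, ]
    base <- s[1]
    for (i in 2:L) {
      if (s[i] > base + thr) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i); pol <- c(pol, 1L)
        base <- base + thr
      } else if (s[i] < base - thr) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i); pol <- c(pol, -1L)
        base <- base - thr
      }
    }
  }
  oracle_events(t, ch, pol)
}

oracle_zcsf <- function(sig, gamma) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  thr <- oracle_sf_threshold(sig, gamma)
  t <- c(); ch <- c(); pol <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    s <- sig$samples[c_i, ]
    for (i in seq_len(L)) {
      if (s[i] > 0 && s[i] > thr) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i); pol <- c(pol, 1L)
      }
    }
  }
  oracle_events(t, ch, pol)
}

# deconvolution family, direct transcription of the subtractive procedure
oracle_deconv <- function(sig, kernel, mode, threshold = NULL) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  w <- length(kernel)
  t <- c(); ch <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    s <- sig$samples[c_i, ]
    for (i in seq_len(L)) {
      jmax <- min(w, L - i + 1)
      emit <- FALSE
      if (mode == "hsa") {
        ok <- TRUE
        for (j in seq_len(jmax)) if (s[i + j - 1] < kernel[j]) { ok <- FALSE; break }
        emit <- ok
      } else if (mode == "mhsa") {
        err <- 0
        for (j in seq_len(jmax)) {
          if (kernel[j] > s[i + j - 1]) err <- err + (kernel[j] - s[i + j - 1])
        }
        emit <- err <= threshold
      } else {
        e1 <- 0; e2 <- 0
        for (j in seq_len(jmax)) {
          e1 <- e1 + abs(s[i + j - 1] - kernel[j])
          e2 <- e2 + abs(s[i + j - 1])
        }
        emit <- e1 <= e2 * threshold
      }
      if (emit) {
        t <- c(t, (i - 1) * dt); ch <- c(ch, c_i)
        for (j in seq_len(jmax)) s[i + j - 1] <- s[i + j - 1] - kernel[j]
      }
    }
  }
  oracle_events(t, ch, rep(1L, length(t)))
}

# rectify + min-max normalization shared by the oracle encoders below
oracle_unit <- function(s) {
  v <- s
  for (i in seq_along(v)) if (v[i] < 0) v[i] <- 0
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(0, length(v)))
  (v - lo) / (hi - lo)
}

# fractional bits via repeated doubling (independent of the bit-shift form)
oracle_bits <- function(v, beta) {
  if (v >= 1) return(rep(1L, beta))
  if (v > 1 - 2^(-beta)) v <- 1 - 2^(-beta)
  bits <- integer(beta)
  u <- v
  for (k in seq_len(beta)) {
    u <- u * 2
    bits[k] <- if (u >= 1) 1L else 0L
    if (u >= 1) u <- u - 1
  }
  bits
}

oracle_phase <- function(sig, beta) {
  L <- ncol(sig$samples); dt_sub <- sig$duration / (L * beta)
  t <- c(); ch <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    v <- oracle_unit(sig$samples[c_i, ])
    for (i in seq_len(L)) {
      if (v[i] <= 0) next
      bits <- oracle_bits(v[i], beta)
      for (k in seq_len(beta)) {
        if (bits[k] == 1L) {
          t <- c(t, ((i - 1) * beta + (k - 1)) * dt_sub); ch <- c(ch, c_i)
        }
      }
    }
  }
  oracle_events(t, ch, rep(1L, length(t)))
}

oracle_ttfs <- function(sig, theta0 = 1, tau_th = 0.1, n_grid = 64) {
  L <- ncol(sig$samples); g <- sig$duration / n_grid
  t <- c(); ch <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    v <- oracle_unit(sig$samples[c_i, ])
    for (i in seq_len(L)) {
      if (v[i] <= 0) next
      t_star <- -tau_th * log(v[i])
      k <- 0
      while (k * g < t_star - 1e-12 * g) k <- k + 1
      tt <- k * g
      if (tt <= sig$duration + 1e-12) {
        t <- c(t, min(tt, sig$duration)); ch <- c(ch, c_i)
      }
    }
  }
  oracle_events(t, ch, rep(1L, length(t)))
}

oracle_burst <- function(sig, n_max, t_min, t_max) {
  L <- ncol(sig$samples); dt <- sig$duration / L
  t <- c(); ch <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    rate <- oracle_unit(sig$samples[c_i, ])
    for (i in seq_len(L)) {
      n_sp <- ceiling(rate[i] * n_max)
      if (n_sp < 1) next
      isi <- if (n_sp > 1) ceiling(t_max - rate[i] * (t_max - t_min)) else t_max
      for (k in seq_len(n_sp)) {
        tt <- (i - 1) * dt + (k - 1) * isi * dt
        if (tt <= sig$duration + 1e-12) {
          t <- c(t, min(tt, sig$duration)); ch <- c(ch, c_i)
        }
      }
    }
  }
  oracle_events(t, ch, rep(1L, length(t)))
}

# Poisson reference: re-draws the same seeded uniform stream and applies the
# inverse-CDF inter-spike interval formula ISI = -log(1 - x) / r
oracle_poisson_rate <- function(sig, rate, seed) {
  set.seed(seed)
  t <- c(); ch <- c()
  for (c_i in seq_len(nrow(sig$samples))) {
    r <- if (length(rate) > 1) rate[c_i] else rate
    if (r > 0) {
      tt <- 0
      repeat {
        tt <- tt - log(1 - runif(1)) / r
        if (tt > sig$duration) break
        t <- c(t, tt); ch <- c(ch, c_i)
      }
    }
  }
  oracle_events(t, ch, rep(1L, length(t)))
}

# refractory reference: sequential drop of events closer than tau_ref
oracle_refractory <- function(df, n_channels, tau_ref) {
  keep <- logical(nrow(df))
  last <- rep(-Inf, n_channels)
  for (k in seq_len(nrow(df))) {
    if (df$t[k] - last[df$ch[k]] >= tau_ref) {
      keep[k] <- TRUE
      last[df$ch[k]] <- df$t[k]
    }
  }
  df[keep, , drop = FALSE]
}

# random test signal: mix of smooth and rough channels
random_signal <- function(L, n_ch, fs = L) {
  m <- matrix(0, nrow = n_ch, ncol = L)
  for (c_i in seq_len(n_ch)) {
    m[c_i, ] <- if (c_i %% 2 == 0) cumsum(rnorm(L, sd = 0.3)) else rnorm(L)
  }
  as_signal(m, fs = fs)
}
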