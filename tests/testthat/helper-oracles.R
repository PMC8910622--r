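# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops / direct DFT sums, sharing
# no code with the package implementations they check.

oracle_time_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  sk <- sum((x - mu)^3) / (n * s^3)
  ku <- sum((x - mu)^4) / (n * s^4) - 3
  xc <- x - mu
  nz <- 0
  for (i in 1:(n - 1)) if (xc[i] * xc[i + 1] < 0) nz <- nz + 1
  d1 <- 0
  for (i in 1:(n - 1)) d1 <- d1 + abs(x[i + 1] - x[i])
  d1 <- d1 / (n - 1)
  d2 <- 0
  for (i in 1:(n - 2)) d2 <- d2 + abs(x[i + 2] - x[i])
  d2 <- d2 / (n - 2)
  fd <- x[-1] - x[-n]
  sd1 <- sqrt(sum((fd - mean(fd))^2) / (n - 1))
  sdd_seq <- fd[-1] - fd[-(n - 1)]
  sd2 <- sqrt(sum((sdd_seq - mean(sdd_seq))^2) / (n - 2))
  c(T1 = max(x) - min(x), T2 = mu, T3 = v, T4 = s,
    T5 = stats::median(x), T6 = sk, T7 = ku, T8 = max(x), T9 = min(x),
    T10 = nz / (n - 1), T11 = d1 / s, T12 = d2 / s,
    T13 = v, T14 = sd1 / s, T15 = (sd2 / sd1) / (sd1 / s))
}

# Band power over [lo, hi) from an explicit two-sided DFT sum.
oracle_band_power <- function(x, lo, hi, fs = 100) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  freqs <- ks * fs / n
  sel <- ks[freqs >= lo & freqs < hi]
  total <- 0
  for (k in sel) {
    ck <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    total <- total + Mod(ck / n)^2
  }
  total
}

oracle_nsi <- function(x, fraction = 0.15) {
  n <- length(x)
  m <- floor(fraction * n)
  q <- n %/% m; r <- n %% m
  lens <- c(rep(q + 1, r), rep(q, m - r))
  means <- numeric(m)
  pos <- 0
  for (k in 1:m) {
    means[k] <- mean(x[(pos + 1):(pos + lens[k])])
    pos <- pos + lens[k]
  }
  sqrt(mean((means - mean(means))^2))
}

# Sample entropy by direct pair counting over template starts 1..N-m
# (vectorized over j for speed, still a literal transcription of the
# definition).
oracle_sampen <- function(x, m = 2, r_coeff = 0.2) {
  n <- length(x)
  r <- r_coeff * sqrt(mean((x - mean(x))^2))
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    js <- (i + 1):nt
    dmax <- abs(x[i] - x[js])
    for (k in 1:(m - 1)) dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
    hit <- dmax <= r
    B <- B + sum(hit)
    A <- A + sum(pmax(dmax, abs(x[i + m] - x[js + m]))[hit] <= r)
  }
  -log(A / B)
}

oracle_higuchi <- function(x, kmax = floor(length(x) / 20)) {
  n <- length(x)
  Hbar <- numeric(kmax)
  for (k in 1:kmax) {
    lens <- numeric(k)
    for (m in 1:k) {
      cnt <- floor((n - m) / k)
      tot <- 0
      for (i in 1:cnt) tot <- tot + abs(x[m + i * k] - x[m + (i - 1) * k])
      lens[m] <- tot * (n - 1) / (cnt * k^2)
    }
    Hbar[k] <- mean(lens)
  }
  fit <- stats::lm(log(Hbar) ~ log(1:kmax))
  -unname(stats::coef(fit)[2])
}

oracle_confusion <- function(truth, estimate) {
  st <- sleep_stages()
  m <- matrix(0L, 5, 5, dimnames = list(st, st))
  for (i in seq_along(truth)) {
    m[as.character(truth[i]), as.character(estimate[i])] <-
      m[as.character(truth[i]), as.character(estimate[i])] + 1L
  }
  m
}
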