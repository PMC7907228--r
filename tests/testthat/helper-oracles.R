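# Independent naive-loop oracles. These deliberately re-derive every
# quantity from its defining sum, without reusing package internals.

rand_slice <- function(M, N = M) matrix(runif(M * N), M, N)

# population variance by explicit loop
naive_pop_var <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  s <- 0
  for (v in x) s <- s + (v - m)^2 / n
  s
}

# central-difference gradient magnitudes by explicit indexing
naive_gradient_mag <- function(I) {
  M <- nrow(I); N <- ncol(I)
  out <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    dx <- if (j == 1) I[i, 2] - I[i, 1] else if (j == N) I[i, N] - I[i, N - 1] else
      (I[i, j + 1] - I[i, j - 1]) / 2
    dy <- if (i == 1) I[2, j] - I[1, j] else if (i == M) I[M, j] - I[M - 1, j] else
      (I[i + 1, j] - I[i - 1, j]) / 2
    out[i, j] <- sqrt(dx^2 + dy^2)
  }
  out
}

# 4-neighbor Laplacian with replicate padding by explicit indexing
naive_laplacian <- function(I) {
  M <- nrow(I); N <- ncol(I)
  out <- matrix(0, M, N)
  cl <- function(i, n) min(max(i, 1), n)
  for (i in 1:M) for (j in 1:N) {
    out[i, j] <- I[cl(i - 1, M), j] + I[cl(i + 1, M), j] +
      I[i, cl(j - 1, N)] + I[i, cl(j + 1, N)] - 4 * I[i, j]
  }
  out
}

# histogram on [0,1]: loop-based binning
naive_hist <- function(x, bins) {
  f <- integer(bins)
  for (v in x) {
    k <- min(floor(v * bins) + 1, bins)
    f[k] <- f[k] + 1
  }
  f
}

naive_histogram_threshold <- function(x, bins = 256L) {
  thr <- sum(x) / length(x)
  thr_bin <- min(floor(thr * bins) + 1, bins)
  f <- naive_hist(x, bins)
  s <- 0
  for (k in seq_len(bins)) {
    if (k > thr_bin) s <- s + (k - 0.5) / bins * f[k]
  }
  s
}

naive_histogram_entropy <- function(x, bins = 256L) {
  f <- naive_hist(x, bins)
  hmax <- max(f)
  s <- 0
  for (k in seq_len(bins)) {
    if (f[k] > 0) {
      p <- f[k] / hmax
      s <- s - p * log2(p)
    }
  }
  s
}

# direct evaluation of the defining DFT sum, one (u, v) at a time
naive_dft <- function(I) {
  M <- nrow(I); N <- ncol(I)
  m <- matrix(rep(0:(M - 1), N), M)
  n <- matrix(rep(0:(N - 1), each = M), M)
  F <- matrix(0 + 0i, M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
    F[u + 1, v + 1] <- sum(I * exp(-2i * pi * (u * m / M + v * n / N)))
  }
  F
}

centered_index <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, (half - n + 1):-1)
}

naive_frequency_threshold <- function(I, r) {
  F <- naive_dft(I)
  u <- centered_index(nrow(I)); v <- centered_index(ncol(I))
  s <- 0
  for (i in seq_along(u)) for (j in seq_along(v)) {
    if (u[i]^2 + v[j]^2 > r^2) s <- s + Mod(F[i, j])
  }
  s
}

# nested-loop bivariate kurtosis of the normalized periodogram
naive_periodogram_kurtosis <- function(I) {
  F <- naive_dft(I)
  A <- Mod(F * Conj(F))
  h <- A / sum(A)
  u <- centered_index(nrow(I)); v <- centered_index(ncol(I))
  mu_u <- 0; mu_v <- 0
  for (i in seq_along(u)) for (j in seq_along(v)) {
    mu_u <- mu_u + u[i] * h[i, j]
    mu_v <- mu_v + v[j] * h[i, j]
  }
  s2u <- 0; s2v <- 0; suv <- 0
  for (i in seq_along(u)) for (j in seq_along(v)) {
    s2u <- s2u + (u[i] - mu_u)^2 * h[i, j]
    s2v <- s2v + (v[j] - mu_v)^2 * h[i, j]
    suv <- suv + (u[i] - mu_u) * (v[j] - mu_v) * h[i, j]
  }
  su <- sqrt(s2u); sv <- sqrt(s2v)
  gam <- function(k, l) {
    s <- 0
    for (i in seq_along(u)) for (j in seq_along(v)) {
      s <- s + h[i, j] * (u[i] - mu_u)^k * (v[j] - mu_v)^l
    }
    s / (su^k * sv^l)
  }
  rho <- suv / (su * sv)
  (gam(4, 0) + gam(0, 4) + 2 * gam(2, 2) +
      4 * rho * (rho * gam(2, 2) - gam(1, 3) - gam(3, 1))) / (1 - rho^2)^2
}

# exhaustive Otsu: try every cut point, maximize between-class variance
naive_otsu <- function(x, bins = 256L) {
  f <- naive_hist(x, bins)
  centers <- (seq_len(bins) - 0.5) / bins
  n <- sum(f)
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(bins - 1)) {
    n0 <- sum(f[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(f[1:k] * centers[1:k]) / n0
    mu1 <- sum(f[(k + 1):bins] * centers[(k + 1):bins]) / n1
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; best_k <- k }
  }
  if (is.na(best_k)) NA_real_ else best_k / bins
}

# textbook Pearson correlation as an explicit sum
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# small reusable phantom for tests that just need plausible slices
small_phantom <- function(q = 0.5, seed = 1, n_slices = 16) {
  generate_phantom(phantom_spec(width = 96L, height = 96L, n_slices = n_slices,
                                spheroid_radius = 38, n_nuclei = 90L,
                                clearing_quality = q, seed = seed))
}
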