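# Brute-force oracles, coded independently of the package implementation:
# explicit loops over sequence pairs and sites, no shared helpers.

brute_pi <- function(mat, L) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2) / L
}

brute_theta_w <- function(S, n, L) {
  a <- 0
  for (i in 1:(n - 1)) a <- a + 1 / i
  S / (a * L)
}

# Tajima (1989) constants, written out from the published formulas
brute_tajima_d <- function(mat) {
  n <- nrow(mat)
  cs <- colSums(mat)
  S <- sum(cs > 0 & cs < n)
  if (S == 0) return(NA_real_)
  pitot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    pitot <- pitot + sum(mat[i, ] != mat[j, ])
  pitot <- pitot / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pitot - S / a1) / sqrt(v)
}

brute_dxy <- function(mx, my, L) {
  tot <- 0
  for (i in seq_len(nrow(mx))) for (j in seq_len(nrow(my)))
    tot <- tot + sum(mx[i, ] != my[j, ])
  tot / (nrow(mx) * nrow(my)) / L
}

brute_da <- function(mx, my, L)
  brute_dxy(mx, my, L) - (brute_pi(mx, L) + brute_pi(my, L)) / 2

brute_fst <- function(mx, my, L) {
  piw <- (brute_pi(mx, L) + brute_pi(my, L)) / 2
  pit <- brute_pi(rbind(mx, my), L)
  if (pit <= 0) return(NA_real_)
  1 - piw / pit
}

brute_abba_baba <- function(m1, m2, m3) {
  num <- den <- 0
  for (s in seq_len(ncol(m1))) {
    p1 <- mean(m1[, s]); p2 <- mean(m2[, s]); p3 <- mean(m3[, s])
    num <- num + (1 - p1) * p2 * p3 - p1 * (1 - p2) * p3
    den <- den + (1 - p1) * p2 * p3 + p1 * (1 - p2) * p3
  }
  if (den <= 0) return(NA_real_)
  num / den
}

brute_patterns <- function(mx, my) {
  ss <- sf <- sxx <- sxy <- 0
  for (s in seq_len(ncol(mx))) {
    ax <- unique(mx[, s]); ay <- unique(my[, s])
    px <- length(ax) > 1; py <- length(ay) > 1
    if (px && py) ss <- ss + 1
    else if (px) sxx <- sxx + 1
    else if (py) sxy <- sxy + 1
    else if (ax != ay) sf <- sf + 1
  }
  c(ss = ss, sf = sf, sx_x = sxx, sx_y = sxy)
}

# random SNP matrix where every column is segregating in the pooled sample
random_pooled_matrix <- function(n, S) {
  repeat {
    m <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    cs <- colSums(m)
    if (all(cs > 0 & cs < n)) return(m)
  }
}
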