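# small deterministic builders shared across test files

make_grid <- function(onsets, played = TRUE, durations = NULL) {
  n <- length(onsets)
  if (is.null(durations))
    durations <- c(diff(onsets), if (n > 1) diff(onsets)[n - 1] else 0.5)
  g <- data.frame(step_index = seq_len(n), onset_s = onsets,
                  duration_s = durations, bar = (seq_len(n) + 1L) %/% 2L,
                  played = rep_len(played, n))
  class(g) <- c("beat_grid", "data.frame")
  g
}

# uniform-tempo grid covering the default passages
quick_grid <- function(seed = 1, cv = 0.062, drift = 0.02) {
  generate_beat_grid(tempo_config(cv = cv, drift_amplitude = drift), seed,
                     default_passages())
}

# definitional Pearson at a lag, written independently of the package path
naive_lagged_r <- function(head, bow, lag_ms, rate = 100) {
  l <- round(lag_ms * rate / 1000)
  n <- length(head)
  hi <- seq(max(1, 1 + l), min(n, n + l))
  h <- head[hi]; b <- bow[hi - l]
  hm <- sum(h) / length(h); bm <- sum(b) / length(b)
  sum((h - hm) * (b - bm)) /
    sqrt(sum((h - hm)^2) * sum((b - bm)^2))
}

# random 3D rotation matrix
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# outward half-space description of a convex hull by brute-force facet
# enumeration over all point triples (independent oracle)
brute_halfspaces <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  hs <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
    nv <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    d <- drop(pts %*% nv) - sum(nv * pts[i, ])
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      sgn <- if (sum(nv * ctr) - sum(nv * pts[i, ]) < 0) 1 else -1
      hs[[length(hs) + 1]] <- c(sgn * nv, sgn * sum(nv * pts[i, ]))
    }
  }
  do.call(rbind, hs)
}

mc_hull_volume <- function(pts, n_samples = 200000) {
  hs <- brute_halfspaces(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  samp <- cbind(runif(n_samples, lo[1], hi[1]),
                runif(n_samples, lo[2], hi[2]),
                runif(n_samples, lo[3], hi[3]))
  inside <- rep(TRUE, n_samples)
  for (r in seq_len(nrow(hs)))
    inside <- inside & (drop(samp %*% hs[r, 1:3]) <= hs[r, 4] + 1e-9)
  mean(inside) * prod(hi - lo) / 1000   # cm^3
}

# independent permutation oracle for the replicated Friedman p-value
perm_oracle_p <- function(x, n_draws = 10000) {
  nb <- dim(x)[1]; m <- dim(x)[2]; k <- dim(x)[3]; N <- m * k
  obs <- friedman_replicated(x)$chi2
  ranks <- lapply(seq_len(nb), function(i) rank(as.vector(x[i, , ])))
  V <- sum(vapply(ranks, function(r)
    m * (N - m) / (N - 1) * mean((r - (N + 1) / 2)^2), numeric(1)))
  E <- nb * m * (N + 1) / 2
  chis <- replicate(n_draws, {
    S <- Reduce(`+`, lapply(ranks, function(r)
      colSums(matrix(sample(r), m, k))))
    (k - 1) / k * sum((S - E)^2) / V
  })
  mean(chis >= obs - 1e-12)
}
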