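# Independent brute-force oracles and small fixtures, kept deliberately
# naive (explicit loops, no reuse of package internals).

# Loop-based evaluation of each time-domain statistic.
brute_feature <- function(x, method, eps = 0.02) {
  n <- length(x)
  switch(method,
    MAV = {
      s <- 0; for (v in x) s <- s + abs(v); s / n
    },
    IEMG = {
      s <- 0; for (v in x) s <- s + abs(v); s
    },
    RMS = {
      s <- 0; for (v in x) s <- s + v^2; sqrt(s / n)
    },
    SSI = {
      s <- 0; for (v in x) s <- s + v^2; s
    },
    MV = sum(x) / n,
    VAR = {
      m <- sum(x) / n
      s <- 0; for (v in x) s <- s + (v - m)^2; s / n
    },
    WL = {
      s <- 0
      for (i in seq_len(n - 1)) s <- s + abs(x[i + 1] - x[i])
      s
    },
    MPV = {
      m <- 0; for (v in x) if (abs(v) > m) m <- abs(v); m
    },
    SSC = {
      cnt <- 0
      for (i in 2:(n - 1)) {
        if (x[i] > x[i - 1] && x[i] > x[i + 1] && (x[i] - x[i + 1]) >= eps) {
          cnt <- cnt + 1
        }
      }
      cnt
    },
    stop("no oracle for ", method))
}

# Batch mean and population covariance of a sample stream (rows).
batch_moments <- function(X) {
  m <- colMeans(X)
  centered <- sweep(X, 2, m)
  list(mean = m, cov = crossprod(centered) / nrow(X))
}

# Exhaustive evaluation of one greedy mRMR step: the candidate maximizing
# MI(f;C) - mean MI(f; selected), ties alphabetical.
brute_mrmr_step <- function(relevance, redundancy, selected) {
  remaining <- sort(setdiff(names(relevance), selected))
  best <- NULL; best_gain <- -Inf
  for (f in remaining) {
    red <- if (length(selected) == 0) 0 else mean(redundancy[f, selected])
    gain <- relevance[[f]] - red
    if (gain > best_gain) { best_gain <- gain; best <- f }
  }
  best
}

# Least-squares sinusoid amplitude on a filtered mid-section.
fitted_amplitude <- function(y, f, fs) {
  n <- length(y)
  idx <- seq(round(n / 4), round(3 * n / 4))
  tt <- (idx - 1) / fs
  co <- stats::lm(y[idx] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt) - 1)
  sqrt(sum(stats::coef(co)^2))
}

# Small 3-gesture synthetic dataset (fast fixture).
small_profiles <- function() {
  list(A = gesture_profile("A", c(0.4, 0.8, 0.4)),
       B = gesture_profile("B", c(1.0, 0.5, 0.6)),
       C = gesture_profile("C", c(0.6, 0.6, 1.1)))
}

small_dataset <- function(seed = 5, trials = 2, duration = 1000,
                          noise = 0.05) {
  cfg <- emg_sim_config(trial_duration = duration, trials_per_gesture = trials,
                        noise_floor = noise, seed = seed)
  generate_dataset(small_profiles(), cfg, "S1")
}

# Ten well-separated 3-D Gaussian blobs: 30 train / 10 test per class,
# centers on a lattice with spacing 8 sigma.
make_blobs <- function(seed = 42, sigma = 0.5, n_train = 30, n_test = 10) {
  set.seed(seed)
  grid <- expand.grid(x = c(0, 4, 8), y = c(0, 4, 8), z = c(0, 4))
  centers <- as.matrix(grid[seq_len(10), ])
  tr_x <- NULL; tr_y <- character(0); te_x <- NULL; te_y <- character(0)
  for (k in seq_len(10)) {
    pts <- matrix(stats::rnorm((n_train + n_test) * 3, sd = sigma),
                  ncol = 3, byrow = TRUE)
    pts <- sweep(pts, 2, centers[k, ], "+")
    tr_x <- rbind(tr_x, pts[seq_len(n_train), ])
    te_x <- rbind(te_x, pts[n_train + seq_len(n_test), ])
    tr_y <- c(tr_y, rep(paste0("G", k), n_train))
    te_y <- c(te_y, rep(paste0("G", k), n_test))
  }
  list(train_x = tr_x, train_y = tr_y, test_x = te_x, test_y = te_y)
}
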