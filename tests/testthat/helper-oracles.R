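# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, brute force, grid search) kept separate from
# the package's code paths.

# Exhaustive grid search over (kprod, kdec) with the residual term pinned,
# refined by zooming on the best cell. Same objective definition as the
# fitter but an entirely independent minimiser.
grid_fit_oracle <- function(t, y, dose, fres_scaled, eps = 1e-6,
                            n = 40, rounds = 4,
                            kp_range = NULL, kd_range = c(0.02, 5)) {
  if (is.null(kp_range)) {
    kp_range <- c(1e-4, max(50 * max(abs(y)) / dose, 1))
  }
  best <- NULL
  for (r in seq_len(rounds)) {
    kp <- exp(seq(log(kp_range[1]), log(kp_range[2]), length.out = n))
    kd <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n))
    sse <- matrix(NA_real_, n, n)
    ly <- log(pmax(y, eps))
    for (j in seq_len(n)) {
      base <- dose * t * exp(-kd[j] * t)
      m <- outer(kp, base) + fres_scaled
      sse[, j] <- rowSums((log(pmax(m, eps)) - rep(ly, each = n))^2)
    }
    idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    best <- list(kprod = kp[i], kdec = kd[j], sse = sse[i, j])
    kp_range <- c(kp[max(i - 1, 1)], kp[min(i + 1, n)])
    kd_range <- c(kd[max(j - 1, 1)], kd[min(j + 1, n)])
  }
  best
}

# All-pairs concordance AUC by explicit double loop (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  y <- as.integer(labels)
  cs <- scores[y == 1]; ct <- scores[y == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Two-sided Fisher p by hypergeometric enumeration at fixed margins.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(xs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Exact Mann-Whitney two-sided p by enumeration of all rank assignments
# (no ties, small samples).
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y); nn <- nx + ny
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- combn(nn, nx)
  us <- apply(sets, 2, function(s) sum(s) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Paired bootstrap test of the AUC difference of two score vectors.
paired_bootstrap_auc_test <- function(sa, sb, labels, n_boot = 10000, seed = 1) {
  y <- as.integer(labels)
  n <- length(y)
  rank_auc <- function(s, yy) {
    r <- rank(s); n1 <- sum(yy == 1)
    (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
  }
  d_obs <- rank_auc(sa, y) - rank_auc(sb, y)
  set.seed(seed)
  ds <- vapply(seq_len(n_boot), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    rank_auc(sa[idx], y[idx]) - rank_auc(sb[idx], y[idx])
  }, 0)
  # two-sided p: does the bootstrap distribution of the difference cross 0?
  p <- 2 * min(mean(ds <= 0), mean(ds >= 0))
  list(d = d_obs, p = min(1, p))
}

# Noiseless five-point normalized series straight from the kinetic model.
model_series <- function(kprod, kdec, fres_scaled, dose = 3,
                         times = c(1, 2, 3, 6, 20)) {
  tibble::tibble(
    time_hr = times,
    signal_norm = eval_repair_model(kprod, kdec, fres_scaled / dose,
                                    dose = dose, time = times, irradiated = 1))
}

# Small planted-signal classification fixture: one informative feature,
# `n_noise` independent noise features.
planted_fixture <- function(n = 200, n_noise = 5, sd_signal = 0.1, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  feats <- tibble::tibble(signal = y + rnorm(n, 0, sd_signal))
  for (k in seq_len(n_noise)) feats[[paste0("noise", k)]] <- rnorm(n)
  list(features = feats, labels = y)
}
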