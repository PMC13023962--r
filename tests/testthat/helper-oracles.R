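# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (lm, welch_psd, aggregate_region) so that each
# check is a genuine two-route comparison.

# brute-force weighted least squares: iteratively refined grid search over
# (intercept, slope), never touching lm()
grid_wls <- function(x, y, w = rep(1, length(x)), iters = 30) {
  sse <- function(a, b) sum(w * (y - a - b * x)^2)
  # start from coarse bounds around the data scale
  a0 <- mean(y); b0 <- 0
  ra <- max(abs(y - mean(y))) * 4 + 1
  rb <- (max(abs(y - mean(y))) / max(diff(range(x)), 1e-6)) * 4 + 1
  for (it in seq_len(iters)) {
    as <- seq(a0 - ra, a0 + ra, length.out = 21)
    bs <- seq(b0 - rb, b0 + rb, length.out = 21)
    g <- outer(as, bs, Vectorize(sse))
    ij <- arrayInd(which.min(g), dim(g))
    a0 <- as[ij[1]]; b0 <- bs[ij[2]]
    ra <- ra * 0.25; rb <- rb * 0.25
  }
  c(intercept = a0, slope = b0)
}

# closed-form OLS via explicit sums (textbook formulas)
ols_closed_form <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# full-length raw-periodogram log-log slope, closed-form regression;
# independent of welch_psd and of the fitting module
periodogram_slope <- function(x, fs) {
  n <- length(x)
  X <- fft(x - mean(x))
  nh <- n %/% 2
  f <- (1:nh) * fs / n
  p <- (2 / (fs * n)) * Mod(X[2:(nh + 1)])^2
  lx <- log10(f); ly <- log10(p)
  unname(ols_closed_form(lx, ly)["slope"])
}

# direct pooled per-bin mean / population SD over a list of psd vectors
pooled_moments <- function(psds) {
  m <- Reduce(`+`, psds) / length(psds)
  v <- Reduce(`+`, lapply(psds, function(p) (p - m)^2)) / length(psds)
  list(mean = m, sd = sqrt(v))
}

# one-way ANOVA F statistic from explicit sums (no aov/lm)
fstat_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ssb <- sum(ng * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# permutation p-value for the one-way layout
perm_anova_p <- function(values, groups, nperm = 499) {
  f0 <- fstat_oneway(values, groups)
  hits <- sum(vapply(seq_len(nperm), function(i)
    fstat_oneway(sample(values), groups) >= f0, logical(1)))
  (hits + 1) / (nperm + 1)
}

# band mean power computed directly from a psd vector (masked mean)
masked_band_mean <- function(freq, psd, f_lo, f_hi) {
  mean(psd[freq > 0 & freq >= f_lo & freq <= f_hi])
}

# small synthetic spectrum_estimate built by hand for unit tests
fake_spectrum <- function(psd_fun, fs = 200, nfft = 2048) {
  freq <- (0:(nfft / 2)) * fs / nfft
  psd <- psd_fun(freq)
  psd[1] <- psd[2]          # finite DC placeholder
  structure(list(freq = freq, psd = psd, fs = fs,
                 settings = list(nperseg = nfft, nfft = nfft, overlap = 0.5,
                                 window = "hamming", detrend = "constant",
                                 n_segments = 1),
                 meta = list(subject_id = NA, region = NA, channel_id = NA,
                             history = "synthetic")),
            class = "spectrum_estimate")
}

# cohort assembled by hand from given channels (bypasses simulate_cohort)
manual_cohort <- function(channels, truth) {
  structure(list(channels = channels, truth = truth,
                 spec = list(regions = data.frame(region = unique(truth$region)),
                             n_subjects = length(unique(truth$subject_id)),
                             n_channels = max(table(truth$subject_id)),
                             between_sd = NA, within_sd = NA,
                             duration_s = length(channels[[1]]$samples) / channels[[1]]$fs,
                             fs = channels[[1]]$fs, peak = NULL, seed = NA)),
            class = "eeg_cohort")
}

# convenience: welch then masked band mean on a raw vector
masked_band_mean_welch <- function(x, fs, f_lo, f_hi) {
  sp <- welch_psd(x, nperseg = min(2048L, length(x)), fs = fs)
  masked_band_mean(sp$freq, sp$psd, f_lo, f_hi)
}
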