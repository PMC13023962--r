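# Cohort statistics: per-subject exponent tables, region ANOVA and Tukey
# HSD, exponent-gamma-power correlation, exponent-age regression, and the
# filter/FFT robustness sweep.

default_filter_for <- function(bd) {
  if (bd$f_hi <= 12) filter_spec("lowpass") else filter_spec("highpass")
}

#' Per-subject exponent estimates across a cohort
#'
#' Fits every channel of every subject in the requested band (after the
#' band's isolation filter) and reports, per subject, the mean channel
#' exponent and the within-subject standard error (SD of channel
#' exponents divided by sqrt of the channel count; 0 for single-channel
#' subjects). These are the replicate units for the region-discrimination
#' statistics: using subject means rather than raw channels avoids
#' pseudo-replication from correlated channels within a subject.
#'
#' @param cohort an `eeg_cohort` (from [simulate_cohort()] or the
#'   readers).
#' @param bd the analysis [band()] (default high band).
#' @param filter the isolation [filter_spec()]; defaults to the band's
#'   matched filter (lowpass for the low band, highpass for the high
#'   band).
#' @param ... further arguments for [specslope()] (Welch settings,
#'   `compensate`).
#' @return a data.frame with columns `subject_id`, `region`, `band`,
#'   `beta_hat`, `within_se`, `n_channels`, `age`, `sex`.
#' @export
per_subject_betas <- function(cohort, bd = band_high(), filter = NULL,
                              ...) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  filter <- filter %||% default_filter_for(bd)
  beta <- vapply(cohort$channels, function(ch)
    abs(specslope(ch, band = bd, filter = filter, ...)$beta), numeric(1))
  info <- cohort$truth
  out <- lapply(split(seq_along(beta), info$subject_id), function(idx) {
    b <- beta[idx]
    data.frame(subject_id = info$subject_id[idx[1]],
               region = info$region[idx[1]], band = bd$name,
               beta_hat = mean(b),
               within_se = if (length(b) > 1) stats::sd(b) / sqrt(length(b)) else 0,
               n_channels = length(b),
               age = info$age[idx[1]], sex = info$sex[idx[1]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$region, out$subject_id), ]
}

check_records <- function(records) {
  need <- c("region", "beta_hat")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_field("records", "must be a data.frame with columns region, beta_hat")
  counts <- table(records$region)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("excluding region(s) with < 2 subjects: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    records <- records[!records$region %in% small, ]
  }
  if (length(unique(records$region)) < 2L)
    stop("need at least 2 regions with >= 2 subjects each", call. = FALSE)
  records$region <- factor(records$region)
  records
}

#' One-way region ANOVA on subject exponents
#'
#' Fixed-effects one-way analysis of variance of per-subject exponent
#' estimates grouped by region, asking whether the scale-free exponent
#' differs across brain regions. Regions with fewer than 2 subjects are
#' excluded with a warning.
#'
#' @param records a data.frame as returned by [per_subject_betas()] or
#'   [simulate_beta_records()].
#' @return an object of class `region_anova`: list with `F`,
#'   `df_between`, `df_within`, `p_value`, `n`, and the underlying
#'   `stats::aov` fit.
#' @export
region_anova <- function(records) {
  records <- check_records(records)
  fit <- stats::aov(beta_hat ~ region, data = records)
  tab <- summary(fit)[[1]]
  structure(
    list(F = tab[1, "F value"], df_between = as.integer(tab[1, "Df"]),
         df_within = as.integer(tab[2, "Df"]), p_value = tab[1, "Pr(>F)"],
         n = nrow(records), fit = fit),
    class = "region_anova")
}

#' @export
print.region_anova <- function(x, ...) {
  cat(sprintf("<region_anova> F(%d, %d) = %.2f, p = %.3g (n = %d subjects)\n",
              x$df_between, x$df_within, x$F, x$p_value, x$n))
  invisible(x)
}

#' Tukey HSD pairwise region comparisons
#'
#' Studentized-range post hoc comparisons between all region pairs after
#' the one-way region ANOVA, controlling the family-wise error rate.
#'
#' @inheritParams region_anova
#' @param alpha significance level for the `significant` flag.
#' @return a data.frame with one row per region pair: `region_i`,
#'   `region_j`, `diff`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(records, alpha = 0.05) {
  av <- region_anova(records)
  tk <- stats::TukeyHSD(av$fit, conf.level = 1 - alpha)$region
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    region_i = vapply(pairs, `[`, character(1), 1),
    region_j = vapply(pairs, `[`, character(1), 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], significant = tk[, "p adj"] < alpha)
  rownames(out) <- NULL
  out
}

#' Correlation between region exponents and gamma-band power
#'
#' Pearson correlation (with the two-sided t-based p-value) between the
#' per-region high-band exponent and the per-region mean normalized
#' gamma-band PSD, testing whether the scale-free slope merely tracks
#' gamma power.
#'
#' @param region_betas,region_gamma paired numeric vectors (one value per
#'   region, n >= 3).
#' @return an object of class `beta_gamma_cor`: list with `r`, `p_value`,
#'   `n`.
#' @export
beta_gamma_correlation <- function(region_betas, region_gamma) {
  if (length(region_betas) != length(region_gamma))
    stop_field("region_gamma", "must pair one value with each region exponent")
  keep <- is.finite(region_betas) & is.finite(region_gamma)
  b <- region_betas[keep]; g <- region_gamma[keep]
  if (length(b) < 3L) stop("need >= 3 paired region values", call. = FALSE)
  if (stats::sd(b) == 0 || stats::sd(g) == 0)
    stop("zero variance in exponents or gamma power", call. = FALSE)
  ct <- stats::cor.test(b, g, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(b)),
            class = "beta_gamma_cor")
}

#' @export
print.beta_gamma_cor <- function(x, ...) {
  cat(sprintf("<beta_gamma_cor> r = %.3f, p = %.3g (n = %d regions)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Exponent-age regression within a region
#'
#' Ordinary least-squares regression of per-subject exponents on age,
#' with a 95% confidence interval on the slope, for checking age trends
#' of the scale-free exponent.
#'
#' @param records a data.frame with columns `beta_hat` and `age`
#'   (typically one region's rows from [per_subject_betas()]).
#' @param level confidence level for the slope interval.
#' @return list with `slope`, `intercept`, `slope_ci` (length 2),
#'   `p_value`, `n`.
#' @export
beta_age_regression <- function(records, level = 0.95) {
  if (!all(c("beta_hat", "age") %in% names(records)))
    stop_field("records", "must have columns beta_hat and age")
  keep <- is.finite(records$beta_hat) & is.finite(records$age)
  d <- records[keep, ]
  if (nrow(d) < 3L) stop("need >= 3 subjects with ages", call. = FALSE)
  if (stats::sd(d$age) == 0) stop("all ages are identical", call. = FALSE)
  fit <- stats::lm(beta_hat ~ age, data = d)
  ci <- quiet_perfect_fit(stats::confint(fit, "age", level = level))
  sm <- quiet_perfect_fit(summary(fit))
  list(slope = unname(stats::coef(fit)["age"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       slope_ci = as.numeric(ci),
       p_value = sm$coefficients["age", 4], n = nrow(d))
}

#' Robustness sweep over filter and FFT parameters
#'
#' Re-runs the band's exponent estimation under all combinations of
#' cutoff frequency, filter order and FFT length, and summarizes how much
#' the per-region exponents move. Per band the default grid is 2 cutoffs
#' x 2 orders x 3 FFT lengths = 12 configurations. When a high-pass
#' cutoff lies above the band's lower edge, the fitted band starts at the
#' cutoff (and symmetrically, a low-pass cutoff below the band's upper
#' edge truncates it): fitting inside the filter's stopband would be
#' meaningless. Configurations whose FFT length exceeds the signal length
#' are skipped with a warning.
#'
#' Region exponents per configuration come from the weighted fit on the
#' region-aggregated spectrum; the homogeneity test is a one-way ANOVA of
#' per-subject exponents with configuration as the factor, per region.
#'
#' @param cohort an `eeg_cohort`.
#' @param bands list of [band()]s to sweep (default both analysis bands).
#' @param lowpass_cutoffs,highpass_cutoffs cutoff grids (Hz).
#' @param orders filter order grid.
#' @param nffts FFT length grid (`nperseg = nfft`).
#' @param ... further arguments for [specslope()].
#' @return an object of class `sweep_result`: list with `table`
#'   (data.frame: band, cutoff, order, nfft, region, beta_hat),
#'   `subject_table` (per-subject exponents per configuration) and
#'   `summary` (per band and region: `max_abs_diff` across
#'   configurations and the homogeneity `p_value`).
#' @export
robustness_sweep <- function(cohort, bands = list(band_low(), band_high()),
                             lowpass_cutoffs = c(4, 8),
                             highpass_cutoffs = c(33, 50),
                             orders = c(5, 7), nffts = c(256, 1024, 2048),
                             ...) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  nmin <- min(vapply(cohort$channels, length, integer(1)))
  tab <- list(); stab <- list()
  for (bd in bands) {
    low <- bd$f_hi <= 12
    cutoffs <- if (low) lowpass_cutoffs else highpass_cutoffs
    for (cut in cutoffs) for (ord in orders) for (nfft in nffts) {
      if (nfft > nmin) {
        warning(sprintf("skipping nfft = %d: exceeds signal length %d", nfft, nmin),
                call. = FALSE)
        next
      }
      fspec <- filter_spec(if (low) "lowpass" else "highpass",
                           cutoff = cut, order = ord)
      fit_band <- if (low) band(bd$f_lo, min(bd$f_hi, cut), bd$name)
                  else band(max(bd$f_lo, cut), bd$f_hi, bd$name)
      # per-channel spectra of the filtered signals
      spectra <- lapply(cohort$channels, function(ch)
        welch_psd(apply_filter(ch, fspec), nperseg = nfft, nfft = nfft))
      by_region <- split(spectra, cohort$truth$region)
      for (reg in names(by_region)) {
        rs <- aggregate_region(by_region[[reg]], region = reg)
        bhat <- abs(specslope(rs, band = fit_band, filter = fspec, ...)$beta)
        tab[[length(tab) + 1L]] <- data.frame(
          band = bd$name, cutoff = cut, order = ord, nfft = nfft,
          region = reg, beta_hat = bhat)
      }
      # per-subject exponents for the homogeneity test
      bchan <- vapply(spectra, function(sp)
        abs(specslope(sp, band = fit_band, filter = fspec, ...)$beta),
        numeric(1))
      bs <- tapply(bchan, cohort$truth$subject_id, mean)
      reg_of <- tapply(as.character(cohort$truth$region),
                       cohort$truth$subject_id, `[`, 1)
      stab[[length(stab) + 1L]] <- data.frame(
        band = bd$name, cutoff = cut, order = ord, nfft = nfft,
        subject_id = names(bs), region = unname(reg_of[names(bs)]),
        beta_hat = unname(bs))
    }
  }
  tab <- do.call(rbind, tab)
  stab <- do.call(rbind, stab)
  rownames(tab) <- rownames(stab) <- NULL
  smry <- do.call(rbind, lapply(split(tab, tab[c("band", "region")], drop = TRUE),
    function(d) {
      s <- stab[stab$band == d$band[1] & stab$region == d$region[1], ]
      s$config <- interaction(s$cutoff, s$order, s$nfft)
      p <- if (nlevels(droplevels(s$config)) > 1)
        summary(stats::aov(beta_hat ~ config, data = s))[[1]][1, "Pr(>F)"]
      else NA_real_
      data.frame(band = d$band[1], region = d$region[1],
                 n_configs = nrow(d),
                 max_abs_diff = max(d$beta_hat) - min(d$beta_hat),
                 p_homogeneity = p)
    }))
  rownames(smry) <- NULL
  structure(list(table = tab, subject_table = stab, summary = smry),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d configuration x region rows\n", nrow(x$table)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
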