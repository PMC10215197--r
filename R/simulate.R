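# Multiplicative log-normal noise with a given CV, median 1.
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sigma))
}

#' Simulate competition-profiling (isoTOP) replicate observations
#'
#' For each site, condition, and replicate, emits light and heavy channel
#' areas whose expected ratio is `1 / (1 - f_total(dose))`, where `f_total`
#' is the site's total (reversible + irreversible) oxidized fraction at the
#' condition's dose. Channel areas carry independent multiplicative
#' log-normal noise of the stated CV. A site is missing from a condition
#' with probability `1 - detect_isotop`, each replicate additionally drops
#' out with probability `dropout_rate`, and sites whose true `f_total`
#' reaches the full-oxidation censoring threshold are never emitted (fully
#' oxidized cysteines are invisible to competition profiling).
#'
#' @param truth data.frame from [simulate_truth()].
#' @param condition_doses Named numeric vector mapping condition label to
#'   dose in mM (e.g. `c(H2O2_1mM = 1, H2O2_10mM = 10)`).
#' @param n_replicates Replicates per condition (>= 1).
#' @param noise_cv Channel-level coefficient of variation (>= 0).
#' @param dropout_rate Per-replicate missingness probability.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param cap Ratio cap passed to [compute_ratio()].
#' @param censor_threshold Sites with `f_total >=` this are emitted as
#'   missing (default 0.98).
#' @param base_area Median channel area at zero oxidation (arbitrary
#'   intensity units).
#' @return data.frame of per-replicate observations: `site_id`,
#'   `protein_id`, `residue`, `condition`, `replicate`, `light_area`,
#'   `heavy_area`, `ratio_LH`, `capped`.
#' @export
simulate_isotop <- function(truth, condition_doses, n_replicates = 2L,
                            noise_cv = 0.2, dropout_rate = 0.05, seed = 1L,
                            cap = 20, censor_threshold = 0.98,
                            base_area = 1e6) {
  stopifnot(noise_cv >= 0, all(condition_doses >= 0),
            !is.null(names(condition_doses)))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  # detection is a per-site property: one draw per run, shared across
  # conditions, so the observed site set is stable along the dose series
  detected <- stats::runif(nrow(truth)) < truth$detect_isotop
  out <- vector("list", length(condition_doses))
  for (ci in seq_along(condition_doses)) {
    cond <- names(condition_doses)[ci]
    f_tot <- oxidized_fraction(truth, condition_doses[[ci]])
    keep <- detected & f_tot < censor_threshold
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      present <- keep & (stats::runif(nrow(truth)) >= dropout_rate)
      n <- sum(present)
      la <- base_area * .ln_noise(n, noise_cv)
      ha <- base_area * (1 - f_tot[present]) * .ln_noise(n, noise_cv)
      rat <- compute_ratio(la, ha, cap = cap)
      rows[[r]] <- data.frame(
        site_id = truth$site_id[present],
        protein_id = truth$protein_id[present],
        residue = truth$residue[present],
        condition = rep(cond, n), replicate = rep(r, n),
        light_area = la, heavy_area = ha,
        ratio_LH = rat$ratio_LH, capped = rat$capped,
        stringsAsFactors = FALSE
      )
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate differential-alkylation (OxICAT) replicate observations
#'
#' In differential alkylation the light channel measures the reduced pool
#' and the heavy channel the reversibly oxidized pool of a single sample:
#' channel proportions are `L` proportional to `1 - f_rev - f_irr` and `H`
#' proportional to `f_rev`. Irreversibly oxidized molecules accept neither
#' label, so they silently inflate the apparent percent oxidation to
#' `100 * f_rev / (1 - f_irr)`. Detection follows `detect_oxicat`,
#' independent of the competition platform.
#'
#' @inheritParams simulate_isotop
#' @param n_replicates Replicates per condition (default 3).
#' @return data.frame as in [simulate_isotop()] plus an `orientation`
#'   column (always `"LH"`: light = reduced, heavy = oxidized).
#' @export
simulate_oxicat <- function(truth, condition_doses, n_replicates = 3L,
                            noise_cv = 0.2, dropout_rate = 0.05, seed = 1L,
                            cap = 20, base_area = 1e6) {
  stopifnot(noise_cv >= 0, all(condition_doses >= 0),
            !is.null(names(condition_doses)))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  # per-site detection draw, as in the competition simulator
  detected <- stats::runif(nrow(truth)) < truth$detect_oxicat
  out <- vector("list", length(condition_doses))
  for (ci in seq_along(condition_doses)) {
    cond <- names(condition_doses)[ci]
    f_tot <- oxidized_fraction(truth, condition_doses[[ci]])
    f_irr <- truth$firr_frac * f_tot
    f_rev <- f_tot - f_irr
    if (any(f_rev + f_irr > 1 + 1e-12)) {
      stop("truth has f_rev + f_irr > 1", call. = FALSE)
    }
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      present <- detected & (stats::runif(nrow(truth)) >= dropout_rate)
      n <- sum(present)
      la <- base_area * (1 - f_rev[present] - f_irr[present]) *
        .ln_noise(n, noise_cv)
      ha <- base_area * f_rev[present] * .ln_noise(n, noise_cv)
      rat <- compute_ratio(la, ha, cap = cap)
      ok <- !is.na(rat$ratio_LH)
      rows[[r]] <- data.frame(
        site_id = truth$site_id[present][ok],
        protein_id = truth$protein_id[present][ok],
        residue = truth$residue[present][ok],
        condition = rep(cond, sum(ok)), replicate = rep(r, sum(ok)),
        light_area = la[ok], heavy_area = ha[ok],
        ratio_LH = rat$ratio_LH[ok], capped = rat$capped[ok],
        orientation = rep("LH", sum(ok)),
        stringsAsFactors = FALSE
      )
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate paired extracted-ion-chromatogram traces for observations
#'
#' Each observation becomes a pair of Gaussian elution peaks (light and
#' heavy channels) sharing one apex time (co-elution), each with area equal
#' to the observation's channel area, sampled on a regular time grid
#' spanning the apex plus/minus `span_sigmas` peak widths, with optional
#' additive Gaussian baseline noise (negative values clamped to 0).
#'
#' @param observations data.frame from [simulate_isotop()] or
#'   [simulate_oxicat()].
#' @param peak_sigma Gaussian peak width (seconds, > 0).
#' @param sampling_interval Grid spacing (seconds, > 0, < `peak_sigma`).
#' @param seed Integer RNG seed (apex times, baseline noise).
#' @param baseline_sd Additive baseline noise standard deviation
#'   (intensity units; default 0 = clean traces).
#' @param span_sigmas Half-width of the emitted window in peak sigmas.
#' @return Long-format data.frame: `site_id`, `condition`, `replicate`,
#'   `channel` (`LIGHT`/`HEAVY`), `time_s`, `intensity`.
#' @export
simulate_chromatograms <- function(observations, peak_sigma = 2,
                                   sampling_interval = 0.05, seed = 1L,
                                   baseline_sd = 0, span_sigmas = 5) {
  stopifnot(peak_sigma > 0, sampling_interval > 0)
  if (sampling_interval >= peak_sigma) {
    stop("sampling_interval must be smaller than the peak width",
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(observations)
  apex <- stats::runif(n, 60, 600)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- seq(apex[i] - span_sigmas * peak_sigma,
              apex[i] + span_sigmas * peak_sigma,
              by = sampling_interval)
    shape <- exp(-(tt - apex[i])^2 / (2 * peak_sigma^2)) /
      (peak_sigma * sqrt(2 * pi))
    li <- observations$light_area[i] * shape
    hi <- observations$heavy_area[i] * shape
    if (baseline_sd > 0) {
      li <- pmax(li + stats::rnorm(length(tt), 0, baseline_sd), 0)
      hi <- pmax(hi + stats::rnorm(length(tt), 0, baseline_sd), 0)
    }
    rows[[i]] <- data.frame(
      site_id = observations$site_id[i],
      condition = observations$condition[i],
      replicate = observations$replicate[i],
      channel = rep(c("LIGHT", "HEAVY"), each = length(tt)),
      time_s = c(tt, tt),
      intensity = c(li, hi),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
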