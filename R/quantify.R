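#' Integrate an extracted-ion-chromatogram trace
#'
#' Trapezoidal integration over an optional retention-time window after
#' subtracting a robust baseline estimate (the median of the lowest decile
#' of intensities). The result is clamped at zero.
#'
#' @param times Strictly increasing numeric vector (seconds), length >= 3.
#' @param intensities Non-negative numeric vector, same length.
#' @param window Optional `c(t_start, t_end)`; must overlap the trace.
#' @param baseline Subtract the baseline estimate (default TRUE).
#' @return Peak area (intensity * seconds), >= 0.
#' @export
integrate_eic <- function(times, intensities, window = NULL,
                          baseline = TRUE) {
  stopifnot(length(times) == length(intensities), length(times) >= 3L,
            all(diff(times) > 0), all(intensities >= 0))
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    if (sum(keep) < 2L) {
      stop("integration window does not overlap the trace", call. = FALSE)
    }
    times <- times[keep]
    intensities <- intensities[keep]
  }
  y <- intensities
  if (baseline) {
    lo <- sort(intensities)[seq_len(max(1L, floor(length(intensities) / 10)))]
    y <- intensities - stats::median(lo)
  }
  area <- sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  max(area, 0)
}

#' Co-elution quality control for a light/heavy trace pair
#'
#' Resamples both traces onto the union time grid of their overlapping
#' domain by linear interpolation, then requires the apex-time offset to be
#' within `apex_limit` seconds and the Pearson correlation of the resampled
#' intensities to reach `cor_limit`. Constant (degenerate) traces fail with
#' an explanatory reason since their correlation is undefined.
#'
#' @param light,heavy data.frames with columns `time_s`, `intensity`.
#' @param apex_limit Maximum allowed apex offset (seconds).
#' @param cor_limit Minimum Pearson shape correlation.
#' @return List with `pass` (logical), `apex_offset_s`, `shape_cor`, and
#'   `reason` (`"OK"`, `"APEX_OFFSET"`, `"LOW_CORRELATION"`,
#'   `"DEGENERATE_TRACE"`, or `"NO_OVERLAP"`).
#' @export
coelution_qc <- function(light, heavy, apex_limit = 10, cor_limit = 0.8) {
  stopifnot(nrow(light) >= 3L, nrow(heavy) >= 3L)
  apex_l <- light$time_s[which.max(light$intensity)]
  apex_h <- heavy$time_s[which.max(heavy$intensity)]
  offset <- apex_l - apex_h
  t0 <- max(min(light$time_s), min(heavy$time_s))
  t1 <- min(max(light$time_s), max(heavy$time_s))
  if (t0 >= t1) {
    return(list(pass = FALSE, apex_offset_s = offset, shape_cor = NA_real_,
                reason = "NO_OVERLAP"))
  }
  grid <- sort(unique(c(light$time_s, heavy$time_s)))
  grid <- grid[grid >= t0 & grid <= t1]
  yl <- stats::approx(light$time_s, light$intensity, xout = grid)$y
  yh <- stats::approx(heavy$time_s, heavy$intensity, xout = grid)$y
  if (stats::sd(yl) == 0 || stats::sd(yh) == 0) {
    return(list(pass = FALSE, apex_offset_s = offset, shape_cor = NA_real_,
                reason = "DEGENERATE_TRACE"))
  }
  rho <- stats::cor(yl, yh)
  if (abs(offset) > apex_limit) {
    reason <- "APEX_OFFSET"
  } else if (rho < cor_limit) {
    reason <- "LOW_CORRELATION"
  } else {
    reason <- "OK"
  }
  list(pass = reason == "OK", apex_offset_s = offset, shape_cor = rho,
       reason = reason)
}

#' Light:heavy ratio from a pair of channel areas
#'
#' The ratio is clamped to `[1/cap, cap]`; a zero heavy channel yields the
#' cap. When both channels are zero the observation is missing (`NA`).
#' Vectorized over paired areas.
#'
#' @param light_area,heavy_area Non-negative areas.
#' @param cap Positive cap (> 1), default 20 (just above the largest ratio
#'   meaningfully quantifiable when the heavy channel nears zero).
#' @return List with numeric `ratio_LH` and logical `capped`.
#' @export
compute_ratio <- function(light_area, heavy_area, cap = 20) {
  stopifnot(cap > 1, all(light_area >= 0), all(heavy_area >= 0),
            length(light_area) == length(heavy_area))
  ratio <- ifelse(heavy_area > 0, light_area / heavy_area, Inf)
  ratio[light_area == 0 & heavy_area == 0] <- NA_real_
  clamped <- pmin(pmax(ratio, 1 / cap), cap)
  list(ratio_LH = clamped,
       capped = !is.na(ratio) & (ratio > cap | ratio < 1 / cap))
}

#' Quantify long-format chromatograms into per-replicate ratio observations
#'
#' Groups traces by site, condition, and replicate, integrates the light
#' and heavy channels, applies co-elution QC, and computes capped
#' light:heavy ratios. Pairs with both areas zero are emitted as missing
#' (dropped).
#'
#' @param chromatograms Long-format data.frame from
#'   [simulate_chromatograms()] (columns `site_id`, `condition`,
#'   `replicate`, `channel`, `time_s`, `intensity`).
#' @param cap Ratio cap.
#' @param apex_limit,cor_limit QC limits (see [coelution_qc()]).
#' @param baseline Passed to [integrate_eic()].
#' @return data.frame of observations with `site_id`, `condition`,
#'   `replicate`, `light_area`, `heavy_area`, `ratio_LH`, `capped`,
#'   `qc_pass`, `qc_reason`.
#' @export
quantify_chromatograms <- function(chromatograms, cap = 20, apex_limit = 10,
                                   cor_limit = 0.8, baseline = TRUE) {
  key <- interaction(chromatograms$site_id, chromatograms$condition,
                     chromatograms$replicate, drop = TRUE)
  groups <- split(chromatograms, key)
  rows <- lapply(groups, function(g) {
    li <- g[g$channel == "LIGHT", , drop = FALSE]
    hv <- g[g$channel == "HEAVY", , drop = FALSE]
    la <- integrate_eic(li$time_s, li$intensity, baseline = baseline)
    ha <- integrate_eic(hv$time_s, hv$intensity, baseline = baseline)
    if (la == 0 && ha == 0) return(NULL)
    qc <- coelution_qc(li, hv, apex_limit = apex_limit,
                       cor_limit = cor_limit)
    rat <- compute_ratio(la, ha, cap = cap)
    data.frame(
      site_id = g$site_id[1L], condition = g$condition[1L],
      replicate = g$replicate[1L],
      light_area = la, heavy_area = ha,
      ratio_LH = rat$ratio_LH, capped = rat$capped,
      qc_pass = qc$pass, qc_reason = qc$reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no quantifiable light/heavy pairs in input", call. = FALSE)
  }
  out <- out[order(out$site_id, out$condition, out$replicate), ]
  rownames(out) <- NULL
  out
}
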