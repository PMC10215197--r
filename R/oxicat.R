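#' Percent oxidation from a differential-alkylation channel ratio
#'
#' In differential alkylation the light channel carries the reduced pool
#' and the heavy channel the reversibly oxidized pool, so the oxidized
#' share is the heavy fraction of the total: with an L:H ratio
#' `100 * (1 - R/(R+1))`, with an H:L ratio `100 * R/(R+1)`. The two
#' orientations agree on reciprocal inputs.
#'
#' @param ratio Positive channel ratio(s).
#' @param orientation `"LH"` (light over heavy) or `"HL"`.
#' @return Percent oxidation in `[0, 100]`.
#' @examples
#' percent_oxidation(1, "LH")   # 50
#' percent_oxidation(19, "HL")  # 95
#' @export
percent_oxidation <- function(ratio, orientation = c("LH", "HL")) {
  orientation <- match.arg(orientation)
  if (any(is.na(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive", call. = FALSE)
  }
  if (orientation == "LH") 100 * (1 - ratio / (ratio + 1))
  else 100 * ratio / (ratio + 1)
}

#' Aggregate per-replicate percent-oxidation values
#'
#' Applies the replicate presence rule, then flags records whose replicate
#' dispersion exceeds `sd_threshold` as `DISPERSION_FAIL`. The default
#' dispersion reading is the sample standard deviation of the replicate
#' percent values in percentage points (`sd_mode = "sd"`); `"sem"`
#' (standard error of the mean) and `"relative"` (100 * sd / mean) are
#' available as alternative readings.
#'
#' @param percents data.frame with `site_id`, `protein_id`, `residue`,
#'   `condition`, `replicate`, `pct` (each in `[0, 100]`).
#' @param required_k,of_n Presence rule (default 2 of 3).
#' @param sd_threshold Dispersion threshold (default 30 points).
#' @param sd_mode Dispersion reading, see above.
#' @return data.frame ordered by (protein, residue, condition):
#'   `site_id`, `protein_id`, `residue`, `condition`, `n_present`,
#'   `mean_pct`, `sd_pct`, `flags`.
#' @export
aggregate_oxidation <- function(percents, required_k = 2L, of_n = 3L,
                                sd_threshold = 30,
                                sd_mode = c("sd", "sem", "relative")) {
  stopifnot(sd_threshold > 0, of_n >= required_k, required_k >= 1L)
  sd_mode <- match.arg(sd_mode)
  if (any(percents$pct < 0 | percents$pct > 100)) {
    stop("percent oxidation outside [0, 100]: corrupt input",
         call. = FALSE)
  }
  grp <- paste(percents$site_id, percents$condition, sep = "\r")
  groups <- split(percents, grp)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    flags <- character(0)
    mean_p <- NA_real_; sd_p <- NA_real_
    if (n < required_k) {
      flags <- c(flags, "PRESENCE_FAIL")
    } else {
      mean_p <- mean(g$pct)
      s <- if (n > 1L) stats::sd(g$pct) else 0
      sd_p <- switch(sd_mode,
        sd = s,
        sem = s / sqrt(n),
        relative = if (mean_p > 0) 100 * s / mean_p else 0
      )
      if (sd_p > sd_threshold) flags <- c(flags, "DISPERSION_FAIL")
    }
    data.frame(
      site_id = g$site_id[1L], protein_id = g$protein_id[1L],
      residue = g$residue[1L], condition = g$condition[1L],
      n_present = n, mean_pct = mean_p, sd_pct = sd_p,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$residue, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Convert ratio observations to per-replicate percent oxidation
#'
#' @param observations data.frame from [simulate_oxicat()] or an external
#'   quantifier, with `ratio_LH` and an `orientation` column (`"LH"` or
#'   `"HL"` per row).
#' @return data.frame suitable for [aggregate_oxidation()].
#' @export
oxidation_from_observations <- function(observations) {
  orient <- observations$orientation
  if (is.null(orient)) orient <- rep("LH", nrow(observations))
  pct <- ifelse(orient == "LH",
                100 * (1 - observations$ratio_LH /
                         (observations$ratio_LH + 1)),
                100 * observations$ratio_LH / (observations$ratio_LH + 1))
  data.frame(
    site_id = observations$site_id,
    protein_id = observations$protein_id,
    residue = observations$residue,
    condition = observations$condition,
    replicate = observations$replicate,
    pct = pct, stringsAsFactors = FALSE
  )
}

#' Percent-oxidation difference between conditions per site
#'
#' Joins retained control and treated records by site and reports the
#' percentage-point delta (treated minus control) with a qualitative call:
#' `increased` when the delta reaches `min_delta`, `decreased` when it
#' falls below `-min_delta`, otherwise `unchanged`.
#'
#' @param control,treated data.frames from [aggregate_oxidation()]
#'   (retained records only; flagged rows are rejected).
#' @param min_delta Minimum percentage-point change for a directional call
#'   (default 20).
#' @return data.frame: `site_id`, `protein_id`, `residue`, `control_pct`,
#'   `treated_pct`, `delta_pct`, `call`.
#' @export
delta_oxidation <- function(control, treated, min_delta = 20) {
  if (any(nzchar(control$flags)) || any(nzchar(treated$flags))) {
    stop("flagged records passed to delta_oxidation; filter with retained()",
         call. = FALSE)
  }
  common <- intersect(control$site_id, treated$site_id)
  if (length(common) == 0L) {
    stop("mismatched sites: no site present in both conditions",
         call. = FALSE)
  }
  ci <- match(common, control$site_id)
  ti <- match(common, treated$site_id)
  delta <- treated$mean_pct[ti] - control$mean_pct[ci]
  out <- data.frame(
    site_id = common,
    protein_id = control$protein_id[ci],
    residue = control$residue[ci],
    control_pct = control$mean_pct[ci],
    treated_pct = treated$mean_pct[ti],
    delta_pct = delta,
    call = ifelse(delta >= min_delta, "increased",
                  ifelse(delta <= -min_delta, "decreased", "unchanged")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id, out$residue), ]
  rownames(out) <- NULL
  out
}
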