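#' Aggregate per-replicate competition ratios into site summaries
#'
#' Sites observed in fewer than `required_k` of `of_n` replicates are
#' flagged `PRESENCE_FAIL` and carry no mean; otherwise the summary holds
#' the arithmetic mean of the replicate ratios and their coefficient of
#' variation (sample standard deviation / mean, on linear ratios by
#' default). A `CAPPED` flag marks sites whose mean rests on at least one
#' capped replicate ratio.
#'
#' @param observations data.frame with at least `site_id`, `protein_id`,
#'   `residue`, `condition`, `replicate`, `ratio_LH`, and optionally
#'   `capped`.
#' @param required_k,of_n Presence rule: ratios required in `required_k`
#'   out of `of_n` replicates (`of_n >= required_k >= 1`).
#' @param log_cv Compute the CV on log-transformed ratios instead of
#'   linear ratios (default FALSE, matching the linear reading of the
#'   replicate-consistency filter).
#' @return data.frame ordered by (protein, residue, condition):
#'   `site_id`, `protein_id`, `residue`, `condition`, `n_present`,
#'   `mean_ratio`, `cv`, `flags` (semicolon-joined).
#' @export
aggregate_replicates <- function(observations, required_k = 2L, of_n = 2L,
                                 log_cv = FALSE) {
  stopifnot(of_n >= required_k, required_k >= 1L)
  key <- paste(observations$site_id, observations$condition,
               observations$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate observation for (site, condition, replicate): %s",
                 gsub("\r", " / ", dup)), call. = FALSE)
  }
  grp <- paste(observations$site_id, observations$condition, sep = "\r")
  groups <- split(observations, grp)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    flags <- character(0)
    if (!is.null(g$capped) && any(g$capped, na.rm = TRUE)) {
      flags <- c(flags, "CAPPED")
    }
    if (n < required_k) {
      flags <- c(flags, "PRESENCE_FAIL")
      mean_r <- NA_real_; cv <- NA_real_
    } else {
      r <- g$ratio_LH
      mean_r <- mean(r)
      if (log_cv) {
        lr <- log(r)
        cv <- if (n > 1L) stats::sd(lr) / abs(mean(lr)) else 0
      } else {
        cv <- if (n > 1L) stats::sd(r) / mean_r else 0
      }
    }
    data.frame(
      site_id = g$site_id[1L], protein_id = g$protein_id[1L],
      residue = g$residue[1L], condition = g$condition[1L],
      n_present = n, mean_ratio = mean_r, cv = cv,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$residue, out$condition), ]
  rownames(out) <- NULL
  out
}

.has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";"), function(f) flag %in% f, logical(1))
}

.add_flag <- function(flags, flag, where) {
  ifelse(where & nzchar(flags), paste(flags, flag, sep = ";"),
         ifelse(where, flag, flags))
}

#' Flag inconsistent changed sites (fold-change / CV filter)
#'
#' Under the default conjunction reading, a site is removed (flagged
#' `CV_FAIL`) only when its mean ratio exceeds the fold threshold AND its
#' replicate CV exceeds the CV threshold: large apparent changes must be
#' reproducible, while unchanged sites are retained regardless of CV. The
#' alternative `"cv_only"` mode flags any summary whose CV exceeds the
#' threshold.
#'
#' @param summaries data.frame from [aggregate_replicates()].
#' @param fold_threshold Mean-ratio threshold (default 2).
#' @param cv_threshold CV threshold (default 0.5).
#' @param mode `"conjunction"` (default) or `"cv_only"`.
#' @return `summaries` with `CV_FAIL` added to `flags` where applicable.
#' @export
filter_changed <- function(summaries, fold_threshold = 2,
                           cv_threshold = 0.5,
                           mode = c("conjunction", "cv_only")) {
  stopifnot(fold_threshold > 0, cv_threshold > 0)
  mode <- match.arg(mode)
  ok <- !is.na(summaries$mean_ratio)
  fail <- rep(FALSE, nrow(summaries))
  if (mode == "conjunction") {
    fail[ok] <- summaries$mean_ratio[ok] > fold_threshold &
      summaries$cv[ok] > cv_threshold
  } else {
    fail[ok] <- summaries$cv[ok] > cv_threshold
  }
  summaries$flags <- .add_flag(summaries$flags, "CV_FAIL", fail)
  summaries
}

#' Retained rows of a summary table
#'
#' Drops rows carrying a failure flag (`PRESENCE_FAIL`, `CV_FAIL`,
#' `DISPERSION_FAIL`). The informational `CAPPED` flag does not exclude a
#' row: capped observations participate in aggregation like ordinary
#' ratios, with the flag carried through to output.
#'
#' @param summaries data.frame with a `flags` column.
#' @return Subset free of failure flags.
#' @export
retained <- function(summaries) {
  fail <- vapply(strsplit(summaries$flags, ";"), function(f) {
    any(f %in% c("PRESENCE_FAIL", "CV_FAIL", "DISPERSION_FAIL"))
  }, logical(1))
  summaries[!fail, , drop = FALSE]
}

#' Classify dose-dependent redox sensitivity for one site
#'
#' The class is read off the mean ratio at the highest available dose:
#' `high` at or above the upper bound (default 5-fold), `moderate` at or
#' above the lower bound (default 2-fold), otherwise `resistant`. A
#' log-log least-squares slope (d log2 ratio / d log2 dose) across the
#' available doses is reported alongside but does not enter the class.
#'
#' @param dose_ratios Named numeric vector: names are doses in mM,
#'   values mean ratios (at least the top dose present).
#' @param class_bounds Lower and upper ratio bounds, default `c(2, 5)`.
#' @return List with `class` and `slope` (NA when only one dose).
#' @export
classify_sensitivity <- function(dose_ratios, class_bounds = c(2, 5)) {
  dose_ratios <- dose_ratios[!is.na(dose_ratios)]
  if (length(dose_ratios) == 0L) stop("no doses present", call. = FALSE)
  doses <- as.numeric(names(dose_ratios))
  stopifnot(!any(is.na(doses)), all(doses > 0), all(dose_ratios > 0))
  top <- dose_ratios[[which.max(doses)]]
  cls <- if (top >= class_bounds[2]) "high"
         else if (top >= class_bounds[1]) "moderate"
         else "resistant"
  slope <- NA_real_
  if (length(doses) >= 2L) {
    fit <- stats::lm(log2(dose_ratios) ~ log2(doses))
    slope <- unname(stats::coef(fit)[2L])
  }
  list(class = cls, slope = slope)
}

#' Classify every site across a dose series of summaries
#'
#' Applies [classify_sensitivity()] per site over retained summaries of
#' dose-labeled conditions. Sites lacking a retained top-dose summary are
#' omitted.
#'
#' @param summaries data.frame from [filter_changed()].
#' @param condition_doses Named numeric vector mapping condition labels to
#'   doses (mM).
#' @param class_bounds Passed to [classify_sensitivity()].
#' @return data.frame: `site_id`, `protein_id`, `residue`,
#'   `sensitivity_class`, `slope`, `top_dose_ratio`.
#' @export
classify_sites <- function(summaries, condition_doses,
                           class_bounds = c(2, 5)) {
  keep <- retained(summaries)
  keep <- keep[keep$condition %in% names(condition_doses), , drop = FALSE]
  top_cond <- names(condition_doses)[which.max(condition_doses)]
  groups <- split(keep, keep$site_id)
  rows <- lapply(groups, function(g) {
    if (!top_cond %in% g$condition) return(NULL)
    dr <- stats::setNames(g$mean_ratio,
                          condition_doses[g$condition])
    cl <- classify_sensitivity(dr, class_bounds)
    data.frame(
      site_id = g$site_id[1L], protein_id = g$protein_id[1L],
      residue = g$residue[1L],
      sensitivity_class = cl$class, slope = cl$slope,
      top_dose_ratio = g$mean_ratio[g$condition == top_cond][1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no site has a retained top-dose summary", call. = FALSE)
  }
  out <- out[order(out$protein_id, out$residue), ]
  rownames(out) <- NULL
  out
}

#' Oxidation stoichiometry implied by a competition ratio
#'
#' Inverts the competition model `R = 1 / (1 - f)`: a mean ratio `R`
#' implies an oxidized percentage `100 * (1 - 1/R)`. Ratios below 1
#' (apparent reactivity gain) return 0 with a warning.
#'
#' @param mean_ratio Positive ratio(s).
#' @return Percent oxidation in `[0, 100)`.
#' @examples
#' implied_oxidation(2)     # 50
#' implied_oxidation(13.3)  # 92.48
#' @export
implied_oxidation <- function(mean_ratio) {
  if (any(is.na(mean_ratio)) || any(mean_ratio <= 0)) {
    stop("mean_ratio must be positive", call. = FALSE)
  }
  sub1 <- mean_ratio < 1
  if (any(sub1)) {
    warning(sprintf("%d ratio(s) below 1 floored to 0%% oxidation",
                    sum(sub1)))
  }
  ifelse(sub1, 0, 100 * (1 - 1 / mean_ratio))
}

#' Per-condition median and quartiles of retained mean ratios
#'
#' @param summaries data.frame with `condition`, `mean_ratio`, `flags`.
#' @return data.frame: `condition`, `n`, `q1`, `median_ratio`, `q3`.
#' @export
median_summary <- function(summaries) {
  keep <- retained(summaries)
  conds <- unique(summaries$condition)
  rows <- lapply(conds, function(cond) {
    r <- keep$mean_ratio[keep$condition == cond]
    if (length(r) == 0L) {
      stop(sprintf("no retained summaries for condition '%s'", cond),
           call. = FALSE)
    }
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(condition = cond, n = length(r),
               q1 = q[1], median_ratio = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
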