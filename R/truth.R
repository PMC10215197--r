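#' Dose-response oxidized fraction for one site
#'
#' Total oxidized fraction at an oxidant concentration under the Hill model
#' `f(c) = basal_ox + fmax_rev * c^hill / (K^hill + c^hill)`: monotone
#' non-decreasing in `c`, equal to `basal_ox` at zero dose, saturating at
#' `basal_ox + fmax_rev`.
#'
#' @param truth One-row data.frame (or list) with fields `basal_ox`,
#'   `fmax_rev`, `K` (mM), `hill`.
#' @param concentration Oxidant concentration in mM (>= 0), vectorized.
#' @return Oxidized fraction(s) in `[0, 1]`.
#' @export
oxidized_fraction <- function(truth, concentration) {
  if (any(truth$K <= 0)) stop("K must be positive", call. = FALSE)
  if (any(concentration < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  f <- truth$basal_ox +
    truth$fmax_rev * concentration^truth$hill /
      (truth$K^truth$hill + concentration^truth$hill)
  pmin(pmax(f, 0), 1)
}

#' Noiseless expected light:heavy competition ratio at a given dose
#' @keywords internal
.expected_ratio <- function(truth, concentration) {
  1 / (1 - oxidized_fraction(truth, concentration))
}

#' Classify redox sensitivity from the dose-response parameters
#'
#' Deterministic class from the noiseless competition ratio at the top
#' dose: `high` if >= the upper bound (default 5), `moderate` if >= the
#' lower bound (default 2), else `resistant`.
#'
#' @keywords internal
.truth_class <- function(truth, top_dose, class_bounds = c(2, 5)) {
  r <- .expected_ratio(truth, top_dose)
  ifelse(r >= class_bounds[2], "high",
         ifelse(r >= class_bounds[1], "moderate", "resistant"))
}

#' Simulate per-site ground truth for both profiling platforms
#'
#' Draws, for each cysteine site, a latent dose-response (Hill) describing
#' its susceptibility to oxidation, the split between reversible and
#' irreversible oxidation, basal (zero-dose) oxidation, and independent
#' detection probabilities for the competition (isoTOP) and differential
#' alkylation (OxICAT) platforms. Class proportions default to the strata
#' observed at the top peroxide dose in mitochondrial lysates (about 42%
#' resistant, 50% moderate, 8% high); a small subpopulation carries high
#' basal oxidation, emulating structural disulfides that sit near-fully
#' oxidized even without added oxidant.
#'
#' @param sites data.frame from [cysteine_sites()] (columns `site_id`,
#'   `protein_id`, `residue`, `peptide`), or an integer number of anonymous
#'   sites.
#' @param class_probs Named probabilities for `resistant`, `moderate`,
#'   `high` generative classes; must sum to 1.
#' @param top_dose Top dose (mM) at which the deterministic
#'   `sensitivity_class` is evaluated.
#' @param class_bounds Ratio boundaries (lower, upper) separating the
#'   classes at the top dose.
#' @param basal_high_prob Probability a site belongs to the high-basal
#'   (structural disulfide-like) subpopulation.
#' @param firr_max Upper bound of the uniform draw for `firr_frac`, the
#'   share of total oxidation that is irreversible.
#' @param detect_range Length-2 range of the uniform per-site detection
#'   probabilities (applied independently per platform).
#' @param hill Hill exponent (shared; default 1, hyperbolic).
#' @param seed Integer RNG seed.
#' @return data.frame (one row per site) with the site columns plus
#'   `fmax_rev`, `K`, `hill`, `basal_ox`, `firr_frac`, `detect_isotop`,
#'   `detect_oxicat`, and `sensitivity_class`.
#' @export
simulate_truth <- function(sites,
                           class_probs = c(resistant = 0.42,
                                           moderate = 0.50,
                                           high = 0.08),
                           top_dose = 10,
                           class_bounds = c(2, 5),
                           basal_high_prob = 0.08,
                           firr_max = 0.15,
                           detect_range = c(0.85, 0.98),
                           hill = 1,
                           seed = 1L) {
  if (is.numeric(sites) && length(sites) == 1L) {
    n <- as.integer(sites)
    sites <- data.frame(
      site_id = sprintf("SYN%04d_C1", seq_len(n)),
      protein_id = sprintf("SYN%04d", seq_len(n)),
      residue = 1L, peptide = "SYNTHETIC", stringsAsFactors = FALSE
    )
  }
  n <- nrow(sites)
  stopifnot(n > 0L, abs(sum(class_probs) - 1) < 1e-9)
  set.seed(seed)
  cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
  fmax <- numeric(n); K <- numeric(n)
  # generative windows chosen so noiseless top-dose ratios are separated by
  # at least two-fold across classes: <=1.3, 2.5-4.2, >=8
  i <- cls == "resistant"
  fmax[i] <- stats::runif(sum(i), 0.02, 0.25)
  K[i] <- stats::runif(sum(i), 1, 8)
  i <- cls == "moderate"
  fmax[i] <- stats::runif(sum(i), 0.66, 0.78)
  K[i] <- stats::runif(sum(i), 0.3, 0.9)
  i <- cls == "high"
  fmax[i] <- stats::runif(sum(i), 0.92, 0.97)
  K[i] <- stats::runif(sum(i), 0.2, 0.5)
  basal <- stats::runif(n, 0, 0.03)
  hi_basal <- stats::runif(n) < basal_high_prob
  basal[hi_basal] <- stats::runif(sum(hi_basal), 0.88, 0.97)
  # enforce basal_ox + fmax_rev <= 1
  fmax <- pmin(fmax, 1 - basal)
  truth <- data.frame(
    sites,
    fmax_rev = fmax, K = K, hill = hill, basal_ox = basal,
    firr_frac = stats::runif(n, 0, firr_max),
    detect_isotop = stats::runif(n, detect_range[1], detect_range[2]),
    detect_oxicat = stats::runif(n, detect_range[1], detect_range[2]),
    stringsAsFactors = FALSE
  )
  truth$sensitivity_class <- .truth_class(truth, top_dose, class_bounds)
  rownames(truth) <- NULL
  truth
}
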