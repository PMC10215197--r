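# Independent oracles and fixture builders shared across the suite.

# Brute-force tryptic digestion oracle: enumerate every substring and keep
# those whose boundaries are cleavage boundaries with at most `max_missed`
# internal cleavage sites. Independent of the segment-walk in digest().
oracle_digest <- function(sequence, max_missed = 0L, min_len = 1L,
                          max_len = 50L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_cut <- function(i) {
    i >= 1 && i <= n && chars[i] %in% c("K", "R") &&
      (i == n || chars[i + 1] != "P")
  }
  out <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1
    if (len < min_len || len > max_len) next
    if (s > 1 && !is_cut(s - 1)) next
    if (e < n && !is_cut(e)) next
    internal <- if (e > s) sum(vapply(s:(e - 1), is_cut, logical(1))) else 0
    if (internal > max_missed) next
    out[[length(out) + 1]] <- data.frame(
      sequence = paste(chars[s:e], collapse = ""),
      start = s, missed_cleavages = internal,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(sequence = character(), start = integer(),
                      missed_cleavages = integer()))
  }
  res[order(res$start, nchar(res$sequence)), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail: P(overlap >= k) summed over all
# achievable overlap outcomes with choose(), no distribution function.
oracle_hyper_tail <- function(k, cat_size, bg_size, fg_size) {
  j <- k:min(cat_size, fg_size)
  sum(choose(cat_size, j) * choose(bg_size - cat_size, fg_size - j)) /
    choose(bg_size, fg_size)
}

random_protein <- function(len) {
  paste(sample(names(cysredox::RESIDUE_MASS), len, replace = TRUE),
        collapse = "")
}

toy_fasta <- function() {
  system.file("extdata", "toy_proteome.fasta", package = "cysredox")
}

toy_annotations <- function() {
  system.file("extdata", "toy_annotations.tsv", package = "cysredox")
}

# Small noiseless observation table for aggregation tests.
make_obs <- function(ratios, site = "P1_C10", cond = "H2O2_10mM",
                     capped = FALSE) {
  data.frame(
    site_id = site, protein_id = sub("_C.*", "", site),
    residue = as.integer(sub(".*_C", "", site)),
    condition = cond, replicate = seq_along(ratios),
    light_area = ratios * 1e5, heavy_area = 1e5,
    ratio_LH = ratios, capped = capped,
    stringsAsFactors = FALSE
  )
}
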