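#' Fixed pathway-bin vocabulary
#'
#' Twelve established mitochondrial biochemical classifications used for
#' pathway binning, plus the implicit catch-all `"other"`.
#'
#' @format Character vector of length 12.
#' @export
PATHWAY_BINS <- c(
  "TCA cycle", "innate immunity", "transport", "urea cycle",
  "fatty acid oxidation", "redox regulation", "Fe-S biogenesis",
  "apoptosis", "tRNA-ligases", "mt ribosomal subunits", "ETC",
  "mt transcription and translation"
)

#' Read a protein annotation table
#'
#' Expected TSV schema: `protein_id`, `is_mitochondrial` (0/1),
#' `pathway_bin` (one of [PATHWAY_BINS] or `"other"`), `flags`
#' (semicolon-separated subset of disulfide / metal_binding /
#' s_palmitoylation; may be empty).
#'
#' @param path TSV path (comment lines starting with `#` are skipped).
#' @return data.frame with logical `is_mitochondrial`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "is_mitochondrial") %in% names(ann)))
  ann$is_mitochondrial <- as.logical(as.integer(ann$is_mitochondrial))
  if (is.null(ann$pathway_bin)) ann$pathway_bin <- "other"
  if (is.null(ann$flags)) ann$flags <- ""
  ann
}

#' Filter site summaries to mitochondrial proteins
#'
#' Joins summaries to an annotation table on `protein_id` and keeps rows
#' on mitochondrially localized proteins. Proteins missing from the
#' annotation table count as non-mitochondrial, with a warning.
#'
#' @param summaries data.frame with `protein_id` and `site_id` columns.
#' @param annotations data.frame from [read_annotations()].
#' @return List with `summaries` (retained subset) and `report`
#'   (`n_proteins`, `n_sites`, `fraction_mitochondrial` of input rows).
#' @export
filter_mitochondrial <- function(summaries, annotations) {
  if (nrow(annotations) == 0L) {
    stop("empty annotation table", call. = FALSE)
  }
  idx <- match(summaries$protein_id, annotations$protein_id)
  if (anyNA(idx)) {
    warning(sprintf(
      "%d protein(s) absent from the annotation table; counted as non-mitochondrial",
      length(unique(summaries$protein_id[is.na(idx)]))
    ))
  }
  is_mito <- !is.na(idx) & annotations$is_mitochondrial[idx]
  kept <- summaries[is_mito, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    summaries = kept,
    report = list(
      n_proteins = length(unique(kept$protein_id)),
      n_sites = length(unique(kept$site_id)),
      fraction_mitochondrial = mean(is_mito)
    )
  )
}

#' Bin proteins into the fixed pathway vocabulary
#'
#' Each protein falls in exactly one bin (or `"other"`). Alongside the
#' per-bin protein lists, counts how many sites per bin exceed the
#' high-sensitivity ratio threshold.
#'
#' @param summaries data.frame with `protein_id`, `site_id`, `mean_ratio`.
#' @param annotations data.frame from [read_annotations()]; an unknown
#'   `pathway_bin` label raises an error naming it.
#' @param high_threshold Ratio at or above which a site counts as highly
#'   sensitive (default 5).
#' @return data.frame: `pathway_bin`, `n_proteins`, `n_sites`,
#'   `n_high_sensitivity`, plus a `proteins` list column.
#' @export
bin_pathways <- function(summaries, annotations, high_threshold = 5) {
  bad <- setdiff(unique(annotations$pathway_bin),
                 c(PATHWAY_BINS, "other"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown pathway bin label: '%s'", bad[1L]),
         call. = FALSE)
  }
  idx <- match(summaries$protein_id, annotations$protein_id)
  bin <- ifelse(is.na(idx), "other", annotations$pathway_bin[idx])
  levels <- c(PATHWAY_BINS, "other")
  rows <- lapply(levels, function(b) {
    sel <- bin == b
    data.frame(
      pathway_bin = b,
      n_proteins = length(unique(summaries$protein_id[sel])),
      n_sites = sum(sel),
      n_high_sensitivity = sum(sel & !is.na(summaries$mean_ratio) &
                                 summaries$mean_ratio >= high_threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$proteins <- lapply(levels, function(b)
    sort(unique(summaries$protein_id[bin == b])))
  rownames(out) <- NULL
  out
}

#' Hypergeometric overrepresentation test across categories
#'
#' For each category, the p-value is the upper-tail hypergeometric
#' probability of drawing at least the observed number of category members
#' in a foreground of its size from the background; fold enrichment is the
#' ratio of the foreground proportion to the background proportion.
#' P-values are Benjamini-Hochberg adjusted across categories.
#'
#' @param foreground Character vector of protein ids (subset of
#'   `background`; anything else is an error).
#' @param background Character vector of protein ids (the universe).
#' @param categories Named list of character vectors (each intersected
#'   with the background).
#' @return data.frame ordered by p-value: `category`, `overlap`,
#'   `category_size`, `fold_enrichment`, `p_value`, `q_value`.
#' @export
overrepresentation <- function(foreground, background, categories) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground is not a subset of background", call. = FALSE)
  }
  n_fg <- length(foreground)
  n_bg <- length(background)
  rows <- lapply(names(categories), function(nm) {
    cat_bg <- intersect(categories[[nm]], background)
    m <- length(cat_bg)
    k <- length(intersect(foreground, cat_bg))
    p <- stats::phyper(k - 1L, m, n_bg - m, n_fg, lower.tail = FALSE)
    fold <- if (m > 0L) (k / n_fg) / (m / n_bg) else NA_real_
    data.frame(category = nm, overlap = k, category_size = m,
               fold_enrichment = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  out
}

#' Mitochondrial-enrichment report versus a reference table
#'
#' Compares an organelle-fractionated identification table with a
#' whole-cell reference: fold changes in mitochondrial protein and
#' cysteine counts and the mitochondrial share of rows in each table.
#'
#' @param fractionated,reference data.frames with `protein_id`, `site_id`,
#'   and logical `is_mitochondrial` columns.
#' @return List: `protein_fold`, `cysteine_fold`,
#'   `fraction_mitochondrial_fractionated`,
#'   `fraction_mitochondrial_reference`, and the underlying counts.
#' @export
enrichment_report <- function(fractionated, reference) {
  count <- function(tbl) {
    mito <- tbl[tbl$is_mitochondrial, , drop = FALSE]
    list(proteins = length(unique(mito$protein_id)),
         cysteines = length(unique(mito$site_id)),
         fraction = mean(tbl$is_mitochondrial))
  }
  f <- count(fractionated)
  r <- count(reference)
  if (r$proteins == 0L) {
    stop("zero mitochondrial rows in the reference table", call. = FALSE)
  }
  list(
    protein_fold = f$proteins / r$proteins,
    cysteine_fold = f$cysteines / r$cysteines,
    fraction_mitochondrial_fractionated = f$fraction,
    fraction_mitochondrial_reference = r$fraction,
    counts = list(fractionated = f, reference = r)
  )
}
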