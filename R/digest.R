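#' Monoisotopic residue masses
#'
#' Standard monoisotopic masses of the 20 canonical amino-acid residues
#' (Da), i.e. the mass each residue contributes inside a peptide chain.
#' Cysteine is counted unmodified; isotopic iodoacetamide adducts are added
#' separately by [peptide_mass()].
#'
#' @format Named numeric vector of length 20.
#' @export
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic mass of water (Da), added once per intact peptide.
#' @export
WATER_MASS <- 18.01056

#' Cysteine adduct masses for the isotopic iodoacetamide probe pair
#'
#' Monoisotopic mass added per labeled cysteine by the light (IA_LIGHT) and
#' heavy (IA_HEAVY) probes. Their difference, 6.02013 Da per cysteine, is
#' the spacing between the paired isotope envelopes that quantification
#' exploits.
#'
#' @format Named numeric vector with elements `IA_LIGHT` and `IA_HEAVY`.
#' @export
ADDUCT_MASS <- c(IA_LIGHT = 306.14806, IA_HEAVY = 312.16819)

.check_canonical <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d", chars[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  chars
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after K or R, suppressing cleavage when the
#' following residue is P, and enumerates all products with at most
#' `max_missed` internal missed cleavage sites and length within
#' `[min_len, max_len]`.
#'
#' @param protein_sequence Amino-acid string using the 20 canonical
#'   one-letter codes.
#' @param max_missed Maximum number of internal missed cleavages (>= 0).
#' @param min_len,max_len Peptide length bounds (residues).
#' @return A data.frame with one row per peptide: `sequence`, `start`
#'   (1-based offset in the protein), `end`, `missed_cleavages`, `n_cys`,
#'   and `cys_positions` (list column of 1-based protein residue indices of
#'   cysteines in the peptide). Rows are ordered by start, then length.
#' @examples
#' digest("AKRC")            # fully cleaved products
#' digest("AKPR")            # KP bond is not cleaved
#' digest("AKRC", max_missed = 1)
#' @export
digest <- function(protein_sequence, max_missed = 0L, min_len = 1L,
                   max_len = 50L) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L,
            max_missed >= 0L, min_len >= 1L, max_len >= min_len)
  chars <- .check_canonical(protein_sequence)
  n <- length(chars)
  # cut points: position i is a cut if chars[i] in K/R and chars[i+1] != P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts == n | chars[pmin(cuts + 1L, n)] != "P"]
  # segment boundaries: fully cleaved fragments between consecutive cuts
  starts <- c(1L, cuts[cuts < n] + 1L)
  ends <- c(cuts[cuts < n], n)
  nseg <- length(starts)
  out <- vector("list", nseg * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      cys <- s - 1L + which(chars[s:e] == "C")
      k <- k + 1L
      out[[k]] <- data.frame(
        sequence = paste(chars[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = m,
        n_cys = length(cys), stringsAsFactors = FALSE
      )
      out[[k]]$cys_positions <- list(cys)
    }
  }
  if (k == 0L) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      n_cys = integer(),
                      cys_positions = I(list())))
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$start, res$end - res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Monoisotopic peptide mass, optionally with an isotopic cysteine adduct
#'
#' Sums the standard residue monoisotopic masses plus one water, and, when a
#' label is requested, adds the corresponding iodoacetamide adduct mass once
#' per cysteine in the peptide.
#'
#' @param sequence Peptide amino-acid string (canonical codes, non-empty).
#' @param label `NULL` (unlabeled), `"IA_LIGHT"`, or `"IA_HEAVY"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                      # 75.03202
#' peptide_mass("C", "IA_HEAVY") - peptide_mass("C", "IA_LIGHT")  # 6.02013
#' @export
peptide_mass <- function(sequence, label = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty peptide sequence", call. = FALSE)
  chars <- .check_canonical(sequence)
  mass <- sum(RESIDUE_MASS[chars]) + WATER_MASS
  if (!is.null(label)) {
    label <- match.arg(label, names(ADDUCT_MASS))
    n_cys <- sum(chars == "C")
    if (n_cys == 0L) {
      stop("label requested on a cysteine-free peptide", call. = FALSE)
    }
    mass <- mass + n_cys * ADDUCT_MASS[[label]]
  }
  unname(mass)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file. The accession is the
#'   first whitespace-delimited token of each description line.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Enumerate cysteine sites across a protein set
#'
#' Digests every protein (zero missed cleavages) and emits one row per
#' cysteine residue covered by a peptide within the length bounds: the unit
#' of quantification for both profiling platforms. A cysteine covered by
#' several peptides keeps the shortest covering peptide.
#'
#' @param proteins Named character vector of protein sequences (as from
#'   [read_fasta()]).
#' @inheritParams digest
#' @return data.frame with columns `site_id` (`<accession>_C<residue>`),
#'   `protein_id`, `residue` (1-based cysteine position in the protein), and
#'   `peptide` (covering tryptic peptide sequence).
#' @export
cysteine_sites <- function(proteins, min_len = 6L, max_len = 40L) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  rows <- lapply(names(proteins), function(acc) {
    pep <- digest(proteins[[acc]], max_missed = 0L, min_len = min_len,
                  max_len = max_len)
    pep <- pep[pep$n_cys > 0L, , drop = FALSE]
    if (nrow(pep) == 0L) return(NULL)
    res <- unlist(pep$cys_positions)
    data.frame(
      protein_id = acc,
      residue = res,
      peptide = rep(pep$sequence, pep$n_cys),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(site_id = character(), protein_id = character(),
                      residue = integer(), peptide = character()))
  }
  out <- out[order(out$protein_id, out$residue, nchar(out$peptide)), ]
  out <- out[!duplicated(out[, c("protein_id", "residue")]), ]
  out <- data.frame(site_id = sprintf("%s_C%d", out$protein_id, out$residue),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
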