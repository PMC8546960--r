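# Transcriptome fractions: cpm filtering, TPM, sector weights, U/M ratio.

#' Counts-per-million
#'
#' @param counts Gene x library numeric matrix of raw counts.
#' @return Matrix of the same shape, `counts / library_size * 1e6`.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  stop_if(length(counts) == 0L, "empty count matrix")
  lib <- colSums(counts)
  stop_if(any(lib <= 0), "all library sizes must be > 0")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Low-count gene filter
#'
#' Retains a gene iff its cpm is >= `threshold` in every library of the
#' comparison (genes with reads of < 0.5 cpm are removed; the boundary value
#' is retained).
#'
#' @param counts Gene x library count matrix with rownames.
#' @param threshold cpm threshold (default 0.5).
#' @return Character vector of retained gene ids.
#' @export
filter_low_counts <- function(counts, threshold = 0.5) {
  x <- cpm(counts)
  keep <- apply(x >= threshold, 1, all)
  rownames(counts)[keep]
}

#' Transcripts per million with a short-gene filter
#'
#' Genes shorter than the mean sequenced fragment length are removed before
#' normalization (their length-normalized rates are inflated), then
#' `TPM_g = (c_g/L_g) / sum(c/L) * 1e6` over the retained genes, which sum
#' to 1e6 per library.
#'
#' @param counts Named numeric vector (one library) or gene x library matrix.
#' @param lengths Named numeric vector of gene lengths (nt), > 0, covering
#'   the rows of `counts`.
#' @param mean_fragment_length Mean paired-end fragment length (nt), > 0;
#'   genes with `length < mean_fragment_length` are excluded. Use 0 to
#'   disable the filter.
#' @return Matrix (genes kept x libraries) of TPM values.
#' @export
compute_tpm <- function(counts, lengths, mean_fragment_length = 0) {
  if (is.null(dim(counts))) counts <- cbind(lib1 = counts)
  counts <- as.matrix(counts)
  stop_if(is.null(rownames(counts)), "counts must carry gene ids as rownames")
  stop_if(!all(rownames(counts) %in% names(lengths)),
          "every gene needs a length")
  assert_number(mean_fragment_length, "mean_fragment_length", lower = 0)
  len <- lengths[rownames(counts)]
  stop_if(any(len <= 0), "gene lengths must be > 0")
  keep <- len >= mean_fragment_length
  stop_if(!any(keep), "all genes removed by the fragment-length filter")
  counts <- counts[keep, , drop = FALSE]
  len <- len[keep]
  rate <- counts / len
  denom <- colSums(rate)
  stop_if(any(denom <= 0), "a library has zero counts on retained genes")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Sector transcriptome fractions and the U/M ratio
#'
#' Per-gene weight `w_g = TPM_g * L_g / sum_{g in M u U}(TPM * L)` — the
#' nucleotide fraction of the sector-assigned transcriptome — summed per
#' sector. The U/M ratio of these summed fractions proxies the proteome
#' `phi_U/phi_M` (subsystem-level proportionality). Normalization is over
#' the joint M u U set; the ratio is identical under per-sector
#' normalization.
#'
#' @param tpm Named numeric vector of TPM values for one strain.
#' @param lengths Named numeric vector of gene lengths (nt).
#' @param sector Named character vector with values `"M"`, `"U"` or other
#'   labels; only genes labeled M or U enter the computation.
#' @return A list: `frac_M`, `frac_U` (sum to 1 over the assigned set),
#'   `um_ratio`, and `weights` (per assigned gene).
#' @export
sector_fraction_ratio <- function(tpm, lengths, sector) {
  genes <- names(tpm)
  stop_if(is.null(genes), "'tpm' must be named by gene id")
  sec <- sector[genes]
  assigned <- !is.na(sec) & sec %in% c("M", "U")
  stop_if(!any(assigned), "no genes assigned to the M or U sector")
  g <- genes[assigned]
  w <- tpm[g] * lengths[g]
  tot <- sum(w)
  stop_if(tot <= 0, "zero total sector weight")
  w <- w / tot
  frac_M <- sum(w[sec[g] == "M"])
  frac_U <- sum(w[sec[g] == "U"])
  stop_if(frac_M <= 0, "U/M undefined: M sector weight is zero")
  list(frac_M = frac_M, frac_U = frac_U, um_ratio = frac_U / frac_M,
       weights = w)
}

#' Call differentially expressed genes from a fold-change/p table
#'
#' Up: `log2FC >= 1` and adjusted p `< 0.05`; down: `log2FC <= -1` and
#' adjusted p `< 0.05` (fold-change boundary inclusive, p boundary
#' exclusive).
#'
#' @param deg_table `data.frame` with columns `gene`, `log2fc`, `adj_p`
#'   (one mutant) and optionally `mutant`.
#' @param lfc_min Minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return The input with an added `call` column (`"up"`, `"down"`,
#'   `"none"`).
#' @export
apply_deg_thresholds <- function(deg_table, lfc_min = 1, alpha = 0.05) {
  stop_if(!all(c("gene", "log2fc", "adj_p") %in% names(deg_table)),
          "deg_table needs columns gene, log2fc, adj_p")
  sig <- deg_table$adj_p < alpha
  call <- rep("none", nrow(deg_table))
  call[sig & deg_table$log2fc >= lfc_min] <- "up"
  call[sig & deg_table$log2fc <= -lfc_min] <- "down"
  deg_table$call <- call
  deg_table
}

#' DEG sets per mutant and their union
#'
#' @param deg_table A called table from [apply_deg_thresholds()] with a
#'   `mutant` column.
#' @return A list per mutant with `up` and `down` gene-id vectors, plus
#'   `union`: all DEGs across mutants (the common assigned set used for
#'   sector fractions of every strain including wild type).
#' @export
deg_sets <- function(deg_table) {
  stop_if(!"call" %in% names(deg_table),
          "run apply_deg_thresholds() first")
  stop_if(!"mutant" %in% names(deg_table), "deg_table needs a mutant column")
  out <- lapply(split(deg_table, deg_table$mutant), function(d) {
    list(up = d$gene[d$call == "up"], down = d$gene[d$call == "down"])
  })
  out$union <- sort(unique(deg_table$gene[deg_table$call != "none"]))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone in rank and capped
#' at 1.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  stop_if(any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
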