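# Metabolite-phenotype correlation analysis.

#' Club technical replicates into biological replicates
#'
#' Metabolite measurements come as 3 biological x 2 technical replicates
#' (n = 6); averaging each technical pair yields n = 3 values comparable
#' with the phenotype replicates.
#'
#' @param values Numeric vector of length 6 ordered as (bio1.tech1,
#'   bio1.tech2, bio2.tech1, bio2.tech2, bio3.tech1, bio3.tech2), or a
#'   matrix with 6 such columns.
#' @param n_bio,n_tech Replicate structure (defaults 3 and 2).
#' @return Vector of length `n_bio` (or matrix with `n_bio` columns) of
#'   technical-pair means.
#' @export
club_replicates <- function(values, n_bio = 3L, n_tech = 2L) {
  if (is.matrix(values)) {
    stop_if(ncol(values) != n_bio * n_tech,
            "expected %d columns (%d bio x %d tech)", n_bio * n_tech,
            n_bio, n_tech)
    out <- sapply(seq_len(n_bio), function(b) {
      rowMeans(values[, (b - 1L) * n_tech + seq_len(n_tech), drop = FALSE])
    })
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(values))
    rownames(out) <- rownames(values)
    colnames(out) <- paste0("bio", seq_len(n_bio))
    return(out)
  }
  stop_if(length(values) != n_bio * n_tech,
          "expected %d values (%d bio x %d tech)", n_bio * n_tech,
          n_bio, n_tech)
  vapply(seq_len(n_bio), function(b) {
    mean(values[(b - 1L) * n_tech + seq_len(n_tech)])
  }, numeric(1))
}

#' Pairwise Pearson correlations with significance
#'
#' Log2-normalizes positive features, then computes the sample Pearson
#' product-moment correlation for every feature pair with a two-sided
#' t-distribution p-value. Pairs with p >= `alpha` are masked in the
#' significant view; the full matrices are retained.
#'
#' @param features Numeric matrix, features x observations (observations =
#'   pooled strain x biological-replicate points), >= 3 observations.
#' @param log2_transform Apply log2 first (default TRUE; requires positive
#'   values for transformed features).
#' @param alpha Significance threshold (default 0.05).
#' @return A list: `r` and `p` (symmetric matrices), `r_significant` (r
#'   with non-significant pairs `NA`), `n` observations. Zero-variance
#'   features give `NA` correlations.
#' @export
pearson_pairs <- function(features, log2_transform = TRUE, alpha = 0.05) {
  features <- as.matrix(features)
  n <- ncol(features)
  stop_if(n < 3L, "need >= 3 paired observations")
  if (log2_transform) {
    stop_if(any(features <= 0, na.rm = TRUE),
            "log2 normalization requires positive values")
    features <- log2(features)
  }
  k <- nrow(features)
  r <- matrix(NA_real_, k, k, dimnames = list(rownames(features),
                                              rownames(features)))
  p <- r
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- features[i, ]; y <- features[j, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  r_sig <- r
  r_sig[!(p < alpha)] <- NA_real_
  list(r = r, p = p, r_significant = r_sig, n = n)
}

#' Correlate significant metabolites with growth phenotypes
#'
#' Builds the feature matrix the correlation analysis expects: clubbed
#' (n = 3) concentrations of the FDR-significant metabolites stacked with
#' per-replicate phenotypes (growth rate, glucose uptake, yields), paired
#' by biological-replicate index, pooled across the requested strains.
#'
#' @param metabolite_conc List per strain of metabolite x 6-replicate
#'   matrices (umol/gDCW).
#' @param phenotypes List per strain of `data.frame` with `n_bio` rows and
#'   phenotype columns (e.g. `growth_rate`, `glucose_uptake`).
#' @param significant_metabolites Character vector (FDR < 0.05 set).
#' @param strains Strains to pool (default: all in `metabolite_conc`).
#' @param alpha Significance threshold for the correlations.
#' @return [pearson_pairs()] output plus `features`, the assembled matrix.
#' @export
correlate_with_phenotypes <- function(metabolite_conc, phenotypes,
                                      significant_metabolites,
                                      strains = names(metabolite_conc),
                                      alpha = 0.05) {
  stop_if(length(significant_metabolites) == 0L,
          "no significant metabolites to correlate")
  blocks <- lapply(strains, function(s) {
    conc <- metabolite_conc[[s]][significant_metabolites, , drop = FALSE]
    clubbed <- club_replicates(conc)
    ph <- t(as.matrix(phenotypes[[s]]))
    stop_if(ncol(ph) != ncol(clubbed),
            "phenotype replicates of '%s' do not match clubbed n", s)
    rbind(clubbed, ph)
  })
  features <- do.call(cbind, blocks)
  colnames(features) <- unlist(lapply(strains, function(s)
    paste0(s, "_bio", seq_len(ncol(blocks[[1]])))))
  out <- pearson_pairs(features, alpha = alpha)
  out$features <- features
  out
}
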