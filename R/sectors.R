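# M/U sector gene classification from ME-model protein translation fluxes.

#' Classify genes as utilized or non-utilized from a flux sweep
#'
#' A gene is "utilized" iff its predicted protein translation flux reaches
#' the threshold (default 1e-15 mmol/gDCW/h, inclusive) in ANY simulation of
#' the sweep (columns = glucose-uptake-constrained runs with zero oxygen);
#' otherwise "non-utilized". The two sets partition the table's genes.
#'
#' @param flux_table Gene x simulation numeric matrix of protein translation
#'   fluxes (mmol/gDCW/h), rownames = gene ids, all >= 0.
#' @param threshold Flux threshold (default 1e-15).
#' @return A list with character vectors `utilized` and `nonutilized`.
#' @export
classify_me_genes <- function(flux_table, threshold = 1e-15) {
  flux_table <- as.matrix(flux_table)
  stop_if(length(flux_table) == 0L, "empty flux table")
  stop_if(is.null(rownames(flux_table)), "flux table needs gene rownames")
  stop_if(any(flux_table < 0), "protein translation fluxes must be >= 0")
  assert_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  hit <- apply(flux_table >= threshold, 1, any)
  list(utilized = rownames(flux_table)[hit],
       nonutilized = rownames(flux_table)[!hit])
}

#' Assign M/U sector labels to genes
#'
#' Only differentially expressed genes (the union across all mutants) are
#' sector-assigned: DEGs among the utilized ME genes form the metabolic M
#' sector and DEGs among the non-utilized ME genes the unused U sector.
#' DEGs outside the ME model's scope are assigned from a manual annotation
#' table, except transcriptional regulator genes, which are excluded from
#' manual additions. Everything else is `"other"`.
#'
#' @param genes Character vector: the full gene namespace.
#' @param deg_union DEG ids (union over mutants).
#' @param utilized,nonutilized Output of [classify_me_genes()]; must be
#'   disjoint.
#' @param manual_annotations Optional `data.frame(gene, sector)` with sector
#'   `"M"` or `"U"` for DEGs outside ME scope.
#' @param regulators Character vector of transcriptional regulator gene ids
#'   (never assigned via manual annotation).
#' @return Named character vector over `genes` with values `"M"`, `"U"`,
#'   `"other"`.
#' @export
assign_sectors <- function(genes, deg_union, utilized, nonutilized,
                           manual_annotations = NULL,
                           regulators = character()) {
  both <- intersect(utilized, nonutilized)
  stop_if(length(both) > 0,
          "genes in both utilized and nonutilized sets: %s",
          paste(utils::head(both, 5), collapse = ", "))
  sector <- stats::setNames(rep("other", length(genes)), genes)
  deg <- intersect(deg_union, genes)
  sector[intersect(deg, utilized)] <- "M"
  sector[intersect(deg, nonutilized)] <- "U"
  if (!is.null(manual_annotations)) {
    stop_if(!all(c("gene", "sector") %in% names(manual_annotations)),
            "manual_annotations needs columns gene, sector")
    stop_if(!all(manual_annotations$sector %in% c("M", "U")),
            "manual sector labels must be M or U")
    outside <- setdiff(deg, c(utilized, nonutilized))
    outside <- setdiff(outside, regulators)
    man <- manual_annotations[manual_annotations$gene %in% outside, ]
    sector[man$gene] <- man$sector
  }
  sector
}
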