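# End-to-end orchestration: bundle -> physiology -> sector fractions ->
# allocation -> enrichment -> metabolomics -> correlations.

#' Analysis thresholds
#'
#' All defaults are the study's printed values: cpm filter 0.5, 2-fold DEG
#' change at adjusted p < 0.05, Fisher p < 0.01 with >= 5-gene sets,
#' pathway tests with >= 10 DEGs at BH-adjusted p < 0.05, metabolite FDR
#' < 0.05, ME flux threshold 1e-15 mmol/gDCW/h, correlation p < 0.05.
#'
#' @param cpm_min,lfc_min,deg_alpha,fisher_alpha,min_set_genes,min_pathway_degs,pathway_alpha,fdr_alpha,flux_threshold,cor_alpha
#'   Individual cutoffs; see Description.
#' @return A named list of thresholds.
#' @export
pipeline_thresholds <- function(cpm_min = 0.5, lfc_min = 1,
                                deg_alpha = 0.05, fisher_alpha = 0.01,
                                min_set_genes = 5L, min_pathway_degs = 10L,
                                pathway_alpha = 0.05, fdr_alpha = 0.05,
                                flux_threshold = 1e-15, cor_alpha = 0.05) {
  th <- list(cpm_min = cpm_min, lfc_min = lfc_min, deg_alpha = deg_alpha,
             fisher_alpha = fisher_alpha, min_set_genes = min_set_genes,
             min_pathway_degs = min_pathway_degs,
             pathway_alpha = pathway_alpha, fdr_alpha = fdr_alpha,
             flux_threshold = flux_threshold, cor_alpha = cor_alpha)
  stop_if(any(unlist(th) <= 0), "all thresholds must be positive")
  th
}

# metabolite x (bio x tech) concentration matrix for one strain, columns
# ordered bio-major so club_replicates() pairs technical replicates
conc_matrix <- function(quant, strain, n_bio = 3L, n_tech = 2L) {
  q <- quant[quant$strain == strain, ]
  mets <- unique(q$metabolite)
  out <- matrix(NA_real_, nrow = length(mets), ncol = n_bio * n_tech,
                dimnames = list(mets, paste0("bio", rep(seq_len(n_bio),
                                                        each = n_tech),
                                             "_t", rep(seq_len(n_tech),
                                                       n_bio))))
  for (i in seq_len(nrow(q))) {
    col <- (q$bio_rep[i] - 1L) * n_tech + q$tech_rep[i]
    out[q$metabolite[i], col] <- q$conc_gdcw[i]
  }
  out
}

#' Run the full allocation analysis on a study bundle
#'
#' Executes every stage in order: growth physiology per strain and
#' replicate; cpm/TPM transcriptome fractions over the DEG-defined M and U
#' sectors; the four-sector allocation with efficiencies and fold changes;
#' regulon, pathway and ppGpp enrichment with regulator-activity calls;
#' isotope-dilution metabolite quantification and significance; and
#' metabolite-phenotype correlations. A rerun on the same bundle is
#' bit-identical (no randomness).
#'
#' @param bundle A `study_bundle` (from [generate_study()] or
#'   [read_study_bundle()]).
#' @param params [allocation_params()].
#' @param thresholds [pipeline_thresholds()].
#' @param extract_volume,biomass_gdcw Metabolomics bookkeeping (liters and
#'   gDCW per sample); defaults follow the bundle's config when present.
#' @param out_dir Optional directory; when given, writes physiology.tsv,
#'   sectors.tsv, allocation.tsv, enrichment.tsv, metabolites.tsv,
#'   correlations.tsv, summary.json and provenance.json.
#' @return A list with elements `physiology`, `sector_assignment`,
#'   `transcriptome`, `allocation`, `enrichment`, `activity`,
#'   `metabolites`, `correlations`, `summary`.
#' @export
run_pipeline <- function(bundle, params = allocation_params(),
                         thresholds = pipeline_thresholds(),
                         extract_volume = NULL, biomass_gdcw = NULL,
                         out_dir = NULL) {
  stop_if(!inherits(bundle, "study_bundle"), "bundle must be a study_bundle")
  cfg <- bundle$truth$config
  if (is.null(extract_volume))
    extract_volume <- if (!is.null(cfg$extract_volume)) cfg$extract_volume
                      else 0.002
  if (is.null(biomass_gdcw))
    biomass_gdcw <- if (!is.null(cfg$biomass_gdcw)) cfg$biomass_gdcw
                    else 0.01
  strains <- unique(bundle$rp_ratio$strain)
  stop_if(strains[1] != "WT", "wild type ('WT') must be the first strain")
  mutants <- strains[-1]
  molar_masses <- c(glucose = 180.16, ammonia = 17.03, formate = 46.03,
                    acetate = 60.05, ethanol = 46.07, lactate = 90.08,
                    succinate = 118.09)

  # 1. physiology ----------------------------------------------------------
  physio_rows <- list()
  for (s in strains) {
    for (b in unique(bundle$od_series$bio_rep)) {
      od <- bundle$od_series[bundle$od_series$strain == s &
                               bundle$od_series$bio_rep == b, ]
      cs <- bundle$substrate_series[bundle$substrate_series$strain == s &
                                      bundle$substrate_series$bio_rep == b, ]
      names(cs)[names(cs) == "od"] <- NULL
      ph <- characterize_physiology(
        data.frame(time = od$time, od = od$od),
        data.frame(time = cs$time, species = cs$species,
                   concentration = cs$concentration),
        molar_masses, dcw_factor = params$dcw_factor)
      ylds <- ph$yields
      physio_rows[[length(physio_rows) + 1L]] <- data.frame(
        strain = s, bio_rep = b, lambda = ph$lambda,
        lambda_se = ph$lambda_se, r_squared = ph$r_squared,
        q_glc = ph$q_glc,
        q_nh3 = unname(ph$rates["ammonia"]),
        yield_lactate = unname(ylds["lactate"]) %||% NA_real_,
        yield_succinate = unname(ylds["succinate"]) %||% NA_real_,
        yield_acetate = unname(ylds["acetate"]) %||% NA_real_)
    }
  }
  physiology <- do.call(rbind, physio_rows)
  lambda_strain <- tapply(physiology$lambda, physiology$strain, mean)

  # 2. transcriptome sector fractions --------------------------------------
  background <- filter_low_counts(bundle$counts,
                                  threshold = thresholds$cpm_min)
  deg_called <- apply_deg_thresholds(bundle$deg_table,
                                     lfc_min = thresholds$lfc_min,
                                     alpha = thresholds$deg_alpha)
  sets <- deg_sets(deg_called)
  me <- classify_me_genes(bundle$flux_table,
                          threshold = thresholds$flux_threshold)
  sector <- assign_sectors(bundle$catalog$gene, sets$union, me$utilized,
                           me$nonutilized, bundle$manual_annotations,
                           regulators = bundle$catalog$gene[
                             bundle$catalog$is_regulator])
  lengths <- stats::setNames(bundle$catalog$length, bundle$catalog$gene)
  frag <- if (!is.null(cfg$mean_fragment_length)) cfg$mean_fragment_length
          else 150
  tx_rows <- list()
  for (s in strains) {
    libs <- grep(paste0("^", s, "_"), colnames(bundle$counts), value = TRUE)
    strain_counts <- rowSums(bundle$counts[, libs, drop = FALSE])
    strain_counts <- strain_counts[names(strain_counts) %in% background]
    tpm <- compute_tpm(strain_counts, lengths, mean_fragment_length = frag)
    sfr <- sector_fraction_ratio(tpm[, 1], lengths, sector)
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      strain = s, frac_M = sfr$frac_M, frac_U = sfr$frac_U,
      um_ratio = sfr$um_ratio)
  }
  transcriptome <- do.call(rbind, tx_rows)

  # 3. allocation ----------------------------------------------------------
  alloc_rows <- list()
  for (s in strains) {
    rp <- mean(bundle$rp_ratio$rp_ratio[bundle$rp_ratio$strain == s])
    um <- transcriptome$um_ratio[transcriptome$strain == s]
    fr <- tryCatch({
      solve_sectors(phi_r_from_rp(rp, params$rho), um, params)
    }, error = function(e) {
      stop(sprintf("allocation failed for strain '%s': %s", s,
                   conditionMessage(e)), call. = FALSE)
    })
    eff <- efficiencies(lambda_strain[[s]], fr)
    alloc_rows[[length(alloc_rows) + 1L]] <-
      cbind(strain = s, rp_ratio = rp, fr, eff[, c("lambda", "tE", "mE",
                                                   "me_te_ratio")])
  }
  allocation <- do.call(rbind, alloc_rows)
  wt_ratio <- allocation$me_te_ratio[allocation$strain == "WT"]
  allocation$fold_change <- fold_change_vs_wt(allocation$me_te_ratio,
                                              wt_ratio)
  tE_wt <- allocation$tE[allocation$strain == "WT"]
  allocation$phi_R_unused <- unused_ribosome_fraction(
    allocation$phi_R, allocation$lambda, tE_wt)

  # 4. metabolomics --------------------------------------------------------
  quant <- quantify_metabolites(bundle$peaks, bundle$calibration,
                                extract_volume, biomass_gdcw,
                                range = if (!is.null(cfg$cal_range))
                                  unlist(cfg$cal_range) else c(0.781, 50))
  conc <- lapply(stats::setNames(strains, strains), conc_matrix,
                 quant = quant)
  met_rows <- list()
  for (m in mutants) {
    res <- test_metabolite_changes(conc$WT, conc[[m]],
                                   alpha = thresholds$fdr_alpha)
    met_rows[[m]] <- cbind(mutant = m, res)
  }
  metabolites <- do.call(rbind, c(met_rows, make.row.names = FALSE))

  # 5. enrichment and regulator activity -----------------------------------
  pathway_sets <- bundle$gene_sets[grep("^pathway_",
                                        names(bundle$gene_sets))]
  enr_rows <- list(); activity <- list()
  for (m in mutants) {
    up <- sets[[m]]$up; dn <- sets[[m]]$down
    for (rg in names(bundle$regulators)) {
      reg <- bundle$regulators[[rg]]
      for (dir in c("up", "down")) {
        res <- fisher_set_enrichment(if (dir == "up") up else dn,
                                     reg$targets, background,
                                     min_genes = thresholds$min_set_genes,
                                     alpha = thresholds$fisher_alpha)
        enr_rows[[length(enr_rows) + 1L]] <-
          cbind(mutant = m, set = paste0("regulon_", rg), direction = dir,
                res)
      }
    }
    pw <- lapply(c(up = "up", down = "down"), function(dir) {
      pathway_enrichment(if (dir == "up") up else dn, pathway_sets,
                         background,
                         min_degs = thresholds$min_pathway_degs,
                         alpha = thresholds$pathway_alpha)
    })
    for (dir in names(pw)) {
      d <- pw[[dir]]
      enr_rows[[length(enr_rows) + 1L]] <- data.frame(
        mutant = m, set = d$pathway, direction = dir, overlap = d$overlap,
        set_size = d$set_size, list_size = length(intersect(
          if (dir == "up") up else dn, background)),
        background_size = length(background), p = d$adj_p,
        eligible = d$tested, significant = d$significant)
    }
    pp <- ppgpp_enrichment(up, dn, bundle$gene_sets$ppgpp_positive,
                           bundle$gene_sets$ppgpp_negative, background,
                           alpha = thresholds$fisher_alpha)
    enr_rows[[length(enr_rows) + 1L]] <- data.frame(
      mutant = m, set = paste0("ppgpp_", pp$target_set),
      direction = pp$deg_direction, overlap = pp$overlap,
      set_size = pp$set_size, list_size = pp$list_size,
      background_size = pp$background_size, p = pp$p,
      eligible = pp$eligible, significant = pp$significant)
    met_m <- metabolites[metabolites$mutant == m, ]
    changes <- data.frame(metabolite = met_m$metabolite,
                          direction = met_m$direction,
                          significant = met_m$significant)
    activity[[m]] <- lapply(bundle$regulators, infer_activity,
                            up_set = up, down_set = dn,
                            background = background,
                            metabolite_changes = changes,
                            alpha = thresholds$fisher_alpha,
                            min_genes = thresholds$min_set_genes)
  }
  enrichment <- do.call(rbind, c(enr_rows, make.row.names = FALSE))

  # 6. correlations --------------------------------------------------------
  sig_mets <- sort(unique(
    metabolites$metabolite[metabolites$significant]))
  correlations <- NULL
  if (length(sig_mets) > 0) {
    phen <- lapply(stats::setNames(strains, strains), function(s) {
      ph <- physiology[physiology$strain == s, ]
      data.frame(growth_rate = ph$lambda, glucose_uptake = ph$q_glc)
    })
    correlations <- correlate_with_phenotypes(conc, phen, sig_mets,
                                              alpha = thresholds$cor_alpha)
  }

  summary <- list(
    strains = strains,
    lambda = as.list(lambda_strain[strains]),
    um_ratio = stats::setNames(as.list(transcriptome$um_ratio),
                               transcriptome$strain),
    me_te_ratio = stats::setNames(as.list(allocation$me_te_ratio),
                                  allocation$strain),
    fold_change = stats::setNames(as.list(allocation$fold_change),
                                  allocation$strain),
    n_significant_metabolites = length(sig_mets))

  out <- list(physiology = physiology, sector_assignment = sector,
              transcriptome = transcriptome, allocation = allocation,
              enrichment = enrichment, activity = activity,
              metabolites = metabolites, correlations = correlations,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, thresholds,
                                                params)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

write_pipeline_outputs <- function(result, out_dir, thresholds, params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$physiology, "physiology.tsv")
  wt(data.frame(gene = names(result$sector_assignment),
                sector = unname(result$sector_assignment)), "sectors.tsv")
  wt(result$allocation, "allocation.tsv")
  wt(result$enrichment, "enrichment.tsv")
  wt(result$metabolites, "metabolites.tsv")
  if (!is.null(result$correlations)) {
    r <- result$correlations$r; p <- result$correlations$p
    idx <- which(upper.tri(r), arr.ind = TRUE)
    wt(data.frame(feature1 = rownames(r)[idx[, 1]],
                  feature2 = colnames(r)[idx[, 2]],
                  r = r[idx], p = p[idx],
                  significant = !is.na(p[idx]) & p[idx] < 0.05),
       "correlations.tsv")
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  prov <- list(package = "sectorAlloc",
               version = as.character(utils::packageVersion("sectorAlloc")),
               thresholds = thresholds,
               params = unclass(params),
               timestamp = NULL)   # omitted so reruns are bit-identical
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
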