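# Synthetic multi-omics study generator with known ground truth.
#
# Emulates a four-strain (wild type + three global-regulator deletion
# mutants) anaerobic glucose-fermentation study: RNA-seq counts with
# planted sector-specific dysregulation, DEG tables, an ME-model flux sweep
# for M/U gene classification, RNA/protein ratios, OD and extracellular
# concentration time courses tied to the growth laws, and isotope-dilution
# metabolomics peak heights with calibration standards. Every planted
# quantity is recorded so downstream estimators can be validated by
# parameter recovery.

default_metabolite_truth <- function() {
  # wild-type concentrations (umol/gDCW) and per-mutant multipliers;
  # accumulation/depletion patterns mirror the regulator-mutant phenotype:
  # PEP up everywhere, alpha-ketoglutarate up in ihf/fnr (2.99 umol/gDCW =
  # 1.3 mM at 2.3 ul/mg) but down in arcA, aspartate/arginine highest in
  # arcA, branched-chain amino acids up in ihf/fnr only.
  m <- data.frame(
    metabolite = c("PEP", "aKG", "aspartate", "glutamate", "leucine",
                   "valine", "glycine", "3PG", "R5P", "citrate",
                   "putrescine", "proline", "threonine", "methionine",
                   "lysine", "arginine", "GABA", "glutamine", "alanine",
                   "fumarate"),
    wt = c(0.40, 1.00, 1.20, 5.00, 0.30, 0.40, 0.50, 0.30, 0.20, 0.80,
           0.60, 0.50, 0.40, 0.20, 0.50, 0.40, 0.30, 0.70, 1.00, 0.30),
    ihf = c(2.5, 2.99, 2.0, 1.8, 2.0, 2.0, 1.7, 2.0, 1.8, 1.0,
            1.6, 1.6, 1.5, 1.5, 1.5, 1.6, 1.5, 1.0, 1.0, 1.0),
    fnr = c(3.0, 2.99, 2.0, 1.8, 2.0, 2.0, 1.7, 1.0, 1.0, 1.0,
            1.6, 1.6, 1.5, 1.5, 1.5, 1.6, 1.5, 1.0, 1.0, 1.0),
    arcA = c(2.0, 0.60, 2.5, 1.5, 1.0, 1.0, 1.0, 1.0, 1.0, 0.5,
             1.6, 1.0, 1.5, 2.0, 1.0, 1.8, 1.5, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)
  m
}

#' Ground-truth configuration for a synthetic study
#'
#' Defines the planted truth of a simulated four-strain study. Sector
#' partitions are specified through the ribosomal fraction `phi_R` per
#' strain and the target efficiency-ratio fold changes of the mutants; the
#' M and U fractions are derived so that `mE/tE` fold changes equal the
#' targets exactly, `phi_R + phi_M + phi_U = phi_max` and `phi_Q = 1 -
#' phi_max` is strain-independent.
#'
#' @param seed Master seed; per-modality streams are derived from it.
#' @param n_genes Number of genes in the catalog (default 2000).
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise (peak heights, R/P, OD, concentrations; default 0.05). 0 turns
#'   noise off.
#' @param nb_dispersion Negative-binomial dispersion of counts (default
#'   0.05). 0 yields idealized expected counts (real-valued), making every
#'   downstream estimator exact.
#' @param phi_R Named ribosomal fractions per strain.
#' @param fold_change Named target `mE/tE` fold changes of the mutants
#'   versus wild type.
#' @param lambda Named growth rates (1/h).
#' @param q_glc Named glucose uptake rates (mmol/gDCW/h).
#' @param q_nh3 Named ammonia uptake rates (mmol/gDCW/h).
#' @param phi_max Growth-related proteome fraction (default 0.43).
#' @param rho RNA-to-proteome conversion factor (default 0.76).
#' @param metabolite_truth `data.frame` of wild-type concentrations
#'   (umol/gDCW) and per-mutant multipliers; see
#'   `sectorAlloc:::default_metabolite_truth`.
#' @param library_depth Expected counts per RNA-seq library (default 5e6).
#' @param mean_fragment_length Mean sequenced fragment length, nt
#'   (default 150).
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         noise_cv = 0.05,
                         nb_dispersion = 0.05,
                         phi_R = c(WT = 0.130, ihf = 0.175, fnr = 0.165,
                                   arcA = 0.155),
                         fold_change = c(ihf = 3.26, fnr = 3.24,
                                         arcA = 2.26),
                         lambda = c(WT = 0.50, ihf = 0.375, fnr = 0.390,
                                    arcA = 0.420),
                         q_glc = c(WT = 30.0, ihf = 22.5, fnr = 23.5,
                                   arcA = 25.5),
                         q_nh3 = c(WT = 4.3, ihf = 3.1, fnr = 3.2,
                                   arcA = 3.5),
                         phi_max = 0.43,
                         rho = 0.76,
                         metabolite_truth = default_metabolite_truth(),
                         library_depth = 5e6,
                         mean_fragment_length = 150) {
  strains <- names(phi_R)
  stop_if(is.null(strains) || strains[1] != "WT",
          "phi_R must be named, wild type ('WT') first")
  mutants <- strains[-1]
  stop_if(!setequal(names(fold_change), mutants),
          "fold_change must name every mutant")
  stop_if(!setequal(names(lambda), strains), "lambda must name every strain")
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_number(phi_max, "phi_max", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  stop_if(any(phi_R <= 0 | phi_R >= phi_max),
          "phi_R values must lie in (0, phi_max)")

  # derive the partition: phi_M chosen so mE/tE fold change vs WT is exact
  um_wt <- 0.30                         # wild-type U/M ratio
  phi_M <- c(WT = unname((phi_max - phi_R[["WT"]]) / (1 + um_wt)))
  ratio_wt <- phi_R[["WT"]] / phi_M[["WT"]]
  for (m in mutants) {
    phi_M[[m]] <- phi_R[[m]] / (ratio_wt * fold_change[[m]])
  }
  phi_U <- phi_max - phi_R - phi_M[strains]
  stop_if(any(phi_U < 0),
          "infeasible truth: phi_U negative for %s",
          paste(strains[phi_U < 0], collapse = ", "))
  sectors <- data.frame(strain = strains,
                        phi_R = unname(phi_R),
                        phi_M = unname(phi_M[strains]),
                        phi_U = unname(phi_U),
                        phi_Q = 1 - phi_max,
                        row.names = NULL)
  sectors$um_ratio <- sectors$phi_U / sectors$phi_M
  sectors$rp_ratio <- sectors$phi_R / rho
  sectors$lambda <- unname(lambda[strains])
  sectors$tE <- sectors$lambda / sectors$phi_R
  sectors$mE <- sectors$lambda / sectors$phi_M
  sectors$me_te_ratio <- sectors$phi_R / sectors$phi_M
  sectors$fold_change <- sectors$me_te_ratio / sectors$me_te_ratio[1]

  sums <- with(sectors, phi_R + phi_M + phi_U + phi_Q)
  stop_if(any(abs(sums - 1) > 1e-9), "sector fractions must sum to 1")

  yields <- data.frame(
    strain = strains,
    formate = c(0.20, 0.20, 0.20, 0.20),
    acetate = c(0.25, 0.24, 0.24, 0.25),
    ethanol = c(0.22, 0.21, 0.21, 0.22),
    lactate = c(0.05, 0.07, 0.12, 0.03),
    succinate = c(0.05, 0.05, 0.02, 0.09))[seq_along(strains), ]
  yields$strain <- strains

  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    noise_cv = noise_cv, nb_dispersion = nb_dispersion,
    strains = strains, mutants = mutants,
    sectors = sectors, phi_max = phi_max, rho = rho,
    q_glc = q_glc[strains], q_nh3 = q_nh3[strains], yields = yields,
    metabolite_truth = metabolite_truth,
    library_depth = library_depth,
    mean_fragment_length = mean_fragment_length,
    od0 = 0.07, dcw_factor = 0.44,
    biomass_gdcw = 0.01, extract_volume = 0.002,
    n_bio = 3L, n_tech = 2L, n_rna_reps = 2L,
    cal_range = c(0.781, 50),
    glucose_molar_mass = 180.16, nh3_molar_mass = 17.03),
    class = "truth_config")
}

#' Write a truth configuration to YAML
#'
#' Serializes the constructor arguments of a [truth_config()] (not the
#' derived partition, which is recomputed on read).
#'
#' @param config A `truth_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_config <- function(config, path) {
  stop_if(!inherits(config, "truth_config"), "not a truth_config")
  args <- list(
    seed = config$seed, n_genes = config$n_genes,
    noise_cv = config$noise_cv, nb_dispersion = config$nb_dispersion,
    phi_R = as.list(stats::setNames(config$sectors$phi_R,
                                    config$sectors$strain)),
    fold_change = as.list(stats::setNames(
      config$sectors$fold_change[-1], config$sectors$strain[-1])),
    lambda = as.list(stats::setNames(config$sectors$lambda,
                                     config$sectors$strain)),
    q_glc = as.list(config$q_glc), q_nh3 = as.list(config$q_nh3),
    phi_max = config$phi_max, rho = config$rho,
    metabolite_truth = as.list(config$metabolite_truth),
    library_depth = config$library_depth,
    mean_fragment_length = config$mean_fragment_length)
  yaml::write_yaml(args, path)
  invisible(path)
}

#' Read a truth configuration from YAML
#'
#' @param path A file written by [write_truth_config()].
#' @return A [truth_config()].
#' @export
read_truth_config <- function(path) {
  stop_if(!file.exists(path), "missing config file: %s", path)
  a <- yaml::read_yaml(path)
  truth_config(
    seed = a$seed, n_genes = a$n_genes, noise_cv = a$noise_cv,
    nb_dispersion = a$nb_dispersion, phi_R = unlist(a$phi_R),
    fold_change = unlist(a$fold_change), lambda = unlist(a$lambda),
    q_glc = unlist(a$q_glc), q_nh3 = unlist(a$q_nh3),
    phi_max = a$phi_max, rho = a$rho,
    metabolite_truth = as.data.frame(a$metabolite_truth,
                                     stringsAsFactors = FALSE),
    library_depth = a$library_depth,
    mean_fragment_length = a$mean_fragment_length)
}

#' Generate a gene catalog with planted sector structure
#'
#' @param config A [truth_config()].
#' @param sector_labels Optional character vector of explicit true sector
#'   labels (`"M"`, `"U"`, `"other"`); overrides `config$n_genes` and the
#'   default planted group structure (useful for small fixtures).
#' @return `data.frame`: `gene`, `length` (nt), `me_class`
#'   (`utilized`/`nonutilized`/`outside`), `sector_true` (`M`/`U`/`other`),
#'   `is_regulator`, `group` (internal expression group label).
#' @export
generate_gene_catalog <- function(config, sector_labels = NULL) {
  set.seed(sub_seed(config$seed, "catalog"))
  if (!is.null(sector_labels)) {
    stop_if(!all(sector_labels %in% c("M", "U", "other")),
            "sector_labels must be M, U or other")
    n <- length(sector_labels)
    len <- pmax(round(stats::rlnorm(n, log(900), 0.45)), 200L)
    return(data.frame(
      gene = sprintf("g%04d", seq_len(n)), length = as.integer(len),
      me_class = c(M = "utilized", U = "nonutilized",
                   other = "outside")[sector_labels],
      sector_true = sector_labels, is_regulator = FALSE,
      group = ifelse(sector_labels == "M", "M_deg",
                     ifelse(sector_labels == "U", "U_deg", "background")),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  n <- config$n_genes
  stop_if(n < 800L, "need at least 800 genes for the planted structure")
  gene <- sprintf("g%04d", seq_len(n))
  # planted groups: 250 M-sector DEGs (ME-utilized), 250 U-sector DEGs
  # (ME-nonutilized), 20 manually annotated outside-ME sector DEGs,
  # 10 regulator DEGs (excluded from sectors), ppGpp target blocks,
  # remainder background
  grp <- rep("background", n)
  grp[1:250] <- "M_deg"
  grp[251:500] <- "U_deg"
  grp[501:510] <- "M_manual"
  grp[511:520] <- "U_manual"
  grp[521:530] <- "regulator_deg"
  grp[531:590] <- "ppgpp_pos"       # positively ppGpp-regulated targets
  grp[591:620] <- "ppgpp_neg"
  grp[621:650] <- "extra_me_util"   # utilized ME genes that are not DEGs
  grp[651:680] <- "extra_me_nonut"
  me_class <- rep("outside", n)
  me_class[grp %in% c("M_deg", "extra_me_util")] <- "utilized"
  me_class[grp %in% c("U_deg", "extra_me_nonut")] <- "nonutilized"
  sector_true <- rep("other", n)
  sector_true[grp %in% c("M_deg", "M_manual")] <- "M"
  sector_true[grp %in% c("U_deg", "U_manual")] <- "U"
  is_regulator <- grp == "regulator_deg"
  # lengths: lognormal around ~900 nt; sector-assigned genes kept >= 200 nt
  # so the fragment-length TPM filter only removes background genes
  len <- round(stats::rlnorm(n, meanlog = log(900), sdlog = 0.45))
  len <- pmax(len, 60L)
  assigned <- sector_true != "other"
  len[assigned] <- pmax(len[assigned], 200L)
  # a handful of short background ORFs below the mean fragment length,
  # exercising the TPM length filter downstream
  short <- utils::tail(which(grp == "background"), max(10L, n %/% 100))
  len[short] <- round(stats::runif(length(short), 60, 140))
  data.frame(gene = gene, length = as.integer(len), me_class = me_class,
             sector_true = sector_true, is_regulator = is_regulator,
             group = grp, stringsAsFactors = FALSE)
}

# expected transcriptome weights per strain; group totals of the
# sector-assigned genes are proportional to the planted phi_M / phi_U so
# the recovered U/M ratio equals the planted one
expression_weights <- function(config, catalog, base) {
  strains <- config$strains
  sec <- config$sectors
  W <- matrix(0, nrow = nrow(catalog), ncol = length(strains),
              dimnames = list(catalog$gene, strains))
  assigned_M <- catalog$sector_true == "M"
  assigned_U <- catalog$sector_true == "U"
  other <- !(assigned_M | assigned_U)
  for (k in seq_along(strains)) {
    s <- strains[k]
    w <- base
    srow <- sec[sec$strain == s, ]
    # scale sector groups to planted fraction of a fixed assigned share
    assigned_share <- 0.40     # sector-assigned genes hold 40% of transcripts
    wM <- base[assigned_M] / sum(base[assigned_M]) *
      assigned_share * srow$phi_M / (srow$phi_M + srow$phi_U)
    wU <- base[assigned_U] / sum(base[assigned_U]) *
      assigned_share * srow$phi_U / (srow$phi_M + srow$phi_U)
    wO <- base[other] / sum(base[other]) * (1 - assigned_share)
    w[assigned_M] <- wM; w[assigned_U] <- wU; w[other] <- wO
    # planted non-sector dysregulation (regulators, ppGpp targets)
    if (s == "ihf") {
      pos <- catalog$group == "ppgpp_pos"
      dn <- which(pos)[seq_len(40)]         # 40/60 positive targets down
      w[dn] <- w[dn] * 2^-1.5
      neg <- which(catalog$group == "ppgpp_neg")[seq_len(15)]
      w[neg] <- w[neg] * 2^1.5
    }
    if (s != "WT") {
      regs <- catalog$group == "regulator_deg"
      w[regs] <- w[regs] * 2^1.4            # regulator DEGs, all mutants
    }
    W[, k] <- w / sum(w)
  }
  W
}

#' Generate a complete synthetic study bundle
#'
#' @param config A [truth_config()].
#' @return A list of class `study_bundle`: `catalog`, `counts` (gene x
#'   library), `deg_table`, `flux_table`, `manual_annotations`,
#'   `regulators`, `gene_sets` (regulon/pathway/ppGpp sets), `rp_ratio`,
#'   `od_series`, `substrate_series`, `peaks`, `calibration`, `truth`
#'   (the config plus derived per-strain truth and expected weights).
#' @export
generate_study <- function(config) {
  stop_if(!inherits(config, "truth_config"), "config must be a truth_config")
  catalog <- generate_gene_catalog(config)
  strains <- config$strains
  sec <- config$sectors
  noise_free <- config$noise_cv == 0

  set.seed(sub_seed(config$seed, "expression"))
  base <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  W <- expression_weights(config, catalog, base)

  # counts: n_rna_reps libraries per strain --------------------------------
  set.seed(sub_seed(config$seed, "counts"))
  libs <- as.vector(t(outer(strains, seq_len(config$n_rna_reps),
                            paste, sep = "_")))
  counts <- matrix(0, nrow = config$n_genes, ncol = length(libs),
                   dimnames = list(catalog$gene, libs))
  for (k in seq_along(strains)) {
    mu <- W[, k] * config$library_depth
    for (r in seq_len(config$n_rna_reps)) {
      col <- paste(strains[k], r, sep = "_")
      counts[, col] <- if (config$nb_dispersion == 0) mu
      else stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$nb_dispersion)
    }
  }

  # DEG table: planted log2 fold changes of expected weights ---------------
  set.seed(sub_seed(config$seed, "deg"))
  deg_rows <- lapply(config$mutants, function(m) {
    lfc <- log2(W[, m] / W[, "WT"])
    planted <- abs(lfc) >= 0.5
    jitter <- if (noise_free) 0 else stats::rnorm(length(lfc), 0, 0.05)
    data.frame(mutant = m, gene = catalog$gene,
               log2fc = lfc + jitter,
               adj_p = ifelse(planted, 1e-8, 0.5),
               stringsAsFactors = FALSE)
  })
  deg_table <- do.call(rbind, deg_rows)

  # ME-model flux sweep -----------------------------------------------------
  set.seed(sub_seed(config$seed, "flux"))
  n_sim <- 5L
  in_scope <- catalog$gene[catalog$me_class != "outside"]
  flux <- matrix(0, nrow = length(in_scope), ncol = n_sim,
                 dimnames = list(in_scope, paste0("glc_", seq_len(n_sim))))
  util <- catalog$me_class[catalog$me_class != "outside"] == "utilized"
  flux[util, ] <- matrix(stats::rlnorm(sum(util) * n_sim,
                                       meanlog = log(1e-5), sdlog = 1),
                         ncol = n_sim)
  # each utilized gene active in a random subset of simulations, >= 1
  for (i in which(util)) {
    off <- sample(n_sim, sample(0:(n_sim - 1L), 1L))
    flux[i, off] <- 0
  }
  manual <- catalog[catalog$group %in% c("M_manual", "U_manual"),
                    c("gene", "sector_true")]
  names(manual) <- c("gene", "sector")

  # regulator specs and gene sets ------------------------------------------
  u_up <- catalog$gene[catalog$group == "U_deg"]
  m_dn <- catalog$gene[catalog$group == "M_deg"]
  gene_sets <- list(
    regulon_RegA = m_dn[1:20],     # activator of M genes (down in mutants)
    regulon_RegB = u_up[1:20],     # repressor of U genes (up in mutants)
    ppgpp_positive = catalog$gene[catalog$group == "ppgpp_pos"],
    ppgpp_negative = catalog$gene[catalog$group == "ppgpp_neg"],
    pathway_amino_acid = u_up[21:60],
    pathway_tca = u_up[61:100],
    pathway_nucleotide = m_dn[21:50],
    pathway_null = catalog$gene[catalog$group == "background"][1:40])
  regulators <- list(
    RegA = list(id = "RegA", mode = "activator",
                targets = gene_sets$regulon_RegA,
                effectors = NULL),
    RegB = list(id = "RegB", mode = "repressor",
                targets = gene_sets$regulon_RegB,
                effectors = data.frame(metabolite = "putrescine",
                                       effect = -1)))

  # RNA/protein ratio, biological duplicates -------------------------------
  set.seed(sub_seed(config$seed, "rp"))
  rp <- do.call(rbind, lapply(seq_along(strains), function(k) {
    data.frame(strain = strains[k], rep = seq_len(2L),
               rp_ratio = sec$rp_ratio[k] * rlnorm_cv(2L, config$noise_cv))
  }))

  # OD and extracellular concentration time courses ------------------------
  set.seed(sub_seed(config$seed, "phenotype"))
  od_rows <- list(); sub_rows <- list()
  yields <- config$yields
  for (k in seq_along(strains)) {
    s <- strains[k]; lam <- sec$lambda[k]
    t_end <- log(0.45 / config$od0) / lam
    times <- seq(0, t_end, length.out = 10L)
    dSdX_glc <- config$q_glc[[s]] * config$glucose_molar_mass / 1000 / lam
    dSdX_nh3 <- config$q_nh3[[s]] * config$nh3_molar_mass / 1000 / lam
    for (b in seq_len(config$n_bio)) {
      od <- config$od0 * exp(lam * times) *
        rlnorm_cv(length(times), config$noise_cv / 2)
      od_rows[[length(od_rows) + 1L]] <-
        data.frame(strain = s, bio_rep = b, time = times, od = od)
      X <- config$od0 * exp(lam * times) * config$dcw_factor
      dX <- X - X[1]
      series <- list(glucose = 2 - dSdX_glc * dX,
                     ammonia = 1 - dSdX_nh3 * dX)
      for (p in c("formate", "acetate", "ethanol", "lactate", "succinate")) {
        series[[p]] <- yields[yields$strain == s, p] * dSdX_glc * dX
      }
      for (sp in names(series)) {
        conc <- series[[sp]]
        if (!noise_free) {
          conc <- conc + stats::rnorm(length(conc), 0,
                                      config$noise_cv / 2 * max(conc, 0.1))
        }
        sub_rows[[length(sub_rows) + 1L]] <-
          data.frame(strain = s, bio_rep = b, time = times, species = sp,
                     concentration = conc)
      }
    }
  }
  od_series <- do.call(rbind, od_rows)
  substrate_series <- do.call(rbind, sub_rows)

  # metabolomics: calibration standards and sample peak heights ------------
  set.seed(sub_seed(config$seed, "peaks"))
  mt <- config$metabolite_truth
  # response slope chosen so the 12C/13C ratio is near 1 at the wild-type
  # concentration: the internal standard is spiked at a level similar to
  # the samples, keeping height ratios inside the 5-fold QC window
  wt_uM <- mt$wt * config$biomass_gdcw / config$extract_volume
  slopes <- 1 / wt_uM * stats::rlnorm(nrow(mt), meanlog = 0, sdlog = 0.1)
  h13 <- stats::rlnorm(nrow(mt), meanlog = log(1e6), sdlog = 0.3)
  cal_conc <- config$cal_range[2] / 2^(0:6)
  calibration <- do.call(rbind, lapply(seq_len(nrow(mt)), function(i) {
    do.call(rbind, lapply(1:2, function(r) {
      data.frame(metabolite = mt$metabolite[i], rep = r, conc_uM = cal_conc,
                 ratio = slopes[i] * cal_conc *
                   rlnorm_cv(length(cal_conc), config$noise_cv / 2))
    }))
  }))
  # umol/gDCW * gDCW / L = umol/L = uM  (biomass per extract volume)
  peak_rows <- list()
  truth_conc <- matrix(NA_real_, nrow = nrow(mt), ncol = length(strains),
                       dimnames = list(mt$metabolite, strains))
  for (k in seq_along(strains)) {
    s <- strains[k]
    mult <- if (s == "WT") rep(1, nrow(mt)) else mt[[s]]
    conc_gdcw <- mt$wt * mult
    truth_conc[, k] <- conc_gdcw
    conc_uM <- conc_gdcw * config$biomass_gdcw / config$extract_volume
    for (b in seq_len(config$n_bio)) {
      bio_noise <- rlnorm_cv(nrow(mt), config$noise_cv)
      for (tr in seq_len(config$n_tech)) {
        tech_noise <- rlnorm_cv(nrow(mt), config$noise_cv / 2)
        ratio <- slopes * conc_uM * bio_noise * tech_noise
        peak_rows[[length(peak_rows) + 1L]] <-
          data.frame(metabolite = mt$metabolite, strain = s, bio_rep = b,
                     tech_rep = tr, h12 = h13 * ratio, h13 = h13,
                     sn = 50, ppm = 1, mode = "positive",
                     stringsAsFactors = FALSE)
      }
    }
  }
  peaks <- do.call(rbind, peak_rows)

  truth <- list(config = config, sectors = sec, weights = W,
                metabolite_conc = truth_conc,
                significant_metabolites = lapply(config$mutants, function(m) {
                  mt$metabolite[mt[[m]] != 1]
                }) |> stats::setNames(config$mutants))

  structure(list(catalog = catalog, counts = counts, deg_table = deg_table,
                 flux_table = flux, manual_annotations = manual,
                 regulators = regulators, gene_sets = gene_sets,
                 rp_ratio = rp, od_series = od_series,
                 substrate_series = substrate_series,
                 peaks = peaks, calibration = calibration, truth = truth),
            class = "study_bundle")
}

#' Serialize a study bundle to a directory of plain-text files
#'
#' Writes counts.tsv, catalog.tsv, deg.tsv, flux.tsv, manual_sectors.tsv,
#' phenotypes.csv, od.csv, rp.csv, peaks.csv, calibration.csv,
#' gene_sets.tsv and truth.json.
#'
#' @param bundle A [generate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, sep = "\t") {
    utils::write.table(x, file.path(dir, f), sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  cts <- data.frame(gene = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE)
  w(cts, "counts.tsv")
  w(bundle$catalog, "catalog.tsv")
  w(bundle$deg_table, "deg.tsv")
  flux <- data.frame(gene = rownames(bundle$flux_table), bundle$flux_table,
                     check.names = FALSE)
  w(flux, "flux.tsv")
  w(bundle$manual_annotations, "manual_sectors.tsv")
  w(bundle$od_series, "od.csv", sep = ",")
  w(bundle$substrate_series, "phenotypes.csv", sep = ",")
  w(bundle$rp_ratio, "rp.csv", sep = ",")
  w(bundle$peaks, "peaks.csv", sep = ",")
  w(bundle$calibration, "calibration.csv", sep = ",")
  sets <- do.call(rbind, lapply(names(bundle$gene_sets), function(s) {
    data.frame(set = s, gene = bundle$gene_sets[[s]])
  }))
  w(sets, "gene_sets.tsv")
  regs <- do.call(rbind, lapply(bundle$regulators, function(rg) {
    eff <- rg$effectors
    data.frame(id = rg$id, mode = rg$mode,
               target_set = paste0("regulon_", rg$id),
               effector_metabolite = if (is.null(eff)) NA else eff$metabolite,
               effector_effect = if (is.null(eff)) NA else eff$effect)
  }))
  w(regs, "regulators.tsv")
  truth <- bundle$truth
  truth$weights <- NULL                       # bulky; regenerable from seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a serialized study bundle
#'
#' Restores the tables written by [write_study_bundle()]. The `truth`
#' element is the deserialized JSON (lists, not the original classed
#' objects); `weights` are not restored.
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return A list of class `study_bundle`.
#' @export
read_study_bundle <- function(dir) {
  r <- function(f, sep = "\t") {
    path <- file.path(dir, f)
    stop_if(!file.exists(path), "missing bundle file: %s", f)
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  cts <- r("counts.tsv")
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$gene
  flux_df <- r("flux.tsv")
  flux <- as.matrix(flux_df[, -1, drop = FALSE])
  rownames(flux) <- flux_df$gene
  sets_df <- r("gene_sets.tsv")
  gene_sets <- split(sets_df$gene, sets_df$set)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  regs_df <- r("regulators.tsv")
  regulators <- lapply(seq_len(nrow(regs_df)), function(i) {
    eff <- if (is.na(regs_df$effector_metabolite[i])) NULL
           else data.frame(metabolite = regs_df$effector_metabolite[i],
                           effect = regs_df$effector_effect[i])
    list(id = regs_df$id[i], mode = regs_df$mode[i],
         targets = gene_sets[[regs_df$target_set[i]]], effectors = eff)
  })
  names(regulators) <- regs_df$id
  structure(list(catalog = r("catalog.tsv"), counts = counts,
                 deg_table = r("deg.tsv"), flux_table = flux,
                 manual_annotations = r("manual_sectors.tsv"),
                 gene_sets = gene_sets, regulators = regulators,
                 rp_ratio = r("rp.csv", ","), od_series = r("od.csv", ","),
                 substrate_series = r("phenotypes.csv", ","),
                 peaks = r("peaks.csv", ","),
                 calibration = r("calibration.csv", ","),
                 truth = truth),
            class = "study_bundle")
}
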