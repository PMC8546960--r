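# Gene-set enrichment of DEG lists and regulator-activity inference.

# one-sided hypergeometric over-representation p-value:
# P(overlap >= x) with set size K, list size n, background N
hyper_tail_p <- function(x, K, n, N) {
  stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Fisher-exact over-representation test of a gene set in a DEG list
#'
#' One-sided test (over-representation) of the 2x2 table (in DEG list /
#' not) x (in set / not) over a background universe; identical to the upper
#' hypergeometric tail. Sets with fewer than `min_genes` members inside the
#' background are flagged ineligible and given `p = NA`.
#'
#' @param deg_list Character vector of DEG ids (one direction, up or down).
#' @param gene_set Character vector of set member ids.
#' @param background Character vector, the gene universe (typically all
#'   catalog genes passing the cpm filter); `deg_list` and `gene_set` are
#'   intersected with it.
#' @param min_genes Minimum eligible set size (default 5); use 0 to disable.
#' @param alpha Significance threshold on the raw p (default 0.01).
#' @return A one-row `data.frame`: `overlap`, `set_size`, `list_size`,
#'   `background_size`, `p`, `eligible`, `significant`.
#' @export
fisher_set_enrichment <- function(deg_list, gene_set, background,
                                  min_genes = 5L, alpha = 0.01) {
  stop_if(length(background) == 0L, "empty background universe")
  background <- unique(background)
  deg <- intersect(unique(deg_list), background)
  set <- intersect(unique(gene_set), background)
  x <- length(intersect(deg, set))
  eligible <- length(set) >= min_genes
  p <- if (eligible) hyper_tail_p(x, length(set), length(deg),
                                  length(background)) else NA_real_
  data.frame(overlap = x, set_size = length(set), list_size = length(deg),
             background_size = length(background), p = p,
             eligible = eligible,
             significant = eligible && is.finite(p) && p < alpha)
}

#' Pathway enrichment with Benjamini-Hochberg correction
#'
#' Hypergeometric over-representation p per pathway; pathways whose DEG
#' overlap is below `min_degs` (default 10) are excluded from testing; BH
#' adjustment across the tested pathways; significant at adjusted p <
#' `alpha`.
#'
#' @param deg_list Character vector of DEG ids (one direction).
#' @param pathway_sets Named list of character vectors.
#' @param background Gene universe.
#' @param min_degs Minimum DEG overlap for a pathway to be tested
#'   (default 10).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `data.frame` with one row per pathway: `pathway`, `overlap`,
#'   `set_size`, `p`, `adj_p`, `tested`, `significant`.
#' @export
pathway_enrichment <- function(deg_list, pathway_sets, background,
                               min_degs = 10L, alpha = 0.05) {
  stop_if(length(background) == 0L, "empty background universe")
  background <- unique(background)
  deg <- intersect(unique(deg_list), background)
  rows <- lapply(names(pathway_sets), function(pw) {
    set <- intersect(unique(pathway_sets[[pw]]), background)
    x <- length(intersect(deg, set))
    data.frame(pathway = pw, overlap = x, set_size = length(set),
               p = NA_real_, tested = x >= min_degs)
  })
  out <- do.call(rbind, rows)
  if (any(out$tested)) {
    out$p[out$tested] <- vapply(which(out$tested), function(i) {
      hyper_tail_p(out$overlap[i], out$set_size[i], length(deg),
                   length(background))
    }, numeric(1))
    out$adj_p <- NA_real_
    out$adj_p[out$tested] <- benjamini_hochberg(out$p[out$tested])
  } else {
    out$adj_p <- NA_real_
  }
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out
}

#' Infer a transcription regulator's activity change
#'
#' Combines two independent lines of evidence. Expression-based: an
#' activator whose targets are enriched among up-DEGs has increased
#' activity (enrichment among down-DEGs: decreased); for a repressor the
#' directions mirror (targets up => activity decreased). Effector-based:
#' the sign of (significant effector concentration change) x (effect of the
#' effector on activity). The combined call is made only when the two agree;
#' discordant evidence is reported as `"conflicting"`.
#'
#' @param regulator A list with `id`, `mode` (`"activator"` or
#'   `"repressor"`), `targets` (character vector), and optionally
#'   `effectors`: `data.frame(metabolite, effect)` with `effect` +1
#'   (activating) or -1 (inhibiting).
#' @param up_set,down_set DEG id vectors for the mutant.
#' @param background Gene universe.
#' @param metabolite_changes Optional `data.frame(metabolite, direction,
#'   significant)` with `direction` +1/-1 for the mutant-vs-WT change.
#' @param alpha Enrichment p threshold (default 0.01).
#' @param min_genes Minimum eligible target-set size (default 5).
#' @return A list: `id`, `expression_call`, `effector_call`, `call`,
#'   `evidence` (the enrichment rows).
#' @export
infer_activity <- function(regulator, up_set, down_set, background,
                           metabolite_changes = NULL, alpha = 0.01,
                           min_genes = 5L) {
  up_en <- fisher_set_enrichment(up_set, regulator$targets, background,
                                 min_genes = min_genes, alpha = alpha)
  dn_en <- fisher_set_enrichment(down_set, regulator$targets, background,
                                 min_genes = min_genes, alpha = alpha)
  act <- identical(regulator$mode, "activator")
  expr_call <- "unchanged"
  if (isTRUE(up_en$significant) && !isTRUE(dn_en$significant)) {
    expr_call <- if (act) "increased" else "decreased"
  } else if (isTRUE(dn_en$significant) && !isTRUE(up_en$significant)) {
    expr_call <- if (act) "decreased" else "increased"
  } else if (isTRUE(up_en$significant) && isTRUE(dn_en$significant)) {
    expr_call <- "conflicting"
  }
  eff_call <- "unchanged"
  if (!is.null(regulator$effectors) && !is.null(metabolite_changes)) {
    m <- merge(regulator$effectors, metabolite_changes, by = "metabolite")
    m <- m[m$significant, , drop = FALSE]
    if (nrow(m) > 0) {
      signs <- unique(sign(m$effect * m$direction))
      eff_call <- if (length(signs) > 1) "conflicting"
                  else if (signs == 1) "increased" else "decreased"
    }
  }
  call <- if (expr_call == eff_call) expr_call
          else if (expr_call == "unchanged") eff_call
          else if (eff_call == "unchanged") expr_call
          else "conflicting"
  list(id = regulator$id, expression_call = expr_call,
       effector_call = eff_call, call = call,
       evidence = rbind(cbind(direction = "up", up_en),
                        cbind(direction = "down", dn_en)))
}

#' ppGpp target enrichment
#'
#' Tests whether genes reported as positively (negatively) regulated by the
#' alarmone ppGpp are over-represented among the down- (up-) regulated DEGs
#' and vice versa — four one-sided Fisher tests. A strong
#' positive-targets-in-down signal suggests lowered ppGpp levels.
#'
#' @param up_set,down_set DEG id vectors.
#' @param positive_targets,negative_targets ppGpp target gene sets; an
#'   empty set is skipped (ineligible rows).
#' @param background Gene universe.
#' @param alpha Raw-p threshold (default 0.01).
#' @return `data.frame` with rows (target set x DEG direction) and the
#'   [fisher_set_enrichment()] columns.
#' @export
ppgpp_enrichment <- function(up_set, down_set, positive_targets,
                             negative_targets, background, alpha = 0.01) {
  combos <- list(
    c(set = "positive", dir = "down"), c(set = "positive", dir = "up"),
    c(set = "negative", dir = "down"), c(set = "negative", dir = "up"))
  rows <- lapply(combos, function(cm) {
    set <- if (cm[["set"]] == "positive") positive_targets
           else negative_targets
    deg <- if (cm[["dir"]] == "up") up_set else down_set
    res <- fisher_set_enrichment(deg, set, background, min_genes = 1L,
                                 alpha = alpha)
    cbind(target_set = cm[["set"]], deg_direction = cm[["dir"]], res)
  })
  do.call(rbind, rows)
}
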