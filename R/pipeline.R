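#' Pipeline configuration
#'
#' Defaults mirror the analysis conditions the package targets: MAF filter
#' 0.03, parentage panel of up to 704 markers with call rate > 0.75, MAF in
#' [0.35, 0.5], HWE exact-test alpha 0.05 and LD r-squared <= 0.2, a 5%
#' exclusion-rate tolerance, 10 replications of 10-fold cross-validation,
#' and generation intervals of 9 years (genomic) versus 14/17 years
#' (pedigree selection).
#'
#' @param maf_min Minimum MAF for the evaluation marker set.
#' @param panel Named list of [select_panel()] arguments.
#' @param max_exclusion_rate Passed to [assign_parentage()].
#' @param cv_k,cv_replications,cv_seed Cross-validation plan.
#' @param L_g,L_a Generation intervals in years (`L_a` may be a vector).
#' @param reml Named list of [reml_estimate()] arguments (e.g. `tol`,
#'   `max_iter`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_min = 0.03,
                            panel = list(call_rate_min = 0.75,
                                         maf_range = c(0.35, 0.5),
                                         hwe_alpha = 0.05, ld_r2_max = 0.2,
                                         max_markers = 704L),
                            max_exclusion_rate = 0.15,
                            cv_k = 10L, cv_replications = 10L,
                            cv_seed = 20191227L,
                            L_g = 9, L_a = c(14, 17),
                            reml = list(tol = 1e-6, max_iter = 500L)) {
  structure(list(maf_min = maf_min, panel = panel,
                 max_exclusion_rate = max_exclusion_rate, cv_k = as.integer(cv_k),
                 cv_replications = as.integer(cv_replications),
                 cv_seed = as.integer(cv_seed), L_g = L_g, L_a = L_a,
                 reml = reml), class = "pipeline_config")
}

#' Run the full genomic-selection evaluation pipeline
#'
#' End-to-end analysis of one dataset: parentage-panel selection and
#' trio-exclusion pedigree correction; marker QC (reference-set allele
#' frequencies, MAF filter, mean imputation) and the genomic relationship
#' matrix; ABLUP and GBLUP fits per trait under both the documented and the
#' corrected pedigree; heritability / accuracy / %VA summaries;
#' cross-validated predictive abilities of both models; and the relative
#' efficiency of genomic selection at each pedigree-selection generation
#' interval.
#'
#' @param data A `gs_sim` from [simulate_dataset()], or a list with elements
#'   `documented_pedigree`, `genotypes`, `phenotypes`, and optionally
#'   `unrelated` (allele-frequency reference ids) and `founders` (candidate
#'   parents).
#' @param config A [pipeline_config()].
#' @param traits Traits to evaluate; default all in the phenotypes.
#' @return A list of class `gs_report`: `genetic_parameters` (heritability /
#'   accuracy / %VA grid), `selection_efficiency` (predictive abilities and
#'   relative efficiencies), `parentage` (assignment tibble and summary),
#'   `meta` (seeds, sizes, thresholds).
#' @export
run_pipeline <- function(data, config = pipeline_config(), traits = NULL) {
  ped_doc <- sort_pedigree(data$documented_pedigree)
  G_raw <- data$genotypes
  pheno <- data$phenotypes
  traits <- traits %||% unique(pheno$trait %||% "value")
  reference <- intersect(data$unrelated %||% character(0), rownames(G_raw))
  if (length(reference) == 0L) {
    pipeline_log("genomat", "no unrelated reference set; using all genotyped individuals")
    reference <- rownames(G_raw)
  }

  # --- parentage correction ------------------------------------------------
  panel <- do.call(select_panel,
                   c(list(G = G_raw, reference = reference), config$panel))
  pipeline_log("panel", nrow(panel), " markers retained")
  candidates <- intersect(
    unique(c(stats::na.omit(c(ped_doc$sire, ped_doc$dam)),
             data$founders %||% character(0))),
    rownames(G_raw)
  )
  progeny <- intersect(
    ped_doc$id[!is.na(ped_doc$sire) | !is.na(ped_doc$dam)],
    rownames(G_raw)
  )
  assignments <- assign_parentage(progeny, candidates, G_raw, panel, ped_doc,
                                  max_exclusion_rate = config$max_exclusion_rate)
  corrected <- correct_pedigree(ped_doc, assignments)
  pipeline_log("parentage", sprintf("%.1f%% trios confirmed, %.1f%% parent slots reassigned",
                                    corrected$summary$pct_confirmed,
                                    corrected$summary$pct_parents_reassigned))

  # --- marker QC and G -----------------------------------------------------
  p <- allele_freq(G_raw, reference = reference)
  G_filt <- filter_maf(G_raw, p, min_maf = config$maf_min)
  pipeline_log("genomat", ncol(G_raw) - ncol(G_filt), " markers removed by MAF filter")
  G_imp <- impute_mean(G_filt, reference = reference)
  p_filt <- p[colnames(G_filt)]
  Gmat <- build_G(G_imp, p_filt)

  # --- model fits and metrics ---------------------------------------------
  variants <- list(documented = ped_doc, corrected = corrected$pedigree)
  reml_args <- config$reml
  params <- list()
  efficiency <- list()
  for (tn in traits) {
    for (pv in names(variants)) {
      ped <- variants[[pv]]
      fit_a <- do.call(fit_ablup, c(list(pheno = pheno, ped = ped, trait = tn), reml_args))
      fit_g <- do.call(fit_gblup, c(list(pheno = pheno, ped = ped, Gmat = Gmat,
                                         trait = tn), reml_args))
      params[[paste(tn, pv)]] <- dplyr::bind_rows(
        evaluation_summary(fit_a, pedigree_variant = pv),
        evaluation_summary(fit_g, pedigree_variant = pv)
      )

      clones <- if ("trait" %in% names(pheno)) {
        unique(pheno$clone[pheno$trait == tn])
      } else {
        unique(pheno$clone)
      }
      clones <- intersect(clones, rownames(Gmat))
      plan <- make_folds(clones, k = config$cv_k,
                         replications = config$cv_replications,
                         seed = config$cv_seed)
      cv_g <- do.call(predictive_ability,
                      c(list(pheno = pheno, ped = ped, Gmat = Gmat, plan = plan,
                             model = "gblup", trait = tn, reference_fit = fit_a),
                        reml_args))
      cv_a <- do.call(predictive_ability,
                      c(list(pheno = pheno, ped = ped, plan = plan,
                             model = "ablup", trait = tn, reference_fit = fit_a),
                        reml_args))
      sigma_ag <- sqrt(vc_value(fit_g$vc, "m"))
      sigma_aa <- sqrt(vc_value(fit_a$vc, "a"))
      eff <- vapply(config$L_a, function(la) {
        relative_efficiency(cv_g$mean_r, cv_a$mean_r, sigma_ag, sigma_aa,
                            L_a = la, L_g = config$L_g)
      }, numeric(1))
      efficiency[[paste(tn, pv)]] <- tibble::tibble(
        trait = tn, pedigree = pv,
        r_ihg = cv_g$mean_r, r_iha = cv_a$mean_r,
        sigma_ag = sigma_ag, sigma_aa = sigma_aa,
        L_a = config$L_a, L_g = config$L_g, efficiency_pct = eff
      )
      pipeline_log("cv", tn, "/", pv,
                   sprintf(": r_IHg = %.3f, r_IHa = %.3f", cv_g$mean_r, cv_a$mean_r))
    }
  }

  structure(list(
    genetic_parameters = dplyr::bind_rows(params),
    selection_efficiency = dplyr::bind_rows(efficiency),
    parentage = list(assignments = assignments, summary = corrected$summary,
                     panel_size = nrow(panel)),
    corrected_pedigree = corrected$pedigree,
    meta = list(
      n_markers_input = ncol(G_raw), n_markers_used = ncol(G_filt),
      n_reference = length(reference), cv_k = config$cv_k,
      cv_replications = config$cv_replications, cv_seed = config$cv_seed,
      maf_min = config$maf_min, max_exclusion_rate = config$max_exclusion_rate
    )
  ), class = "gs_report")
}

#' @exportS3Method base::print
print.gs_report <- function(x, ...) {
  cat("<gs_report>\n")
  cat("Parentage:", sprintf("%.1f%% trios confirmed (panel of %d markers)\n",
                            x$parentage$summary$pct_confirmed, x$parentage$panel_size))
  cat("\nGenetic parameters (cross-site averages):\n")
  avg <- dplyr::filter(x$genetic_parameters, .data$site == "average")
  print(tidyr::pivot_wider(avg, names_from = "parameter", values_from = "value"),
        n = 50)
  cat("\nPredictive ability and relative efficiency:\n")
  print(x$selection_efficiency, n = 50)
  invisible(x)
}
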