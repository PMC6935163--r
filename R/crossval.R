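#' Replicated k-fold assignments over genotypes
#'
#' Randomly partitions the ids into `k` folds within each replication, fold
#' sizes differing by at most one. Clones travel as whole genotypes: all
#' ramets of a clone share its fold. The plan is deterministic given the
#' seed and does not disturb the caller's RNG stream.
#'
#' @param ids Character vector of genotype (clone) ids.
#' @param k Number of folds (default 10).
#' @param replications Number of replications (default 10).
#' @param seed Integer seed (default 20191227).
#' @return A `cv_plan` tibble with columns `replication`, `id`, `fold`.
#' @export
make_folds <- function(ids, k = 10L, replications = 10L, seed = 20191227L) {
  ids <- as.character(ids)
  if (k < 2L) abort("`k` must be at least 2.")
  if (k > length(ids)) abort("`k` cannot exceed the number of ids.")
  plan <- with_seed(seed, {
    purrr::map_dfr(seq_len(replications), function(r) {
      fold <- sample(rep_len(seq_len(k), length(ids)))
      tibble::tibble(replication = r, id = ids, fold = fold)
    })
  })
  attr(plan, "k") <- as.integer(k)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("cv_plan", class(plan))
  plan
}

#' Cross-validated predictive ability
#'
#' The predictive ability of a selection method: full-data ABLUP
#' EBVs are the reference; within each replication of the plan, each fold's
#' phenotypes are set missing in turn, the model is refitted on the remaining
#' data, and the withheld genotypes' predicted genetic values (GEBVs for
#' GBLUP, EBVs for ABLUP) are collected. The Pearson correlation between
#' predictions and reference EBVs over all withheld genotypes of a
#' replication is that replication's predictive ability; the mean over
#' replications is reported. An optional mode correlates predictions with
#' clone-mean phenotypes instead.
#'
#' @param pheno Phenotype tibble (one trait, or use `trait`).
#' @param ped Pedigree used for `A` (corrected or documented).
#' @param Gmat Genomic relationship matrix; required for `model = "gblup"`.
#' @param plan A [make_folds()] plan over the phenotyped clones.
#' @param model `"gblup"` or `"ablup"` — the model refitted per fold.
#' @param trait Trait name when `pheno` holds several.
#' @param reference_fit Optional precomputed full-data ABLUP `gs_fit` used as
#'   the EBV reference (fitted internally when omitted).
#' @param target `"ebv"` (default, reference EBVs) or `"phenotype"`
#'   (clone-mean phenotypes).
#' @param spec Model specification for the refits.
#' @param ... Passed to [reml_estimate()] via the fit functions.
#' @return A `gs_cv` list: `mean_r`, `per_replication` (tibble), `folds`
#'   (tibble of per-fold validation sizes), `model`, `seed`.
#' @export
predictive_ability <- function(pheno, ped, Gmat = NULL, plan,
                               model = c("gblup", "ablup"), trait = NULL,
                               reference_fit = NULL, target = c("ebv", "phenotype"),
                               spec = NULL, ...) {
  model <- match.arg(model)
  target <- match.arg(target)
  pheno <- select_trait(pheno, trait)
  trait <- attr(pheno, "trait")
  if (model == "gblup" && is.null(Gmat)) abort("GBLUP cross-validation needs `Gmat`.")
  spec <- spec %||% if (model == "gblup") gblup_spec() else ablup_spec()

  if (target == "ebv") {
    reference_fit <- reference_fit %||% fit_ablup(pheno, ped, ...)
    ref <- genetic_values(reference_fit)
    reference <- setNames(ref$ebv, ref$id)
  } else {
    cm <- dplyr::summarise(dplyr::group_by(pheno, .data$clone),
                           m = mean(.data$value, na.rm = TRUE))
    reference <- setNames(cm$m, cm$clone)
  }

  reps <- sort(unique(plan$replication))
  fold_rows <- list()
  per_rep <- purrr::map_dfr(reps, function(r) {
    rep_plan <- plan[plan$replication == r, ]
    preds <- numeric(0)
    for (f in sort(unique(rep_plan$fold))) {
      valid <- rep_plan$id[rep_plan$fold == f]
      train <- dplyr::filter(pheno, !.data$clone %in% valid)
      fit <- if (model == "gblup") {
        fit_gblup(train, ped, Gmat, spec = spec, ...)
      } else {
        fit_ablup(train, ped, spec = spec, ...)
      }
      gv <- genetic_values(fit)
      pred_col <- if (model == "gblup") gv$gebv else gv$ebv
      pv <- setNames(pred_col, gv$id)[valid]
      preds <- c(preds, pv)
      fold_rows[[length(fold_rows) + 1L]] <<-
        tibble::tibble(replication = r, fold = f, n_validation = length(valid))
    }
    common <- intersect(names(preds), names(reference))
    if (length(common) < 3L || sd(preds[common]) == 0 || sd(reference[common]) == 0) {
      warn(paste0("Replication ", r, ": correlation undefined; excluded."))
      return(tibble::tibble(replication = r, r = NA_real_, n = length(common)))
    }
    tibble::tibble(replication = r,
                   r = cor(preds[common], reference[common]),
                   n = length(common))
  })
  out <- list(
    mean_r = mean(per_rep$r, na.rm = TRUE),
    per_replication = per_rep,
    folds = dplyr::bind_rows(fold_rows),
    model = model, trait = trait, target = target,
    k = attr(plan, "k"), seed = attr(plan, "seed")
  )
  class(out) <- "gs_cv"
  out
}

#' @exportS3Method base::print
print.gs_cv <- function(x, ...) {
  cat("<gs_cv> ", toupper(x$model), " predictive ability for '", x$trait,
      "': ", signif(x$mean_r, 3), "\n", sep = "")
  cat("  ", nrow(x$per_replication), " replication(s) of ", x$k %||% NA,
      "-fold CV (seed ", x$seed %||% NA, ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.gs_fit
#' @export
tidy.gs_cv <- function(x, ...) x$per_replication

#' @rdname tidy.gs_fit
#' @export
glance.gs_cv <- function(x, ...) {
  tibble::tibble(model = x$model, trait = x$trait, target = x$target,
                 mean_r = x$mean_r,
                 n_replications = nrow(x$per_replication), k = x$k %||% NA_integer_)
}

#' Plot per-replication predictive abilities
#'
#' @param object A `gs_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_cv <- function(object, ...) {
  df <- object$per_replication
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replication), y = .data$r)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_r, linetype = 2) +
    ggplot2::labs(title = paste0(toupper(object$model), " predictive ability: ",
                                 object$trait),
                  x = "replication", y = "correlation with reference EBVs") +
    ggplot2::theme_minimal()
}

#' Relative efficiency of genomic over pedigree-based selection
#'
#' Expected genetic gain per year of genomic selection relative to
#' traditional pedigree BLUP selection,
#' `E = (r_g * sigma_g) / (r_a * sigma_a) * (L_a / L_g) * 100%`.
#' Selection intensity cancels and is deliberately not an argument. `sigma_g`
#' is the square root of the marker-explained additive variance from a
#' full-data GBLUP fit; `sigma_a` the square root of the additive variance
#' from a full-data ABLUP fit. Generation intervals reflect forward
#' selection: around 9 years with genomic selection versus 14 (with a clonal
#' archive of tested material) or 17 years (without) for phenotype-plus-
#' pedigree selection in radiata pine.
#'
#' @param r_ihg Predictive ability of genomic selection.
#' @param r_iha Predictive ability of traditional BLUP selection.
#' @param sigma_ag,sigma_aa Additive genetic standard deviations (trait units).
#' @param L_a Generation interval of pedigree selection, years (14 or 17).
#' @param L_g Generation interval of genomic selection, years (default 9).
#' @return Efficiency in percent (100 = equal gain per year).
#' @export
relative_efficiency <- function(r_ihg, r_iha, sigma_ag = 1, sigma_aa = 1,
                                L_a = 17, L_g = 9) {
  for (nm in c("r_ihg", "r_iha", "sigma_ag", "sigma_aa", "L_a", "L_g")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (abs(r_ihg) > 1 || abs(r_iha) > 1) abort("Predictive abilities must lie in [-1, 1].")
  if (r_iha == 0) abort("`r_iha` must be non-zero.")
  if (sigma_aa <= 0) abort("`sigma_aa` must be positive.")
  if (sigma_ag < 0) abort("`sigma_ag` must be non-negative.")
  if (L_a <= 0 || L_g <= 0) abort("Generation intervals must be positive.")
  (r_ihg * sigma_ag) / (r_iha * sigma_aa) * (L_a / L_g) * 100
}
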