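#' Heritability from pedigree-based variance components
#'
#' Per-site narrow-sense heritability from an ABLUP fit:
#' `h2_a(i) = s2_a / (s2_a + s2_d + s2_e(i))`, with `s2_e(i)` the residual
#' variance at site `i`. With `site = NULL` every site is returned, plus the
#' unweighted cross-site average.
#'
#' @param fit A `gs_fit` from [fit_ablup()], or its variance-component tibble.
#' @param site Site label, or `NULL` for all sites.
#' @return A tibble with columns `site`, `h2` (rows `site = "average"` for the
#'   cross-site mean when `site = NULL`), or a scalar when one site is named.
#' @export
h2_pedigree <- function(fit, site = NULL) {
  vc <- vc_of(fit)
  h2_ratio(vc, num = "a", extra = character(0), site = site, name = "h2_a")
}

#' Marker-based and combined heritabilities from a GBLUP fit
#'
#' `h2_marker()` is the share of phenotypic variance captured by the marker
#' term, `s2_m / (s2_m + s2_a* + s2_d + s2_e(i))`; `h2_combined()` puts the
#' residual polygenic variance in the numerator as well,
#' `(s2_m + s2_a*) / (s2_m + s2_a* + s2_d + s2_e(i))`, so it is the total
#' additive (marker plus pedigree) heritability and never falls below
#' `h2_marker()`.
#'
#' @inheritParams h2_pedigree
#' @export
h2_marker <- function(fit, site = NULL) {
  vc <- vc_of(fit)
  h2_ratio(vc, num = "m", extra = "a_star", site = site, name = "h2_m")
}

#' @rdname h2_marker
#' @export
h2_combined <- function(fit, site = NULL) {
  vc <- vc_of(fit)
  h2_ratio(vc, num = c("m", "a_star"), extra = character(0), site = site,
           name = "h2_am")
}

vc_of <- function(fit) {
  if (inherits(fit, "gs_fit")) fit$vc
  else if (is.data.frame(fit)) fit
  else abort("`fit` must be a gs_fit or a variance-component tibble.")
}

vc_value <- function(vc, component, required = TRUE) {
  v <- vc$variance[vc$component == component & is.na(vc$site)]
  if (length(v) == 0L) {
    if (required) abort(paste0("Variance component '", component, "' not in the fit."))
    return(0)
  }
  v[1L]
}

h2_ratio <- function(vc, num, extra, site, name) {
  num_val <- sum(vapply(num, vc_value, numeric(1), vc = vc))
  extra_val <- sum(vapply(extra, vc_value, numeric(1), vc = vc))
  d_val <- vc_value(vc, "d", required = FALSE)
  res <- vc[vc$component == "residual", , drop = FALSE]
  if (!is.null(site)) {
    if (!site %in% res$site) abort(paste0("No residual variance for site '", site, "'."))
    res <- res[res$site == site, , drop = FALSE]
  }
  denom <- num_val + extra_val + d_val + res$variance
  if (any(denom <= 0)) abort("Zero phenotypic variance; heritability undefined.")
  h2 <- num_val / denom
  if (!is.null(site)) return(unname(h2))
  out <- tibble::tibble(site = res$site, value = h2)
  out <- dplyr::bind_rows(out, tibble::tibble(site = "average", value = mean(h2)))
  names(out)[2L] <- name
  out
}

#' Accuracy of (genomic) breeding values from prediction error variance
#'
#' `r = sqrt(1 - PEV / ((1 + F) * sigma2))`, where `sigma2` is the variance
#' of the genetic term the PEV belongs to (`s2_a` for ABLUP EBVs, `s2_m` for
#' GBLUP GEBVs) and `F` is the diagonal offset of the corresponding
#' relationship matrix. PEVs exceeding the theoretical bound by more than
#' `1e-8` raise an error; tiny overshoots clamp the accuracy to 0.
#'
#' @param pev Numeric vector of prediction error variances.
#' @param F Inbreeding coefficients (same length or scalar).
#' @param sigma2 Genetic variance of the term.
#' @return Numeric vector of accuracies in `[0, 1]`.
#' @export
accuracy <- function(pev, F = 0, sigma2) {
  stopifnot_scalar_number(sigma2, "sigma2")
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  bound <- (1 + F) * sigma2
  if (any(pev < 0)) abort("PEV must be non-negative.")
  over <- pev - bound
  if (any(over > 1e-8)) {
    abort("PEV exceeds (1 + F) * sigma2; accuracy undefined.")
  }
  sqrt(pmax(1 - pev / bound, 0))
}

#' Per-individual and mean accuracy of a fit
#'
#' Applies [accuracy()] to the genetic term of a fit (`a` for ABLUP, `m` for
#' GBLUP). The population summary is the mean over phenotyped individuals;
#' accuracies of non-phenotyped relatives (selection candidates, parents) are
#' returned per individual so other averaging sets can be formed.
#'
#' @param fit A `gs_fit`.
#' @return A tibble `id`, `accuracy`, `phenotyped`; the mean accuracy over
#'   phenotyped individuals is attached as attribute `mean_accuracy`.
#' @export
accuracy_summary <- function(fit) {
  term <- if (fit$method == "ablup") "a" else "m"
  tb <- fit$genetic[[term]]
  sigma2 <- vc_value(fit$vc, term)
  acc <- accuracy(tb$pev, tb$F, sigma2)
  out <- tibble::tibble(id = tb$level, accuracy = acc,
                        phenotyped = tb$level %in% fit$phenotyped)
  attr(out, "mean_accuracy") <- mean(acc[out$phenotyped])
  out
}

#' Percentage of additive variance captured by markers
#'
#' `%VA = 100 * s2_m / (s2_m + s2_a*)` from a GBLUP fit with a residual
#' polygenic term.
#'
#' @param fit A `gs_fit` from [fit_gblup()] (or its variance tibble).
#' @return Scalar percentage in `[0, 100]`.
#' @export
percent_va <- function(fit) {
  vc <- vc_of(fit)
  s2m <- vc_value(vc, "m")
  s2a <- vc_value(vc, "a_star")
  if (s2m + s2a <= 0) abort("s2_m + s2_a* is zero; %VA undefined.")
  100 * s2m / (s2m + s2a)
}

#' Heritability / accuracy / %VA summary of one fit
#'
#' One row per heritability type and site (plus the cross-site average),
#' with mean accuracy and, for GBLUP, %VA.
#'
#' @param fit A `gs_fit`.
#' @param pedigree_variant Label recorded in the output (e.g. `"documented"`
#'   or `"corrected"`).
#' @return A tibble in long format: `trait`, `model`, `pedigree`, `parameter`,
#'   `site`, `value`.
#' @export
evaluation_summary <- function(fit, pedigree_variant = "documented") {
  long <- function(tb) {
    tidyr::pivot_longer(tb, -"site", names_to = "parameter", values_to = "value")
  }
  rows <- if (fit$method == "ablup") {
    long(h2_pedigree(fit))
  } else {
    dplyr::bind_rows(long(h2_marker(fit)), long(h2_combined(fit)))
  }
  acc <- attr(accuracy_summary(fit), "mean_accuracy")
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(site = "average",
                   parameter = if (fit$method == "ablup") "r_ebv" else "r_gebv",
                   value = acc)
  )
  if (fit$method == "gblup") {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(site = "average", parameter = "pct_va", value = percent_va(fit))
    )
  }
  dplyr::mutate(rows, trait = fit$trait, model = fit$method,
                pedigree = pedigree_variant, .before = 1L)
}
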