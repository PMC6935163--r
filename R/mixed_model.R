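#' Model specifications for clonal-trial genetic evaluation
#'
#' The evaluation model for one trait is
#' `y = Xb + Z_g g(+...) + Z_d d + Z_r r + Z_w w + Z_b b + e`,
#' with fixed intercept and site effects, one or two genetic terms, a
#' clone-level non-additive term `d` (identity covariance; the clonal design
#' identifies it), and replicate / set-within-replicate / incomplete-block
#' terms whose variances are heterogeneous across sites, as is the residual.
#' Genetic variances are homogeneous across sites.
#'
#' * `ablup_spec()`: one additive term `a` with pedigree covariance `A`.
#' * `gblup_spec()`: marker term `m` with genomic covariance `G` plus a
#'   residual polygenic term `a_star` with covariance `A`.
#'
#' @param genetic Named character vector mapping genetic term names to
#'   relationship-matrix labels (`"A"` or `"G"`).
#' @param strata Environmental strata fitted as random effects, in nesting
#'   order within site.
#' @param nonadditive Fit the clone-level non-additive term `d`?
#' @return A `model_spec` list.
#' @export
model_spec <- function(genetic, strata = c("rep", "set", "block"), nonadditive = TRUE) {
  if (is.null(names(genetic)) || any(names(genetic) == "")) {
    abort("`genetic` must be a named vector, e.g. c(a = \"A\").")
  }
  if (anyDuplicated(unname(genetic))) {
    abort("At most one genetic term per covariance source.")
  }
  structure(list(genetic = genetic, strata = strata, nonadditive = nonadditive),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
ablup_spec <- function(strata = c("rep", "set", "block"), nonadditive = TRUE) {
  model_spec(c(a = "A"), strata = strata, nonadditive = nonadditive)
}

#' @rdname model_spec
#' @export
gblup_spec <- function(strata = c("rep", "set", "block"), nonadditive = TRUE) {
  model_spec(c(m = "G", a_star = "A"), strata = strata, nonadditive = nonadditive)
}

#' Build design matrices for one trait
#'
#' Constructs the fixed design `X` (intercept plus site contrasts; with a
#' single site the site term is absorbed into the intercept) and one
#' incidence matrix per random term. Genetic terms are indexed by the labels
#' of their relationship matrix, so all ramets of a clone load on one level
#' and non-phenotyped relatives obtain predictions through the covariance.
#' Strata terms are indexed site-wise (`site:rep`, `site:rep:set`,
#' `site:rep:set:block`) and carry one variance component per site; strata
#' columns absent from the data are dropped with a warning.
#'
#' @param pheno Phenotype tibble with columns `clone`, `site`, `value` and
#'   optionally `rep`, `set`, `block` (one trait; see [fit_ablup()] for the
#'   multi-trait front end).
#' @param spec A [model_spec()].
#' @param relmats Named list of relationship matrices referenced by the spec,
#'   e.g. `list(A = A)`.
#' @return A design bundle (list) consumed by [reml_estimate()] and
#'   [solve_mme()].
#' @export
build_design <- function(pheno, spec, relmats) {
  if (!all(c("clone", "site", "value") %in% names(pheno))) {
    abort("`pheno` needs columns clone, site, value.")
  }
  pheno <- dplyr::filter(pheno, !is.na(.data$value))
  n <- nrow(pheno)
  if (n == 0L) abort("No non-missing phenotypes.")
  site <- factor(pheno$site)
  X <- if (nlevels(site) > 1L) {
    stats::model.matrix(~site, data = data.frame(site = site))
  } else {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }

  terms <- list()
  for (g in names(spec$genetic)) {
    K <- relmats[[spec$genetic[[g]]]]
    if (is.null(K)) abort(paste0("Relationship matrix '", spec$genetic[[g]], "' not supplied."))
    labels <- rownames(K)
    missing_cl <- setdiff(unique(pheno$clone), labels)
    if (length(missing_cl) > 0L) {
      abort(paste0("Clone(s) absent from the ", spec$genetic[[g]], " matrix: ",
                   paste(head(missing_cl, 5L), collapse = ", ")))
    }
    kin <- safe_rel_inverse(K, label = spec$genetic[[g]])
    terms[[g]] <- list(
      name = g, levels = labels, K = K, Kinv = kin$inv, logdetK = kin$logdet,
      Z = incidence(factor(pheno$clone, levels = labels)),
      components = list(list(label = g, site = NA_character_,
                             cols = seq_along(labels)))
    )
  }
  if (isTRUE(spec$nonadditive)) {
    cl <- factor(pheno$clone)
    terms[["d"]] <- list(
      name = "d", levels = levels(cl), K = NULL, Kinv = NULL, logdetK = 0,
      Z = incidence(cl),
      components = list(list(label = "d", site = NA_character_,
                             cols = seq_len(nlevels(cl))))
    )
  }
  nesting <- c(rep = "rep", set = "set", block = "block")
  parent_cols <- list(rep = "site", set = c("site", "rep"),
                      block = c("site", "rep", "set"))
  for (st in spec$strata) {
    cols <- c(parent_cols[[st]], nesting[[st]])
    if (!all(cols %in% names(pheno)) || all(is.na(pheno[[st]]))) {
      warn(paste0("Stratum '", st, "' absent from the data; term dropped."))
      next
    }
    f <- droplevels(interaction(pheno[, cols], drop = TRUE, sep = ":"))
    lv_site <- vapply(strsplit(levels(f), ":", fixed = TRUE), `[[`, character(1), 1L)
    comps <- lapply(levels(site), function(s) {
      list(label = paste0(st, ":", s), site = s, cols = which(lv_site == s))
    })
    comps <- comps[vapply(comps, function(cp) length(cp$cols) > 0L, logical(1))]
    terms[[st]] <- list(name = st, levels = levels(f), K = NULL, Kinv = NULL,
                        logdetK = 0, Z = incidence(f), components = comps)
  }

  # flatten components with global column offsets into the stacked Z
  offset <- 0L
  comps <- list()
  for (tm in terms) {
    for (cp in tm$components) {
      comps[[length(comps) + 1L]] <- list(
        id = cp$label, term = tm$name, site = cp$site,
        cols = offset + cp$cols,
        type = if (is.null(tm$K)) "iid" else "K"
      )
    }
    offset <- offset + length(tm$levels)
  }
  Z <- Reduce(Matrix::cbind2, lapply(terms, `[[`, "Z"))

  list(
    y = pheno$value, X = X, Z = Z, n = n, site = site, clone = pheno$clone,
    terms = terms, comps = comps, q = ncol(Z)
  )
}

# sparse 0/1 incidence matrix of a factor
incidence <- function(f) {
  n <- length(f)
  Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                       dims = c(n, nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

component_names <- function(design) {
  c(vapply(design$comps, `[[`, character(1), "id"),
    paste0("residual:", levels(design$site)))
}

default_start <- function(design) {
  vy <- var(design$y)
  k <- length(design$comps)
  theta <- c(rep(0.5 * vy / max(k, 1L), k), rep(0.5 * vy, nlevels(design$site)))
  setNames(theta, component_names(design))
}

# One restricted-likelihood evaluation at `theta`, returning the MME solution,
# the PEV blocks needed by the EM updates, the log-likelihood, and the EM
# update of every component.
mme_eval <- function(design, theta) {
  comps <- design$comps
  sites <- levels(design$site)
  res_names <- paste0("residual:", sites)
  sig_e <- theta[res_names]
  w <- unname(sig_e[as.integer(design$site)])^-1

  X <- design$X; Z <- design$Z
  p <- ncol(X); q <- design$q; n <- design$n
  Xw <- X * w
  Zw <- Matrix::Diagonal(x = w) %*% Z
  C <- matrix(0, p + q, p + q)
  C[1:p, 1:p] <- crossprod(X, Xw)
  C[1:p, p + 1:q] <- as.matrix(Matrix::crossprod(Matrix::Matrix(Xw, sparse = TRUE), Z))
  C[p + 1:q, 1:p] <- t(C[1:p, p + 1:q])
  C[p + 1:q, p + 1:q] <- as.matrix(Matrix::crossprod(Z, Zw))
  logdetG <- 0
  for (cp in comps) {
    idx <- p + cp$cols
    if (cp$type == "K") {
      tm <- design$terms[[cp$term]]
      C[idx, idx] <- C[idx, idx] + tm$Kinv / theta[cp$id]
      logdetG <- logdetG + length(cp$cols) * log(theta[cp$id]) + tm$logdetK
    } else {
      C[cbind(idx, idx)] <- C[cbind(idx, idx)] + 1 / theta[cp$id]
      logdetG <- logdetG + length(cp$cols) * log(theta[cp$id])
    }
  }
  rhs <- c(crossprod(Xw, design$y), as.numeric(Matrix::crossprod(Zw, design$y)))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    abort("Mixed-model coefficient matrix is singular; consider blending the relationship matrix.")
  }
  Cinv <- chol2inv(ch)
  s <- drop(Cinv %*% rhs)
  beta <- s[1:p]
  u <- s[p + 1:q]

  yPy <- sum(w * design$y^2) - sum(rhs * s)
  logdetR <- sum(log(sig_e)[as.integer(design$site)])
  loglik <- -0.5 * (logdetR + logdetG + 2 * sum(log(diag(ch))) + yPy)

  # EM updates
  theta_new <- theta
  for (cp in comps) {
    idx <- p + cp$cols
    qk <- length(cp$cols)
    blockPEV <- Cinv[idx, idx, drop = FALSE]
    if (cp$type == "K") {
      Kinv <- design$terms[[cp$term]]$Kinv
      uk <- u[cp$cols]
      theta_new[cp$id] <- (drop(crossprod(uk, Kinv %*% uk)) + sum(Kinv * blockPEV)) / qk
    } else {
      uk <- u[cp$cols]
      theta_new[cp$id] <- (sum(uk^2) + sum(diag(blockPEV))) / qk
    }
  }
  W <- Matrix::cbind2(Matrix::Matrix(X, sparse = TRUE), Z)
  ehat <- design$y - as.numeric(W %*% s)
  rowtr <- Matrix::rowSums((W %*% Cinv) * W)
  for (i in seq_along(sites)) {
    rows <- which(as.integer(design$site) == i)
    theta_new[res_names[i]] <-
      (sum(ehat[rows]^2) + sum(rowtr[rows])) / length(rows)
  }

  list(theta_new = theta_new, loglik = loglik, beta = beta, u = u,
       Cinv = Cinv, p = p, ehat = ehat)
}

#' REML variance components by EM iteration
#'
#' Expectation-maximisation REML on Henderson's mixed-model equations, with
#' optional Aitken extrapolation (accepted only when it does not decrease the
#' restricted likelihood). Components hitting the boundary are clamped at a
#' small floor (`1e-8` times the phenotypic variance) and reported in the
#' convergence record. Convergence is declared when the largest relative
#' component change falls below `tol`.
#'
#' @param design Design bundle from [build_design()].
#' @param start Optional named start values (see `component_names`); default
#'   splits half the phenotypic variance equally across random terms.
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param accelerate Use Aitken extrapolation every few iterations?
#' @param on_nonconvergence `"warn"` (default) or `"error"`.
#' @param verbose Print the likelihood and worst-converged component every
#'   25 iterations?
#' @return Named numeric vector of variance components with attributes
#'   `convergence` (list) and `loglik`.
#' @export
reml_estimate <- function(design, start = NULL, tol = 1e-6, max_iter = 500L,
                          accelerate = TRUE, on_nonconvergence = c("warn", "error"),
                          verbose = FALSE) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  floor_val <- 1e-8 * var(design$y)
  # denominator guard for the relative-change criterion: components this close
  # to the boundary are judged on movement relative to a small fraction of the
  # phenotypic variance, so a vanishing component cannot stall convergence
  change_ref <- 1e-4 * var(design$y)
  theta <- start %||% default_start(design)
  theta <- theta[component_names(design)]
  if (anyNA(theta)) abort("`start` must name every variance component.")
  history <- list() # last three iterates, oldest first
  change <- Inf
  ll <- -Inf
  iter <- 0L
  # components that decay monotonically toward zero make EM geometrically
  # slow; once one has spent a few iterations below a negligible share of the
  # phenotypic variance and is still shrinking, it is clamped at the floor
  # (reported via `floored`) and removed from the convergence criterion
  boundary_thresh <- 1e-4 * var(design$y)
  frozen <- setNames(rep(FALSE, length(theta)), names(theta))
  shrink_count <- setNames(integer(length(theta)), names(theta))
  ll_prev <- -Inf
  stagnant <- 0L
  reason <- "component_change"
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- mme_eval(design, theta)
    theta_next <- pmax(step$theta_new, floor_val)
    ll <- step$loglik
    shrinking <- (theta_next < theta & theta_next < boundary_thresh) |
      theta_next <= 2 * floor_val
    shrink_count <- ifelse(shrinking, shrink_count + 1L, 0L)
    frozen <- frozen | shrink_count >= 3L
    theta_next[frozen] <- floor_val
    history <- c(history, list(theta))
    if (length(history) > 3L) history <- history[-1L]
    change <- max(c(0, (abs(theta_next - theta) /
                          pmax(theta, change_ref))[!frozen]))
    if (accelerate && iter %% 3L == 0L && length(history) == 3L) {
      acc <- aitken_extrapolate(history, theta_next, floor_val)
      if (!is.null(acc)) {
        acc[frozen] <- floor_val
        trial <- mme_eval(design, acc)
        if (is.finite(trial$loglik) && trial$loglik >= ll - 1e-8 * abs(ll)) {
          theta_next <- pmax(trial$theta_new, floor_val)
          theta_next[frozen] <- floor_val
          ll <- trial$loglik
          history <- list() # the jump breaks the geometric decay pattern
        }
      }
    }
    if (verbose && iter %% 25L == 0L) {
      rel <- abs(theta_next - theta) / pmax(theta, change_ref)
      rel[frozen] <- 0
      inform(sprintf("iter %d logLik %.4f max change %.3g (%s)", iter, ll,
                     max(rel), names(theta)[which.max(rel)]))
    }
    theta <- theta_next
    if (change < tol) break
    # once the restricted likelihood has been flat for many iterations the
    # remaining component movement is numerical noise below the resolution of
    # the dense solves; treat as converged
    stagnant <- if (abs(ll - ll_prev) < 1e-9 * (1 + abs(ll))) stagnant + 1L else 0L
    ll_prev <- ll
    if (stagnant >= 10L) {
      reason <- "loglik_stagnation"
      break
    }
  }
  converged <- change < tol || reason == "loglik_stagnation"
  if (!converged) {
    msg <- paste0("REML did not converge in ", max_iter,
                  " iterations (last relative change ", signif(change, 3), ").")
    if (on_nonconvergence == "error") {
      cond <- rlang::error_cnd(class = "pinegs_reml_nonconvergence",
                               message = msg, theta = theta, change = change)
      stop(cond)
    }
    warn(msg)
  }
  floored <- names(theta)[theta <= floor_val * (1 + 1e-12)]
  attr(theta, "convergence") <- list(iterations = iter, converged = converged,
                                     change = change, floored = floored,
                                     floor = floor_val, criterion = reason)
  attr(theta, "loglik") <- ll
  theta
}

# componentwise Aitken delta-squared extrapolation from the last three EM
# iterates; returns NULL when the geometric-rate assumption is violated
aitken_extrapolate <- function(history, current, floor_val) {
  if (length(history) < 3L) return(NULL)
  t1 <- history[[1L]]; t2 <- history[[2L]]; t3 <- history[[3L]]
  d1 <- t2 - t1; d2 <- t3 - t2
  rate <- d2 / d1
  out <- current
  ok <- is.finite(rate) & rate > 0 & rate < 0.9999 & abs(d1) > 0
  out[ok] <- t2[ok] + d2[ok] / (1 - rate[ok])
  out <- pmax(out, floor_val)
  if (all(out == current)) NULL else out
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Generalized-least-squares fixed effects, BLUPs of every random term, and
#' prediction error variances (the diagonal blocks of the inverse coefficient
#' matrix) at the supplied variance components.
#'
#' @param design Design bundle from [build_design()].
#' @param vc Named variance-component vector (e.g. from [reml_estimate()]).
#' @return A list with `beta`, `blups` (named list of tibbles `level`, `blup`,
#'   `pev`), `vc`, `loglik`.
#' @export
solve_mme <- function(design, vc) {
  vc <- vc[component_names(design)]
  if (anyNA(vc)) abort("`vc` must name every variance component of the design.")
  if (any(vc <= 0)) abort("Variance components must be strictly positive.")
  step <- mme_eval(design, vc)
  p <- step$p
  offset <- 0L
  blups <- list()
  for (tm in design$terms) {
    idx <- offset + seq_along(tm$levels)
    blups[[tm$name]] <- tibble::tibble(
      level = tm$levels,
      blup = unname(step$u[idx]),
      pev = unname(diag(step$Cinv)[p + idx])
    )
    offset <- offset + length(tm$levels)
  }
  list(beta = setNames(step$beta, colnames(design$X)), blups = blups,
       vc = vc, loglik = step$loglik, Cinv = step$Cinv, p = p)
}

vc_tibble <- function(vc, method) {
  nm <- strsplit(names(vc), ":", fixed = TRUE)
  tibble::tibble(
    component = vapply(nm, `[[`, character(1), 1L),
    site = vapply(nm, function(x) if (length(x) > 1L) x[2L] else NA_character_, character(1)),
    variance = unname(vc)
  )
}

#' Fit the pedigree-based (ABLUP) evaluation model
#'
#' Composes [build_design()], [reml_estimate()] and [solve_mme()] for the
#' additive-pedigree model and returns a `gs_fit` with estimated breeding
#' values (EBVs) for every pedigree member, their prediction error variances
#' and the variance components.
#'
#' @param pheno Phenotype tibble with columns `clone`, `site`, `rep`, `set`,
#'   `block`, `trait`, `value` (the `trait` column may be omitted for
#'   single-trait data).
#' @param ped Pedigree tibble.
#' @param trait Trait to fit when `pheno` holds several traits.
#' @param spec Model specification, default [ablup_spec()].
#' @param ... Passed to [reml_estimate()] (`tol`, `max_iter`, `accelerate`,
#'   `start`, `on_nonconvergence`).
#' @return A `gs_fit` object; see [tidy.gs_fit()], [glance.gs_fit()],
#'   [autoplot.gs_fit()].
#' @export
fit_ablup <- function(pheno, ped, trait = NULL, spec = ablup_spec(), ...) {
  pheno <- select_trait(pheno, trait)
  ped <- sort_pedigree(ped)
  A <- build_A(ped)
  design <- build_design(pheno, spec, list(A = A))
  vc <- reml_estimate(design, ...)
  sol <- solve_mme(design, vc)
  new_gs_fit(method = "ablup", trait = attr(pheno, "trait"), design = design,
             sol = sol, vc = vc, relmats = list(A = A), spec = spec)
}

#' Fit the genomic (GBLUP) evaluation model
#'
#' Marker term `m` with genomic covariance `G` plus residual polygenic term
#' `a_star` with pedigree covariance `A`. Phenotyped clones without a row in
#' `Gmat` are excluded with a warning. The genomic breeding value (GEBV) is
#' the marker term alone — the scale on which PEV-based accuracy uses
#' `sigma2_m` — and `m + a_star` is also reported as the total EBV.
#'
#' @inheritParams fit_ablup
#' @param Gmat Genomic relationship matrix from [build_G()].
#' @return A `gs_fit` object.
#' @export
fit_gblup <- function(pheno, ped, Gmat, trait = NULL, spec = gblup_spec(), ...) {
  pheno <- select_trait(pheno, trait)
  drop_cl <- setdiff(unique(pheno$clone), rownames(Gmat))
  if (length(drop_cl) > 0L) {
    warn(paste0(length(drop_cl), " phenotyped clone(s) not genotyped; excluded."))
    pheno <- dplyr::filter(pheno, !.data$clone %in% drop_cl)
  }
  ped <- sort_pedigree(ped)
  A <- build_A(ped)
  design <- build_design(pheno, spec, list(A = A, G = Gmat))
  vc <- reml_estimate(design, ...)
  sol <- solve_mme(design, vc)
  new_gs_fit(method = "gblup", trait = attr(pheno, "trait"), design = design,
             sol = sol, vc = vc, relmats = list(A = A, G = Gmat), spec = spec)
}

select_trait <- function(pheno, trait) {
  if ("trait" %in% names(pheno)) {
    traits <- unique(pheno$trait)
    trait <- trait %||% traits[1L]
    if (!trait %in% traits) abort(paste0("Trait '", trait, "' not in the data."))
    pheno <- dplyr::filter(pheno, .data$trait == !!trait)
  } else {
    trait <- trait %||% "value"
  }
  attr(pheno, "trait") <- trait
  pheno
}

new_gs_fit <- function(method, trait, design, sol, vc, relmats, spec) {
  conv <- attr(vc, "convergence")
  genetic <- list()
  for (g in names(spec$genetic)) {
    K <- relmats[[spec$genetic[[g]]]]
    tb <- sol$blups[[g]]
    tb$F <- diag(K) - 1
    genetic[[g]] <- tb
  }
  structure(list(
    method = method, trait = trait, spec = spec,
    vc = vc_tibble(vc, method), theta = as.numeric(vc) |> setNames(names(vc)),
    beta = sol$beta, blups = sol$blups, genetic = genetic,
    loglik = attr(vc, "loglik") %||% sol$loglik,
    convergence = conv,
    n_obs = design$n, sites = levels(design$site),
    phenotyped = unique(design$clone)
  ), class = "gs_fit")
}

#' @exportS3Method base::print
print.gs_fit <- function(x, ...) {
  cat("<gs_fit> ", toupper(x$method), " fit of trait '", x$trait, "'\n", sep = "")
  cat(" ", x$n_obs, "observations over", length(x$sites), "site(s);",
      "REML", if (isTRUE(x$convergence$converged)) "converged" else "NOT converged",
      "in", x$convergence$iterations, "iterations\n")
  print(x$vc, n = nrow(x$vc))
  invisible(x)
}

#' Extract genetic-effect predictions from a fit
#'
#' EBVs (ABLUP) or GEBVs plus residual polygenic effects and the total EBV
#' (GBLUP), with per-individual PEV and the inbreeding-style diagonal offset
#' of the corresponding relationship matrix.
#'
#' @param fit A `gs_fit`.
#' @return A tibble with columns `id`, per-term predictions, `pev`, `F`.
#' @export
genetic_values <- function(fit) {
  if (fit$method == "ablup") {
    out <- fit$genetic$a
    names(out)[names(out) == "level"] <- "id"
    names(out)[names(out) == "blup"] <- "ebv"
    return(out)
  }
  m <- fit$genetic$m
  a_star <- fit$genetic$a_star
  out <- tibble::tibble(id = m$level, gebv = m$blup, pev = m$pev, F = m$F)
  out$a_star <- a_star$blup[match(out$id, a_star$level)]
  out$ebv_total <- out$gebv + dplyr::coalesce(out$a_star, 0)
  out
}

#' Broom-style tidiers for `gs_fit` objects
#'
#' `tidy()` returns the variance components (default) or the genetic-effect
#' predictions; `glance()` returns a one-row model summary.
#'
#' @param x,object A `gs_fit`.
#' @param effects `"varcomp"` or `"genetic"`.
#' @param ... Unused.
#' @export
tidy.gs_fit <- function(x, effects = c("varcomp", "genetic"), ...) {
  effects <- match.arg(effects)
  if (effects == "varcomp") x$vc else genetic_values(x)
}

#' @rdname tidy.gs_fit
#' @export
glance.gs_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, trait = x$trait, n_obs = x$n_obs,
    n_sites = length(x$sites), logLik = x$loglik,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot variance components of a fit
#'
#' Bar chart of the REML variance components, faceted homogeneous vs
#' per-site heterogeneous terms.
#'
#' @param object A `gs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_fit <- function(object, ...) {
  df <- object$vc
  df$site <- dplyr::coalesce(df$site, "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variance,
                                   fill = .data$site)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      title = paste0(toupper(object$method), ": ", object$trait),
      x = NULL, y = "variance component", fill = "site"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
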