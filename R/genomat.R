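#' Allele frequencies on a reference set
#'
#' Alternate-allele frequencies per marker, computed over a designated
#' reference set of individuals (typically a panel of unrelated trees, so the
#' frequencies are not distorted by family structure). Missing genotypes are
#' excluded marker-wise.
#'
#' @param G Genotype matrix, individuals x markers, entries 0/1/2 or `NA`.
#' @param reference Character vector of row labels to use; default all rows.
#' @return Named numeric vector `p` in `[0, 1]`, one entry per marker.
#' @export
allele_freq <- function(G, reference = NULL) {
  G <- check_genotypes(G)
  reference <- reference %||% rownames(G)
  missing_ref <- setdiff(reference, rownames(G))
  if (length(missing_ref) > 0L) {
    abort(paste0("Reference id(s) not genotyped: ",
                 paste(head(missing_ref, 5L), collapse = ", ")))
  }
  sub <- G[reference, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  if (any(n_obs == 0L)) {
    abort(paste0("Marker(s) with no non-missing reference genotype: ",
                 paste(head(colnames(sub)[n_obs == 0L], 5L), collapse = ", ")))
  }
  colSums(sub, na.rm = TRUE) / (2 * n_obs)
}

check_genotypes <- function(G) {
  if (!is.matrix(G)) abort("`G` must be a matrix (individuals x markers).")
  if (is.null(rownames(G)) || is.null(colnames(G))) {
    abort("Genotype matrix must carry individual rownames and marker colnames.")
  }
  bad <- !is.na(G) & !(G %in% c(0, 1, 2)) & (G < 0 | G > 2)
  if (any(bad)) abort("Genotype values must lie in [0, 2] or be NA.")
  G
}

#' Filter markers on minor allele frequency
#'
#' Markers whose minor allele frequency `min(p, 1 - p)` falls below `min_maf`
#' are dropped; a MAF exactly at the threshold is retained.
#'
#' @param G Genotype matrix.
#' @param p Allele-frequency vector aligned to `colnames(G)`.
#' @param min_maf Minimum minor allele frequency (default 0.03).
#' @return The genotype matrix restricted to retained markers.
#' @export
filter_maf <- function(G, p, min_maf = 0.03) {
  G <- check_genotypes(G)
  p <- align_freq(p, G)
  keep <- pmin(p, 1 - p) >= min_maf
  if (!any(keep)) warn("All markers removed by the MAF filter.")
  G[, keep, drop = FALSE]
}

align_freq <- function(p, G) {
  if (is.null(names(p))) {
    if (length(p) != ncol(G)) abort("`p` must align with the markers of `G`.")
    names(p) <- colnames(G)
    return(p)
  }
  missing_p <- setdiff(colnames(G), names(p))
  if (length(missing_p) > 0L) {
    abort(paste0("No allele frequency for marker(s): ",
                 paste(head(missing_p, 5L), collapse = ", ")))
  }
  p[colnames(G)]
}

#' Mean-impute missing genotypes
#'
#' Missing dosages are replaced by the marker mean over the non-missing
#' genotypes of a reference set (default: all individuals), leaving observed
#' values untouched. Using the same reference set as [allele_freq()] keeps
#' imputation and G-matrix centring consistent.
#'
#' @param G Genotype matrix with possible `NA`s.
#' @param reference Row labels whose means are used; default all rows.
#' @return A numeric matrix with no missing values, entries in `[0, 2]`.
#' @export
impute_mean <- function(G, reference = NULL) {
  G <- check_genotypes(G)
  reference <- reference %||% rownames(G)
  sub <- G[reference, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  if (any(n_obs == 0L)) {
    abort(paste0("Cannot impute marker(s) with all-missing reference genotypes: ",
                 paste(head(colnames(G)[n_obs == 0L], 5L), collapse = ", ")))
  }
  mu <- colSums(sub, na.rm = TRUE) / n_obs
  out <- G * 1.0
  idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(idx) > 0L) out[idx] <- mu[idx[, 2L]]
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p * (1 - p)))` with `W` the dosage matrix centred by
#' `2p` per marker. Under Hardy-Weinberg allele frequencies the diagonal
#' averages 1 and unrelated pairs average 0, putting G on the same scale as
#' the pedigree numerator relationship matrix.
#'
#' @param G Imputed genotype matrix (no `NA`s).
#' @param p Allele frequencies used for centring (and for the denominator),
#'   aligned to the markers.
#' @return Dense symmetric genomic relationship matrix with individual labels.
#' @export
build_G <- function(G, p) {
  if (anyNA(G)) abort("Genotype matrix must be imputed (no NA) before build_G().")
  G <- check_genotypes(G)
  p <- align_freq(p, G)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("All markers are fixed (2*sum(p*(1-p)) = 0); cannot normalize G.")
  W <- sweep(G, 2L, 2 * p, "-")
  out <- tcrossprod(W) / denom
  (out + t(out)) / 2
}

#' Blend a relationship matrix toward the identity
#'
#' `weight * K + (1 - weight) * I`, the standard stabilization applied before
#' inverting a (near-)singular genomic relationship matrix.
#'
#' @param K Square relationship matrix.
#' @param weight Weight on `K` (default 0.99).
#' @return Blended matrix.
#' @export
blend_relationship <- function(K, weight = 0.99) {
  if (nrow(K) != ncol(K)) abort("`K` must be square.")
  weight * K + (1 - weight) * diag(nrow(K))
}

# Inverse of a relationship matrix; blends toward I when numerically singular
# (Cholesky failure or pivot ratio below 1e-6) and reports the blend.
safe_rel_inverse <- function(K, label = "K") {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) / max(diag(ch)) < 1e-6) {
    pipeline_log("relmat", label, " not positive definite; blending 0.99*", label, " + 0.01*I")
    ch <- chol(blend_relationship(K))
  }
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(K)
  list(inv = inv, logdet = 2 * sum(log(diag(ch))))
}
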