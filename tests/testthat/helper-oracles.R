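# Independent oracles and small fixture builders used across the test files.

# Recursive coancestry f(i, j) computed straight from the definition, with
# memoisation; independent of the tabular-method code under test.
coancestry_oracle <- function(ped) {
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      s <- si[i]; d <- di[i]
      0.5 * (1 + if (!is.na(s) && !is.na(d)) f(s, d) else 0)
    } else {
      # j is the later individual in pedigree order
      s <- si[j]; d <- di[j]
      0.5 * ((if (!is.na(s)) f(i, s) else 0) + (if (!is.na(d)) f(i, d) else 0))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# Random valid (sorted) pedigree: founders plus individuals whose parents are
# drawn from earlier individuals, with some unknown parents.
random_pedigree <- function(n, n_founders = max(2L, n %/% 3L)) {
  id <- sprintf("i%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- id[seq_len(i - 1L)]
    if (stats::runif(1) < 0.85) sire[i] <- sample(pool, 1L)
    if (stats::runif(1) < 0.85) dam[i] <- sample(pool, 1L)
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# Brute-force trio exclusion count: enumerate the four transmitted-allele
# combinations per marker.
trio_oracle <- function(prog, p1, p2) {
  gametes <- function(g) if (g == 0L) c(0L, 0L) else if (g == 2L) c(1L, 1L) else c(0L, 1L)
  excl <- 0L; inf <- 0L
  for (k in seq_along(prog)) {
    if (is.na(prog[k]) || is.na(p1[k]) || is.na(p2[k])) next
    inf <- inf + 1L
    possible <- unique(as.vector(outer(gametes(p1[k]), gametes(p2[k]), "+")))
    if (!prog[k] %in% possible) excl <- excl + 1L
  }
  c(exclusions = excl, informative = inf)
}

# Direct GLS solution of the mixed model (dense, no MME): fixed effects,
# BLUPs and PEV for one K-structured random term plus iid terms.
gls_oracle <- function(design, vc) {
  Z <- as.matrix(design$Z); X <- design$X; y <- design$y
  R <- diag(vc[paste0("residual:", as.character(design$site))],
            nrow = design$n)
  Gb <- matrix(0, design$q, design$q)
  for (cp in design$comps) {
    if (cp$type == "K") {
      Gb[cp$cols, cp$cols] <- vc[cp$id] * design$terms[[cp$term]]$K
    } else {
      Gb[cbind(cp$cols, cp$cols)] <- vc[cp$id]
    }
  }
  V <- Z %*% Gb %*% t(Z) + R
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  u <- Gb %*% t(Z) %*% Vi %*% (y - X %*% beta)
  pev <- diag(Gb - Gb %*% t(Z) %*% P %*% Z %*% Gb)
  list(beta = drop(beta), u = drop(u), pev = pev)
}

# Tiny clonal trial phenotype table on a full-sib pedigree; returns the
# pedigree, phenotypes and the true breeding values used.
tiny_trial <- function(n_fam = 5L, prog_per_fam = 6L, ramets = 2L,
                       sites = c("s1", "s2"), h2 = 0.3, seed = 1L) {
  withr::local_seed(seed)
  sires <- sprintf("S%d", seq_len(n_fam))
  dams <- sprintf("D%d", seq_len(n_fam))
  prog <- as.vector(vapply(seq_len(n_fam), function(f) {
    sprintf("F%dC%d", f, seq_len(prog_per_fam))
  }, character(prog_per_fam)))
  ped <- tibble::tibble(
    id = c(sires, dams, prog),
    sire = c(rep(NA, 2 * n_fam), rep(sires, each = prog_per_fam)),
    dam = c(rep(NA, 2 * n_fam), rep(dams, each = prog_per_fam))
  )
  s2a <- h2; s2e <- 1 - h2
  bv_par <- stats::rnorm(2 * n_fam, 0, sqrt(s2a))
  names(bv_par) <- c(sires, dams)
  bv <- vapply(seq_along(prog), function(i) {
    f <- (i - 1L) %/% prog_per_fam + 1L
    0.5 * (bv_par[sires[f]] + bv_par[dams[f]]) + stats::rnorm(1, 0, sqrt(0.5 * s2a))
  }, numeric(1))
  names(bv) <- prog
  rows <- expand.grid(clone = prog, site = sites, ramet = seq_len(ramets),
                      stringsAsFactors = FALSE)
  rows$value <- 10 + bv[rows$clone] + stats::rnorm(nrow(rows), 0, sqrt(s2e))
  list(ped = ped,
       pheno = tibble::tibble(clone = rows$clone, site = rows$site,
                              value = rows$value),
       bv = bv)
}

# model specs for tiny_trial data, which carries no rep/set/block strata
spec_a0 <- function() ablup_spec(strata = character(0))
spec_g0 <- function() gblup_spec(strata = character(0))
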