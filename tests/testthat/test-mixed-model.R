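test_that("design matrices map ramets to clone levels and absorb single-site", {
  ped <- tibble::tibble(id = c("c1", "c2"), sire = NA_character_, dam = NA_character_)
  A <- build_A(ped)
  pheno <- tibble::tibble(clone = rep(c("c1", "c2"), each = 2), site = "s1",
                          value = rnorm(4))
  spec <- model_spec(c(a = "A"), strata = character(0), nonadditive = FALSE)
  d <- build_design(pheno, spec, list(A = A))
  Za <- as.matrix(d$terms$a$Z)
  expect_equal(dim(Za), c(4L, 2L))
  expect_equal(unname(colSums(Za)), c(2, 2))
  expect_equal(colnames(d$X), "(Intercept)")
})

test_that("per-observation blocks give an identity incidence matrix", {
  ped <- tibble::tibble(id = sprintf("c%d", 1:4), sire = NA_character_, dam = NA_character_)
  pheno <- tibble::tibble(clone = sprintf("c%d", 1:4), site = "s1",
                          rep = "1", set = "1", block = as.character(1:4),
                          value = rnorm(4))
  spec <- model_spec(c(a = "A"), strata = "block", nonadditive = FALSE)
  expect_warning(d <- build_design(pheno, spec, list(A = build_A(ped))), NA)
  Zb <- as.matrix(d$terms$block$Z)
  expect_equal(dim(Zb), c(4L, 4L))
  expect_equal(unname(rowSums(Zb)), rep(1, 4))
  expect_equal(unname(colSums(Zb)), rep(1, 4))
})

test_that("missing strata are dropped with a warning and absent clones error", {
  ped <- tibble::tibble(id = "c1", sire = NA_character_, dam = NA_character_)
  pheno <- tibble::tibble(clone = "c1", site = "s1", value = 1)
  spec <- model_spec(c(a = "A"), strata = "rep", nonadditive = FALSE)
  expect_warning(build_design(pheno, spec, list(A = build_A(ped))), "dropped")
  pheno2 <- tibble::tibble(clone = "c9", site = "s1", value = 1)
  expect_error(
    suppressWarnings(build_design(pheno2, spec, list(A = build_A(ped)))),
    "c9"
  )
})

test_that("REML matches the balanced one-way closed form", {
  withr::local_seed(42)
  nc <- 30; nr <- 4
  cl <- rep(sprintf("c%02d", 1:nc), each = nr)
  u <- rnorm(nc, 0, sqrt(2))
  y <- 5 + u[match(cl, unique(cl))] + rnorm(nc * nr)
  pheno <- tibble::tibble(clone = cl, site = "s1", value = y)
  spec <- model_spec(setNames(character(0), character(0)),
                     strata = character(0), nonadditive = TRUE)
  d <- build_design(pheno, spec, list())
  vc <- reml_estimate(d, tol = 1e-9, max_iter = 1000)
  ybar <- tapply(y, cl, mean)
  msb <- nr * sum((ybar - mean(y))^2) / (nc - 1)
  msw <- sum((y - ybar[cl])^2) / (nc * (nr - 1))
  expect_equal(unname(vc["d"]), (msb - msw) / nr, tolerance = 1e-6)
  expect_equal(unname(vc["residual:s1"]), msw, tolerance = 1e-6)
})

test_that("a truly zero variance component collapses toward the boundary", {
  withr::local_seed(43)
  cl <- rep(sprintf("c%02d", 1:50), each = 6)
  pheno <- tibble::tibble(clone = cl, site = "s1", value = rnorm(300))
  spec <- model_spec(setNames(character(0), character(0)),
                     strata = character(0), nonadditive = TRUE)
  d <- build_design(pheno, spec, list())
  vc <- reml_estimate(d, tol = 1e-8, max_iter = 500)
  conv <- attr(vc, "convergence")
  # the clone variance is zero in truth; its REML estimate sits essentially
  # at the boundary relative to the residual variance
  expect_lte(unname(vc["d"]), 0.02 * var(pheno$value))
  expect_true(conv$converged)
})

test_that("plain EM iterations never decrease the restricted likelihood", {
  withr::local_seed(44)
  tt <- tiny_trial(n_fam = 4L, prog_per_fam = 5L, seed = 3L)
  A <- build_A(sort_pedigree(tt$ped))
  spec <- model_spec(c(a = "A"), strata = character(0), nonadditive = TRUE)
  d <- build_design(tt$pheno, spec, list(A = A))
  theta <- pinegs:::default_start(d)
  ll_prev <- -Inf
  for (i in 1:40) {
    st <- pinegs:::mme_eval(d, theta)
    expect_gte(st$loglik, ll_prev - 1e-8)
    ll_prev <- st$loglik
    theta <- pmax(st$theta_new, 1e-10)
  }
})

test_that("MME solutions equal direct GLS on random small instances", {
  withr::local_seed(45)
  for (rep in 1:6) {
    n_cl <- sample(5:10, 1)
    ped <- random_pedigree(n_cl + 4L, n_founders = 4L)
    A <- build_A(ped)
    clones <- ped$id[(nrow(ped) - n_cl + 1L):nrow(ped)]
    pheno <- tibble::tibble(
      clone = rep(clones, each = 3),
      site = rep_len(c("s1", "s2"), 3 * n_cl),
      value = rnorm(3 * n_cl, 8)
    )
    spec <- model_spec(c(a = "A"), strata = character(0), nonadditive = TRUE)
    d <- build_design(pheno, spec, list(A = A))
    vc <- setNames(runif(4, 0.2, 1.5),
                   c("a", "d", "residual:s1", "residual:s2"))
    sol <- solve_mme(d, vc)
    oracle <- gls_oracle(d, vc)
    expect_lt(max(abs(sol$beta - oracle$beta)), 1e-8)
    u_hat <- unlist(lapply(sol$blups, `[[`, "blup"), use.names = FALSE)
    expect_lt(max(abs(u_hat - oracle$u)), 1e-8)
    pev_hat <- unlist(lapply(sol$blups, `[[`, "pev"), use.names = FALSE)
    expect_lt(max(abs(pev_hat - oracle$pev)), 1e-8)
  }
})

test_that("duplicating every observation leaves the GLS fixed effects unchanged", {
  withr::local_seed(46)
  tt <- tiny_trial(n_fam = 3L, prog_per_fam = 4L, seed = 5L)
  A <- build_A(sort_pedigree(tt$ped))
  spec <- model_spec(c(a = "A"), strata = character(0), nonadditive = FALSE)
  d1 <- build_design(tt$pheno, spec, list(A = A))
  d2 <- build_design(dplyr::bind_rows(tt$pheno, tt$pheno), spec, list(A = A))
  vc <- c(a = 0.4, `residual:s1` = 0.6, `residual:s2` = 0.8)
  expect_equal(solve_mme(d1, vc)$beta, solve_mme(d2, vc)$beta, tolerance = 1e-10)
})

test_that("a floored variance component shrinks its BLUPs to zero", {
  withr::local_seed(47)
  tt <- tiny_trial(n_fam = 3L, prog_per_fam = 4L, seed = 6L)
  A <- build_A(sort_pedigree(tt$ped))
  spec <- model_spec(c(a = "A"), strata = character(0), nonadditive = FALSE)
  d <- build_design(tt$pheno, spec, list(A = A))
  sol <- solve_mme(d, c(a = 1e-10, `residual:s1` = 1, `residual:s2` = 1))
  expect_lt(max(abs(sol$blups$a$blup)), 1e-6)
})

test_that("ABLUP EBVs track true breeding values, more tightly at higher h2", {
  withr::local_seed(48)
  cors <- vapply(c(0.15, 0.6), function(h2) {
    tt <- tiny_trial(n_fam = 12L, prog_per_fam = 8L, ramets = 3L,
                     h2 = h2, seed = round(100 * h2))
    fit <- fit_ablup(tt$pheno, tt$ped, spec = spec_a0(), tol = 1e-5, max_iter = 200)
    gv <- genetic_values(fit)
    cor(gv$ebv[match(names(tt$bv), gv$id)], tt$bv)
  }, numeric(1))
  expect_gt(cors[1], 0)
  expect_gt(cors[2], cors[1])
})

test_that("GBLUP with G = A reproduces the ABLUP evaluation", {
  withr::local_seed(49)
  tt <- tiny_trial(n_fam = 8L, prog_per_fam = 6L, ramets = 2L, seed = 9L)
  ped <- sort_pedigree(tt$ped)
  A <- build_A(ped)
  fit_a <- fit_ablup(tt$pheno, ped, spec = spec_a0(), tol = 1e-5, max_iter = 500)
  fit_g <- fit_gblup(tt$pheno, ped, Gmat = A, spec = spec_g0(), tol = 1e-5, max_iter = 500)
  gv_a <- genetic_values(fit_a)
  gv_g <- genetic_values(fit_g)
  total <- gv_g$ebv_total[match(gv_a$id, gv_g$id)]
  expect_gt(cor(total, gv_a$ebv), 0.99)
})

test_that("PEV never exceeds the theoretical (1 + F) sigma2 bound", {
  withr::local_seed(50)
  tt <- tiny_trial(n_fam = 6L, prog_per_fam = 5L, seed = 12L)
  fit <- fit_ablup(tt$pheno, tt$ped, spec = spec_a0(), tol = 1e-5, max_iter = 200)
  tb <- fit$genetic$a
  s2a <- fit$vc$variance[fit$vc$component == "a"]
  expect_true(all(tb$pev <= (1 + tb$F) * s2a + 1e-8))
  acc <- accuracy_summary(fit)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
})

test_that("tidy and glance expose components and convergence", {
  withr::local_seed(51)
  tt <- tiny_trial(n_fam = 3L, prog_per_fam = 4L, seed = 13L)
  fit <- fit_ablup(tt$pheno, tt$ped, spec = spec_a0(), tol = 1e-4, max_iter = 100)
  td <- tidy(fit)
  expect_true(all(c("component", "site", "variance") %in% names(td)))
  expect_true(all(td$variance >= 0))
  gl <- glance(fit)
  expect_identical(gl$method, "ablup")
  expect_true(is.finite(gl$logLik))
  expect_s3_class(autoplot(fit), "ggplot")
})
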