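small_cfg <- function(..., traits = list(score = trait_config())) {
  sim_config(
    series = list(list(name = "A", n_founders = 20L, n_progeny = 60L,
                       mating = "single_pair", sites = c("s1", "s2"))),
    n_markers = 200L, n_unrelated = 10L, traits = traits,
    ...
  )
}

test_that("founder genotypes respect the MAF bounds and the seed", {
  cfg <- small_cfg(seed = 5L)
  G1 <- simulate_founders(cfg)
  G2 <- simulate_founders(cfg)
  expect_identical(G1, G2)
  maf_hat <- pmin(colMeans(G1) / 2, 1 - colMeans(G1) / 2)
  # binomial sampling error at n = 30 individuals: allow 3 SE outside bounds
  se <- sqrt(0.5 * 0.5 / (2 * nrow(G1)))
  expect_true(all(maf_hat >= cfg$maf_bounds[1] - 3 * se))
  cfg50 <- small_cfg(maf_bounds = c(0.5, 0.5), seed = 6L)
  G50 <- simulate_founders(cfg50)
  expect_lt(abs(mean(G50) - 1), 3 * sqrt(0.5 / (length(G50))))
})

test_that("mating designs produce the advertised family structures", {
  cfg <- small_cfg(seed = 7L)
  ped <- simulate_pedigree(cfg)
  prog <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(prog), 60L)
  # single-pair: every sire always mates the same dam
  expect_true(all(tapply(prog$dam, prog$sire, function(x) length(unique(x))) == 1))
  expect_error(
    simulate_pedigree(sim_config(series = list(list(name = "X", n_founders = 5L,
                                                    n_progeny = 4L,
                                                    mating = "single_pair",
                                                    sites = "s1")))),
    "even"
  )
  fac <- sim_config(series = list(list(name = "F", n_founders = 8L,
                                       n_progeny = 40L, mating = "factorial",
                                       sites = "s1")), seed = 8L)
  pf <- simulate_pedigree(fac)
  progf <- pf[!is.na(pf$sire), ]
  expect_true(all(progf$sire != progf$dam))
  expect_gt(length(unique(paste(progf$sire, progf$dam))), 8L)
})

test_that("gene drop transmits alleles by Mendelian rules", {
  ped <- tibble::tibble(id = c("S", "D", paste0("C", 1:2000)),
                        sire = c(NA, NA, rep("S", 2000)),
                        dam = c(NA, NA, rep("D", 2000)))
  founders <- matrix(c(0L, 2L, 1L,
                       0L, 0L, 1L), 2, 3, byrow = TRUE,
                     dimnames = list(c("S", "D"), c("m1", "m2", "m3")))
  G <- gene_drop(ped, founders, seed = 9L)
  expect_true(all(G[-(1:2), "m1"] == 0L))  # 0 x 0 -> 0
  expect_true(all(G[-(1:2), "m2"] == 1L))  # 2 x 0 -> 1
  # het x het -> 1/4, 1/2, 1/4
  tab <- tabulate(G[-(1:2), "m3"] + 1L, nbins = 3L)
  expect_gt(stats::chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
})

test_that("phenotypes decompose into the configured variance pieces", {
  # all variance off except residual: phenotypic variance tracks sigma2_e
  cfg <- small_cfg(
    traits = list(tr = trait_config(mean = 0, sigma2_a = 0, pct_va = 0,
                                    sigma2_d = 0, sigma2_r = 0, sigma2_w = 0,
                                    sigma2_b = 0, sigma2_e = 1)),
    seed = 10L
  )
  dat <- simulate_dataset(cfg)
  v_site <- tapply(dat$phenotypes$value, dat$phenotypes$site, var)
  expect_true(all(abs(v_site - 1) < 0.25))

  # noise-free limit: clone means equal a + d exactly
  cfg0 <- small_cfg(
    traits = list(tr = trait_config(mean = 0, sigma2_a = 0.5, pct_va = 60,
                                    sigma2_d = 0.2, sigma2_r = 0, sigma2_w = 0,
                                    sigma2_b = 0, sigma2_e = 1e-12)),
    seed = 11L
  )
  dat0 <- simulate_dataset(cfg0)
  ph <- dat0$phenotypes[dat0$phenotypes$site == "s1", ]
  cm <- tapply(ph$value, ph$clone, mean)
  tr <- dat0$truth$tr
  bv <- setNames(tr$breeding_values$bv_total, tr$breeding_values$id)
  expected <- bv[names(cm)] + tr$d[names(cm)] + tr$site_effects["s1"]
  expect_lt(max(abs(cm - expected)), 1e-4)
})

test_that("realized additive variance matches the configuration at scale", {
  cfg <- sim_config(
    series = list(list(name = "A", n_founders = 100L, n_progeny = 1000L,
                       mating = "single_pair", sites = "s1")),
    n_markers = 300L, n_unrelated = 0L, ramets_per_site = 1L,
    traits = list(tr = trait_config(sigma2_a = 0.4, pct_va = 100)),
    seed = 12L
  )
  founders <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg)
  geno <- gene_drop(ped, founders, seed = 13L)
  attr(geno, "freq_true") <- attr(founders, "freq_true")
  sim <- simulate_phenotypes(ped, geno, cfg)
  bv <- sim$truth$tr$breeding_values
  prog_bv <- bv$bv_total[grepl("_C", bv$id)]
  expect_lt(abs(var(prog_bv) - 0.4) / 0.4, 0.10)
})

test_that("categorical mapping lands scores on the requested scale", {
  cfg <- small_cfg(categorical = list(score = "9pt"), seed = 14L)
  dat <- simulate_dataset(cfg)
  expect_true(all(dat$phenotypes$value %in% 1:9))
})

test_that("pedigree error injection corrupts the requested fraction", {
  cfg <- small_cfg(seed = 15L)
  ped <- simulate_pedigree(cfg)
  out0 <- inject_pedigree_errors(ped, 0, seed = 1L)
  expect_identical(out0$pedigree, ped)
  expect_length(out0$corrupted, 0L)
  out1 <- inject_pedigree_errors(ped, 1, seed = 2L)
  expect_length(out1$corrupted, 60L)
  prog <- function(p) p[!is.na(p$sire), c("sire", "dam")]
  expect_true(all(rowSums(prog(out1$pedigree) != prog(ped)) >= 1))

  big <- tibble::tibble(
    id = c(sprintf("P%02d", 1:10), sprintf("C%04d", 1:1000)),
    sire = c(rep(NA, 10), rep(sprintf("P%02d", 1:5), 200)),
    dam = c(rep(NA, 10), rep(sprintf("P%02d", 6:10), 200))
  )
  out <- inject_pedigree_errors(big, 0.5, seed = 3L)
  frac <- length(out$corrupted) / 1000
  expect_lt(abs(frac - 0.5), 0.05)
  expect_error(inject_pedigree_errors(ped, 0.5, candidates = "A_P001"),
               "at least two")
})

test_that("genotype noise injection hits the configured rates", {
  withr::local_seed(16)
  G <- matrix(rbinom(20000, 2, 0.4), 100, 200,
              dimnames = list(sprintf("i%03d", 1:100), sprintf("M%03d", 1:200)))
  out <- inject_genotype_noise(G, error_rate = 0.05, missing_rate = 0.08, seed = 4L)
  expect_identical(inject_genotype_noise(G, 0.05, 0.08, seed = 4L), out)
  expect_identical(inject_genotype_noise(G, 0, 0, seed = 5L), G)
  miss <- mean(is.na(out))
  expect_lt(abs(miss - 0.08), 0.01)
  chg <- mean(out[!is.na(out)] != G[!is.na(out)])
  expect_lt(abs(chg - 0.05), 0.01)
})

test_that("the full dataset generator is reproducible from config and seed", {
  cfg <- small_cfg(seed = 17L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$documented_pedigree, d2$documented_pedigree)
  d3 <- simulate_dataset(cfg, seed = 18L)
  expect_false(identical(d1$genotypes, d3$genotypes))
})

test_that("heritability from a badly wrong pedigree is biased downward", {
  h2_pair <- function(seed) {
    cfg <- sim_config(
      series = list(list(name = "A", n_founders = 20L, n_progeny = 80L,
                         mating = "single_pair", sites = "s1")),
      n_markers = 2L, n_unrelated = 0L, ramets_per_site = 2L,
      traits = list(tr = trait_config(sigma2_a = 0.35, pct_va = 0,
                                      sigma2_d = 0.05, sigma2_e = 0.6)),
      pedigree_error_rate = 0.5, seed = seed
    )
    dat <- simulate_dataset(cfg)
    args <- list(pheno = dat$phenotypes, tol = 1e-4, max_iter = 150)
    f_true <- suppressWarnings(do.call(fit_ablup, c(args, list(ped = dat$true_pedigree))))
    f_bad <- suppressWarnings(do.call(fit_ablup, c(args, list(ped = dat$documented_pedigree))))
    c(true = h2_pedigree(f_true, "s1"), bad = h2_pedigree(f_bad, "s1"))
  }
  res <- vapply(1:20, h2_pair, numeric(2))
  wins <- sum(res["bad", ] < res["true", ])
  expect_lt(stats::binom.test(wins, 20, alternative = "greater")$p.value, 0.05)
  expect_lt(mean(res["bad", ]), mean(res["true", ]))
})
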