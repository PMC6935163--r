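make_geno <- function(mat, ids = sprintf("i%d", seq_len(nrow(mat))),
                      markers = sprintf("M%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(ids, markers)
  mat
}

test_that("panel selection applies call-rate, MAF and duplicate-marker rules", {
  withr::local_seed(5)
  n <- 60
  base <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  G <- cbind(
    base[, 1],              # duplicate pair (r2 = 1)
    base[, 1],
    rbinom(n, 2, 0.05),     # low MAF
    base[, 2],
    base[, 3]
  )
  G[1:20, 4] <- NA          # call rate 2/3 < 0.75
  G <- make_geno(G, markers = paste0("M", 1:5))
  panel <- select_panel(G, call_rate_min = 0.75, maf_range = c(0.1, 0.5),
                        hwe_alpha = 1e-6, ld_r2_max = 0.2)
  expect_false("M4" %in% panel$marker)          # call rate
  expect_false("M3" %in% panel$marker)          # MAF
  expect_equal(sum(c("M1", "M2") %in% panel$marker), 1L)  # LD prune keeps one
  expect_true("M5" %in% panel$marker)
  rem <- attr(panel, "removed")
  expect_gte(rem[["ld"]], 1)
})

test_that("MAF window retains exactly the in-range markers", {
  withr::local_seed(6)
  G <- make_geno(cbind(rbinom(400, 2, 0.10), rbinom(400, 2, 0.40),
                       rbinom(400, 2, 0.50)))
  panel <- select_panel(G, call_rate_min = 0, maf_range = c(0.35, 0.5),
                        hwe_alpha = 0, ld_r2_max = 1)
  expect_setequal(panel$marker, c("M2", "M3"))
  expect_error(select_panel(G, maf_range = c(0.49999, 0.5), call_rate_min = 0,
                            hwe_alpha = 0, ld_r2_max = 1e-9),
               "relax")
})

test_that("trio exclusion counts match the spec cases", {
  expect_equal(trio_exclusions(2L, 0L, 0L), c(exclusions = 1L, informative = 1L))
  expect_equal(trio_exclusions(2L, 2L, 0L), c(exclusions = 1L, informative = 1L))
  expect_equal(trio_exclusions(1L, 2L, 0L), c(exclusions = 0L, informative = 1L))
  expect_equal(trio_exclusions(1L, 1L, 1L), c(exclusions = 0L, informative = 1L))
  expect_equal(trio_exclusions(NA_integer_, 1L, 1L),
               c(exclusions = 0L, informative = 0L))
  expect_error(trio_exclusions(c(0L, 1L), 0L, 0L), "equal length")
})

test_that("trio exclusions are parent-symmetric and match the enumeration oracle", {
  withr::local_seed(11)
  for (rep in 1:25) {
    L <- 40
    g <- function() {
      v <- rbinom(L, 2, runif(1, 0.2, 0.8))
      v[runif(L) < 0.1] <- NA
      as.integer(v)
    }
    prog <- g(); p1 <- g(); p2 <- g()
    expect_identical(trio_exclusions(prog, p1, p2), trio_exclusions(prog, p2, p1))
    expect_identical(trio_exclusions(prog, p1, p2), trio_oracle(prog, p1, p2))
  }
})

# Small gene-drop world shared by the assignment tests.
drop_world <- function(n_parents = 20L, n_progeny = 50L, n_markers = 300L,
                       error_rate = 0, seed = 42L) {
  withr::local_seed(seed)
  parents <- sprintf("P%02d", seq_len(n_parents))
  prog <- sprintf("C%02d", seq_len(n_progeny))
  sire <- sample(parents, n_progeny, replace = TRUE)
  dam <- vapply(sire, function(s) sample(setdiff(parents, s), 1), character(1))
  ped <- tibble::tibble(
    id = c(parents, prog),
    sire = c(rep(NA, n_parents), sire),
    dam = c(rep(NA, n_parents), unname(dam))
  )
  p <- runif(n_markers, 0.3, 0.7)
  founders <- make_geno(
    matrix(rbinom(n_parents * n_markers, 2, rep(p, each = n_parents)),
           n_parents, n_markers),
    ids = parents, markers = sprintf("M%03d", seq_len(n_markers))
  )
  G <- gene_drop(ped, founders, seed = seed + 1L)
  if (error_rate > 0) {
    G <- inject_genotype_noise(G, error_rate, 0, seed = seed + 2L)
  }
  list(ped = ped, G = G, markers = colnames(G))
}

test_that("minimum-exclusion assignment picks the documented pair when it wins", {
  w <- drop_world(n_parents = 8L, n_progeny = 6L, n_markers = 120L)
  out <- assign_parentage(progeny = "C01", candidates = sprintf("P%02d", 1:8),
                          G = w$G, panel = w$markers, documented = w$ped)
  doc <- w$ped[w$ped$id == "C01", ]
  expect_identical(sort(c(out$parent1, out$parent2)), sort(c(doc$sire, doc$dam)))
  expect_identical(out$status, "confirmed")
  expect_equal(out$exclusions, 0L)
})

test_that("error-free gene-drop trios have zero exclusions, wrong homozygotes at least one", {
  w <- drop_world(n_parents = 10L, n_progeny = 10L, n_markers = 150L)
  for (i in 1:10) {
    pr <- sprintf("C%02d", i)
    doc <- w$ped[w$ped$id == pr, ]
    ex <- trio_exclusions(w$G[pr, ], w$G[doc$sire, ], w$G[doc$dam, ])
    expect_equal(unname(ex["exclusions"]), 0L)
  }
  # a pair opposite-homozygous to the progeny at >= 1 marker scores >= 1
  pr <- w$G["C01", ]
  fake <- 2L - pr
  ex <- trio_exclusions(pr, fake, fake)
  expect_gte(unname(ex["exclusions"]), 1L)
})

test_that("assignment recovers true parents with 5% genotyping error", {
  w <- drop_world(n_parents = 20L, n_progeny = 50L, n_markers = 300L,
                  error_rate = 0.05)
  prog <- sprintf("C%02d", 1:50)
  out <- assign_parentage(prog, sprintf("P%02d", 1:20), w$G, w$markers, w$ped,
                          max_exclusion_rate = 0.05)
  truth <- w$ped[match(prog, w$ped$id), ]
  hits <- mapply(function(a1, a2, s, d) identical(sort(c(a1, a2)), sort(c(s, d))),
                 out$parent1, out$parent2, truth$sire, truth$dam)
  expect_gte(mean(hits), 0.95)
})

test_that("assignment errors are informative", {
  w <- drop_world(n_parents = 6L, n_progeny = 4L, n_markers = 50L)
  expect_error(assign_parentage("nope", sprintf("P%02d", 1:6), w$G, w$markers, w$ped),
               "not genotyped")
  expect_error(assign_parentage("C01", character(0), w$G, w$markers, w$ped),
               "candidates")
})

test_that("pedigree correction substitutes assigned pairs and summarises", {
  w <- drop_world(n_parents = 10L, n_progeny = 20L, n_markers = 200L)
  prog <- sprintf("C%02d", 1:20)
  out <- assign_parentage(prog, sprintf("P%02d", 1:10), w$G, w$markers, w$ped)
  res <- correct_pedigree(w$ped, out)
  expect_equal(res$summary$pct_confirmed, 100)
  expect_equal(res$summary$pct_parents_reassigned, 0)
  corr <- res$pedigree[match(w$ped$id, res$pedigree$id), ]
  expect_equal(corr$sire, w$ped$sire)

  # corrupt the documentation completely: nothing can be confirmed
  doc <- w$ped
  doc$sire[doc$id %in% prog] <- "P01"
  doc$dam[doc$id %in% prog] <- "P02"
  really_wrong <- !(w$ped$sire %in% c("P01", "P02") &
                      w$ped$dam %in% c("P01", "P02"))[match(prog, w$ped$id)]
  out2 <- assign_parentage(prog[really_wrong], sprintf("P%02d", 1:10),
                           w$G, w$markers, doc)
  expect_equal(correct_pedigree(doc, out2)$summary$pct_confirmed, 0)

  expect_error(correct_pedigree(w$ped, dplyr::mutate(out, progeny = paste0("zz", progeny))),
               "absent")
})

test_that("confirmed fraction tracks an injected documentation error rate", {
  w <- drop_world(n_parents = 16L, n_progeny = 60L, n_markers = 250L, seed = 9L)
  inj <- inject_pedigree_errors(w$ped, rate = 0.5,
                                candidates = sprintf("P%02d", 1:16), seed = 10L)
  prog <- sprintf("C%02d", 1:60)
  out <- assign_parentage(prog, sprintf("P%02d", 1:16), w$G, w$markers,
                          inj$pedigree)
  res <- correct_pedigree(inj$pedigree, out)
  # binomial 3 sigma around 50% at n = 60 is +/- 19.4 percentage points
  expect_lt(abs(res$summary$pct_confirmed - 50), 3 * sqrt(0.25 / 60) * 100)
})
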