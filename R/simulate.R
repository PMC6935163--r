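#' Trait configuration for the trial simulator
#'
#' Variance components on the latent Gaussian scale of one trait. The total
#' additive variance `sigma2_a` is split between a marker-explained part
#' (`pct_va` percent, generated from marker effects) and a residual polygenic
#' part (sampled down the pedigree), so marker-captured-variance recovery is
#' directly testable. Environmental strata variances may be scalars (recycled
#' over sites) or named per-site vectors, giving heterogeneous variances.
#'
#' @param mean Trait mean (score units).
#' @param sigma2_a Total additive variance.
#' @param pct_va Percent of additive variance at markers (0-100).
#' @param sigma2_d Clone-level non-additive variance.
#' @param sigma2_r,sigma2_w,sigma2_b Replicate, set-within-replicate and
#'   incomplete-block variances (scalar or per-site).
#' @param sigma2_e Residual variance (scalar or per-site).
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(mean = 6.5, sigma2_a = 0.25, pct_va = 80,
                         sigma2_d = 0.08, sigma2_r = 0.05, sigma2_w = 0.04,
                         sigma2_b = 0.04, sigma2_e = 0.63) {
  vals <- list(mean = mean, sigma2_a = sigma2_a, pct_va = pct_va,
               sigma2_d = sigma2_d, sigma2_r = sigma2_r, sigma2_w = sigma2_w,
               sigma2_b = sigma2_b, sigma2_e = sigma2_e)
  if (any(unlist(vals[-c(1, 3)]) < 0)) abort("Variances must be non-negative.")
  if (pct_va < 0 || pct_va > 100) abort("`pct_va` must lie in [0, 100].")
  structure(vals, class = "trait_config")
}

#' Simulation configuration for clonal trial series
#'
#' Desk-scale emulation of two clonally replicated progeny trial series: one
#' single-pair-mated series and one factorially mated series, planted on two
#' to three sites with a shared site, plus a set of unrelated genotyped trees
#' used as the allele-frequency reference. Defaults give ~400 progeny, 2000
#' unlinked SNPs, ~5% genotyping error, ~8% missing genotypes and a 50%
#' documented-pedigree error rate.
#'
#' @param series List of series descriptions: `name`, `n_founders`,
#'   `n_progeny`, `mating` (`"single_pair"` or `"factorial"`), `sites`.
#' @param n_markers Number of unlinked biallelic markers.
#' @param maf_bounds Founder minor-allele-frequency bounds (uniform draw).
#' @param n_qtl Markers carrying effects; `NULL` = all markers.
#' @param n_unrelated Unrelated reference genotypes.
#' @param traits Named list of [trait_config()]s.
#' @param reps_per_site,sets_per_rep,blocks_per_set Trial layout strata.
#' @param ramets_per_site Clonal copies of each progeny per site.
#' @param pedigree_error_rate Fraction of progeny whose documented parents
#'   are corrupted.
#' @param genotype_error_rate Per-call probability of a wrong genotype.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param categorical Optional named list mapping trait names to score scales
#'   (`"9pt"` or `"0to3"`); `NULL` keeps latent Gaussian values.
#' @param seed Integer seed; every stage derives its own sub-seed from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    series = list(
      list(name = "A", n_founders = 60L, n_progeny = 200L,
           mating = "single_pair", sites = c("site1", "site2")),
      list(name = "B", n_founders = 24L, n_progeny = 200L,
           mating = "factorial", sites = c("site2", "site3"))
    ),
    n_markers = 2000L, maf_bounds = c(0.1, 0.5), n_qtl = NULL,
    n_unrelated = 50L, traits = list(score = trait_config()),
    reps_per_site = 2L, sets_per_rep = 2L, blocks_per_set = 2L,
    ramets_per_site = 2L, pedigree_error_rate = 0.5,
    genotype_error_rate = 0.05, missing_rate = 0.08,
    categorical = NULL, seed = 1L) {
  for (r in c(pedigree_error_rate, genotype_error_rate, missing_rate)) {
    if (r < 0 || r > 1) abort("Rates must lie in [0, 1].")
  }
  if (maf_bounds[1] > maf_bounds[2] || maf_bounds[1] < 0 || maf_bounds[2] > 0.5) {
    abort("`maf_bounds` must satisfy 0 <= lo <= hi <= 0.5.")
  }
  for (s in series) {
    if (s$mating == "single_pair" && s$n_founders %% 2L != 0L) {
      abort(paste0("Series '", s$name, "': single_pair mating needs an even founder count."))
    }
    if (!s$mating %in% c("single_pair", "factorial")) {
      abort("`mating` must be 'single_pair' or 'factorial'.")
    }
  }
  structure(list(
    series = series, n_markers = as.integer(n_markers), maf_bounds = maf_bounds,
    n_qtl = n_qtl, n_unrelated = as.integer(n_unrelated), traits = traits,
    reps_per_site = as.integer(reps_per_site),
    sets_per_rep = as.integer(sets_per_rep),
    blocks_per_set = as.integer(blocks_per_set),
    ramets_per_site = as.integer(ramets_per_site),
    pedigree_error_rate = pedigree_error_rate,
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    categorical = categorical, seed = as.integer(seed)
  ), class = "sim_config")
}

founder_ids <- function(cfg) {
  unlist(lapply(cfg$series, function(s) {
    sprintf("%s_P%03d", s$name, seq_len(s$n_founders))
  }))
}

unrelated_ids <- function(cfg) {
  if (cfg$n_unrelated == 0L) character(0) else sprintf("U%03d", seq_len(cfg$n_unrelated))
}

#' Simulate founder and reference genotypes
#'
#' Unlinked markers with allele frequencies drawn uniformly from the MAF
#' bounds (randomly polarized so the alternate allele is not always minor);
#' genotypes are Hardy-Weinberg draws `Binomial(2, p)`, independent across
#' individuals and markers.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to a sub-seed of `cfg$seed`.
#' @return Genotype matrix for all series founders plus the unrelated
#'   reference trees, with the true frequencies in attribute `freq_true`.
#' @export
simulate_founders <- function(cfg, seed = derive_seed(cfg$seed, 1L)) {
  ids <- c(founder_ids(cfg), unrelated_ids(cfg))
  m <- cfg$n_markers
  with_seed(seed, {
    maf <- runif(m, cfg$maf_bounds[1], cfg$maf_bounds[2])
    p <- ifelse(runif(m) < 0.5, maf, 1 - maf)
    G <- matrix(rbinom(length(ids) * m, 2L, rep(p, each = length(ids))),
                nrow = length(ids), ncol = m,
                dimnames = list(ids, sprintf("M%04d", seq_len(m))))
    attr(G, "freq_true") <- setNames(p, colnames(G))
    G
  })
}

#' Simulate the true pedigree of the trial series
#'
#' Single-pair mating pairs the founders disjointly and distributes progeny
#' round-robin among the pairs; factorial mating draws each progeny's sire
#' and dam (distinct) at random from the series founders.
#'
#' @inheritParams simulate_founders
#' @return A pedigree tibble (founders first, then progeny).
#' @export
simulate_pedigree <- function(cfg, seed = derive_seed(cfg$seed, 2L)) {
  with_seed(seed, {
    rows <- lapply(cfg$series, function(s) {
      fid <- sprintf("%s_P%03d", s$name, seq_len(s$n_founders))
      pid <- sprintf("%s_C%03d", s$name, seq_len(s$n_progeny))
      if (s$mating == "single_pair") {
        pair <- matrix(fid, ncol = 2L, byrow = TRUE)
        k <- rep_len(seq_len(nrow(pair)), s$n_progeny)
        sire <- pair[k, 1L]; dam <- pair[k, 2L]
      } else {
        sire <- sample(fid, s$n_progeny, replace = TRUE)
        dam <- vapply(sire, function(x) sample(setdiff(fid, x), 1L), character(1))
      }
      dplyr::bind_rows(
        tibble::tibble(id = fid, sire = NA_character_, dam = NA_character_),
        tibble::tibble(id = pid, sire = sire, dam = unname(dam))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Each progeny receives one uniformly chosen allele from each parent at each
#' marker, independently across markers (unlinked loci). Individuals already
#' present in `founder_geno` keep their genotypes.
#'
#' @param ped Pedigree tibble (will be sorted).
#' @param founder_geno Genotype matrix covering every founder.
#' @param seed Integer seed.
#' @return Genotype matrix over all pedigree members (founders first in
#'   pedigree order), plus any extra rows of `founder_geno` (e.g. unrelated
#'   reference trees).
#' @export
gene_drop <- function(ped, founder_geno, seed = 1L) {
  ped <- sort_pedigree(ped)
  m <- ncol(founder_geno)
  extra <- setdiff(rownames(founder_geno), ped$id)
  out <- matrix(NA_integer_, nrow(ped) + length(extra), m,
                dimnames = list(c(ped$id, extra), colnames(founder_geno)))
  out[extra, ] <- founder_geno[extra, , drop = FALSE]
  with_seed(seed, {
    transmit <- function(g) (g == 2L) + (g == 1L) * rbinom(m, 1L, 0.5)
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (id %in% rownames(founder_geno)) {
        out[id, ] <- founder_geno[id, ]
      } else {
        s <- ped$sire[i]; d <- ped$dam[i]
        if (is.na(s) || is.na(d)) {
          abort(paste0("Individual '", id, "' has unknown parent(s) and no founder genotype."))
        }
        out[id, ] <- transmit(out[s, ]) + transmit(out[d, ])
      }
    }
  })
  out
}

#' Simulate clonal multi-site phenotypes with known genetic truth
#'
#' Generates, per trait: marker breeding values `W alpha` with Gaussian
#' effects at the QTL subset (scaled so their expected variance equals the
#' marker-explained additive variance), residual polygenic values sampled
#' down the pedigree with Mendelian-sampling variance `sigma2_a*/2`, a
#' clone-level non-additive effect, and site / replicate / set / block
#' effects and residuals drawn with the configured per-site variances.
#' Each progeny clone is planted as `ramets_per_site` ramets on every site of
#' its series, assigned at random to replicate, set and block. Optionally the
#' latent Gaussian is cut into 9-point or 0-3 score scales by fixed
#' quantile cut-points.
#'
#' @param ped True pedigree.
#' @param genotypes Error-free genotype matrix (from [gene_drop()]).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `phenotypes` (tibble `clone`, `site`, `rep`, `set`,
#'   `block`, `trait`, `value`) and `truth` (list with per-trait breeding
#'   values, marker effects, site effects and the configured components).
#' @export
simulate_phenotypes <- function(ped, genotypes, cfg,
                                seed = derive_seed(cfg$seed, 3L)) {
  ped <- sort_pedigree(ped)
  progeny <- lapply(cfg$series, function(s) {
    sprintf("%s_C%03d", s$name, seq_len(s$n_progeny))
  })
  names(progeny) <- vapply(cfg$series, `[[`, character(1), "name")
  sites <- unique(unlist(lapply(cfg$series, `[[`, "sites")))
  p_true <- attr(genotypes, "freq_true") %||% colMeans(genotypes) / 2

  with_seed(seed, {
    pheno_rows <- list()
    truth <- list()
    for (tn in names(cfg$traits)) {
      tc <- cfg$traits[[tn]]
      s2m <- tc$sigma2_a * tc$pct_va / 100
      s2astar <- tc$sigma2_a - s2m

      qtl <- colnames(genotypes)
      if (!is.null(cfg$n_qtl) && cfg$n_qtl < length(qtl)) {
        qtl <- sample(qtl, cfg$n_qtl)
      }
      pq <- p_true[qtl]
      denom <- 2 * sum(pq * (1 - pq))
      alpha <- if (s2m > 0) rnorm(length(qtl), 0, sqrt(s2m / denom)) else numeric(length(qtl))
      Wq <- sweep(genotypes[ped$id, qtl, drop = FALSE], 2L, 2 * pq, "-")
      bv_m <- setNames(as.numeric(Wq %*% alpha), ped$id)

      a_star <- setNames(numeric(nrow(ped)), ped$id)
      for (i in seq_len(nrow(ped))) {
        s <- ped$sire[i]; d <- ped$dam[i]
        if (is.na(s) && is.na(d)) {
          a_star[i] <- rnorm(1L, 0, sqrt(s2astar))
        } else {
          ps <- if (is.na(s)) 0 else a_star[s]
          pd <- if (is.na(d)) 0 else a_star[d]
          a_star[i] <- 0.5 * (ps + pd) + rnorm(1L, 0, sqrt(0.5 * s2astar))
        }
      }

      all_prog <- unlist(progeny)
      d_eff <- setNames(rnorm(length(all_prog), 0, sqrt(tc$sigma2_d)), all_prog)
      site_eff <- setNames(rnorm(length(sites), 0, 0.5), sites)
      per_site <- function(x) {
        v <- if (length(x) == 1L) setNames(rep(x, length(sites)), sites) else x
        v[sites]
      }
      v_r <- per_site(tc$sigma2_r); v_w <- per_site(tc$sigma2_w)
      v_b <- per_site(tc$sigma2_b); v_e <- per_site(tc$sigma2_e)

      rep_eff <- set_eff <- blk_eff <- list()
      for (st in sites) {
        for (r in seq_len(cfg$reps_per_site)) {
          rep_eff[[paste(st, r)]] <- rnorm(1L, 0, sqrt(v_r[st]))
          for (w in seq_len(cfg$sets_per_rep)) {
            set_eff[[paste(st, r, w)]] <- rnorm(1L, 0, sqrt(v_w[st]))
            for (b in seq_len(cfg$blocks_per_set)) {
              blk_eff[[paste(st, r, w, b)]] <- rnorm(1L, 0, sqrt(v_b[st]))
            }
          }
        }
      }

      for (s in cfg$series) {
        prog <- progeny[[s$name]]
        for (st in s$sites) {
          n_ram <- cfg$ramets_per_site
          cl <- rep(prog, each = n_ram)
          rp <- sample(cfg$reps_per_site, length(cl), replace = TRUE)
          se <- sample(cfg$sets_per_rep, length(cl), replace = TRUE)
          bl <- sample(cfg$blocks_per_set, length(cl), replace = TRUE)
          y <- tc$mean + site_eff[st] + bv_m[cl] + a_star[cl] + d_eff[cl] +
            unlist(rep_eff[paste(st, rp)]) +
            unlist(set_eff[paste(st, rp, se)]) +
            unlist(blk_eff[paste(st, rp, se, bl)]) +
            rnorm(length(cl), 0, sqrt(v_e[st]))
          pheno_rows[[length(pheno_rows) + 1L]] <- tibble::tibble(
            clone = cl, site = st, rep = as.character(rp),
            set = as.character(se), block = as.character(bl),
            trait = tn, value = unname(y)
          )
        }
      }
      truth[[tn]] <- list(
        breeding_values = tibble::tibble(
          id = ped$id, bv_marker = unname(bv_m), a_star = unname(a_star),
          bv_total = unname(bv_m + a_star)
        ),
        d = d_eff, marker_effects = setNames(alpha, qtl),
        site_effects = site_eff,
        components = list(sigma2_m = s2m, sigma2_a_star = s2astar,
                          sigma2_d = tc$sigma2_d, sigma2_r = v_r,
                          sigma2_w = v_w, sigma2_b = v_b, sigma2_e = v_e)
      )
    }
    pheno <- dplyr::bind_rows(pheno_rows)
    if (!is.null(cfg$categorical)) {
      for (tn in intersect(names(cfg$categorical), names(cfg$traits))) {
        idx <- pheno$trait == tn
        pheno$value[idx] <- map_to_scale(pheno$value[idx], cfg$categorical[[tn]])
      }
    }
    list(phenotypes = pheno, truth = truth)
  })
}

# Quantile mapping of a latent Gaussian to categorical score scales.
map_to_scale <- function(x, scale = c("9pt", "0to3")) {
  scale <- match.arg(scale)
  scores <- if (scale == "9pt") 1:9 else 0:3
  cuts <- stats::quantile(x, probs = seq(0, 1, length.out = length(scores) + 1L))
  cuts[1L] <- -Inf; cuts[length(cuts)] <- Inf
  scores[cut(x, breaks = unique(cuts), labels = FALSE)]
}

#' Corrupt documented parentage records
#'
#' Replaces one or both parents of a random subset of progeny with a
#' different candidate parent, emulating documentation errors. The true
#' pedigree is left untouched; the returned `corrupted` ids identify the
#' altered records.
#'
#' @param ped True pedigree tibble.
#' @param rate Fraction of progeny records to corrupt.
#' @param candidates Candidate replacement parents (default: all parents
#'   appearing in `ped`).
#' @param seed Integer seed.
#' @return A list with `pedigree` (the corrupted, "documented" pedigree) and
#'   `corrupted` (character vector of progeny ids).
#' @export
inject_pedigree_errors <- function(ped, rate, candidates = NULL, seed = 1L) {
  ped <- as_pedigree(ped)
  if (rate < 0 || rate > 1) abort("`rate` must lie in [0, 1].")
  candidates <- candidates %||% stats::na.omit(unique(c(ped$sire, ped$dam)))
  if (length(candidates) < 2L) {
    abort("Need at least two candidate parents to inject errors.")
  }
  prog_idx <- which(!is.na(ped$sire) | !is.na(ped$dam))
  n_bad <- round(rate * length(prog_idx))
  with_seed(seed, {
    bad <- prog_idx[sample.int(length(prog_idx), n_bad)]
    for (i in bad) {
      slots <- sample(c("sire", "dam"), sample(1:2, 1L))
      for (sl in slots) {
        cur <- ped[[sl]][i]
        pool <- setdiff(candidates, cur)
        ped[[sl]][i] <- sample(pool, 1L)
      }
    }
    list(pedigree = ped, corrupted = ped$id[sort(bad)])
  })
}

#' Add genotyping error and missingness to a genotype matrix
#'
#' Each call is independently replaced by one of the two other genotypes
#' with probability `error_rate`, then set missing with probability
#' `missing_rate`.
#'
#' @param G Genotype matrix (0/1/2).
#' @param error_rate Per-call error probability.
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return The corrupted genotype matrix.
#' @export
inject_genotype_noise <- function(G, error_rate, missing_rate, seed = 1L) {
  for (r in c(error_rate, missing_rate)) {
    if (r < 0 || r > 1) abort("Rates must lie in [0, 1].")
  }
  with_seed(seed, {
    out <- G
    obs <- which(!is.na(out))
    err <- obs[runif(length(obs)) < error_rate]
    if (length(err) > 0L) {
      out[err] <- (out[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
    miss <- obs[runif(length(obs)) < missing_rate]
    out[miss] <- NA_integer_
    attr(out, "freq_true") <- attr(G, "freq_true")
    out
  })
}

#' Simulate a complete trial dataset with known truth
#'
#' Orchestrates [simulate_founders()], [simulate_pedigree()], [gene_drop()],
#' [simulate_phenotypes()], [inject_genotype_noise()] and
#' [inject_pedigree_errors()] into one reproducible dataset: the study-style
#' bundle of a (partly wrong) documented pedigree, noisy genotypes with
#' missing calls, clonal multi-site phenotypes, and the full generating
#' truth.
#'
#' @param cfg A [sim_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list of class `gs_sim`: `config`, `true_pedigree`,
#'   `documented_pedigree`, `corrupted`, `genotypes` (noisy),
#'   `genotypes_clean`, `phenotypes`, `truth`, `founders`, `unrelated`,
#'   `progeny`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  founders <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg)
  geno <- gene_drop(ped, founders, seed = derive_seed(cfg$seed, 4L))
  attr(geno, "freq_true") <- attr(founders, "freq_true")
  sim <- simulate_phenotypes(ped, geno, cfg)
  noisy <- inject_genotype_noise(geno, cfg$genotype_error_rate,
                                 cfg$missing_rate,
                                 seed = derive_seed(cfg$seed, 5L))
  doc <- inject_pedigree_errors(ped, cfg$pedigree_error_rate,
                                candidates = founder_ids(cfg),
                                seed = derive_seed(cfg$seed, 6L))
  structure(list(
    config = cfg,
    true_pedigree = ped,
    documented_pedigree = doc$pedigree,
    corrupted = doc$corrupted,
    genotypes = noisy,
    genotypes_clean = geno,
    phenotypes = sim$phenotypes,
    truth = sim$truth,
    founders = founder_ids(cfg),
    unrelated = unrelated_ids(cfg),
    progeny = setdiff(ped$id, founder_ids(cfg))
  ), class = "gs_sim")
}

#' @exportS3Method base::print
print.gs_sim <- function(x, ...) {
  cat("<gs_sim> simulated clonal trial dataset\n")
  cat("  individuals:", nrow(x$true_pedigree), "(", length(x$progeny), "progeny )\n")
  cat("  markers:", ncol(x$genotypes), " traits:",
      paste(names(x$truth), collapse = ", "), "\n")
  cat("  corrupted pedigree records:", length(x$corrupted), "\n")
  invisible(x)
}
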