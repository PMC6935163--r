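#' Select a parentage-verification marker panel
#'
#' Filters markers for trio-exclusion parentage testing: call rate above a
#' floor, minor allele frequency inside a window (near 0.5 markers are the
#' most informative for exclusions), no departure from Hardy-Weinberg
#' equilibrium (exact test), and no pairwise linkage disequilibrium above an
#' r-squared ceiling (greedy prune keeping the better call rate). The
#' surviving markers are capped at `max_markers`, best call rates first.
#'
#' @param G Genotype matrix (0/1/2/`NA`), individuals x markers.
#' @param call_rate_min Minimum fraction of non-missing calls (exclusive
#'   threshold; default 0.75).
#' @param maf_range Closed MAF interval, default `c(0.35, 0.5)`.
#' @param hwe_alpha Markers with exact-test p below this are removed
#'   (default 0.05).
#' @param ld_r2_max Maximum pairwise r-squared retained (default 0.2).
#' @param max_markers Cap on panel size (default 704).
#' @param reference Individuals used for allele frequencies and the HWE test;
#'   default all genotyped individuals.
#' @return A tibble (class `marker_panel`) with columns `marker`, `call_rate`,
#'   `maf`, `hwe_p`; the per-criterion removal counts are attached as the
#'   `removed` attribute and shown by `print()`.
#' @export
select_panel <- function(G, call_rate_min = 0.75, maf_range = c(0.35, 0.5),
                         hwe_alpha = 0.05, ld_r2_max = 0.2, max_markers = 704,
                         reference = NULL) {
  G <- check_genotypes(G)
  reference <- reference %||% rownames(G)
  call_rate <- colMeans(!is.na(G))
  sub <- G[reference, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  p <- ifelse(n_obs > 0, colSums(sub, na.rm = TRUE) / (2 * pmax(n_obs, 1L)), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(sub)), function(j) {
    g <- sub[, j]
    hwe_exact_p(sum(g == 1, na.rm = TRUE),
                sum(g == 0, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, numeric(1))

  keep_cr <- call_rate > call_rate_min
  keep_maf <- !is.na(maf) & maf >= maf_range[1] & maf <= maf_range[2]
  keep_hwe <- !is.na(hwe_p) & hwe_p >= hwe_alpha
  removed <- c(call_rate = sum(!keep_cr),
               maf = sum(keep_cr & !keep_maf),
               hwe = sum(keep_cr & keep_maf & !keep_hwe))
  keep <- which(keep_cr & keep_maf & keep_hwe)

  # greedy LD prune: consider markers by decreasing call rate, keep a marker
  # only if its r^2 with every already-kept marker stays at or below the cap
  keep <- keep[order(call_rate[keep], decreasing = TRUE)]
  kept <- integer(0)
  n_ld <- 0L
  n_cap <- 0L
  if (length(keep) > 0L) {
    imputed <- impute_mean(G[, keep, drop = FALSE], reference = reference)
    for (pos in seq_along(keep)) {
      if (length(kept) >= max_markers) {
        n_cap <- n_cap + 1L
        next
      }
      if (length(kept) > 0L) {
        r <- suppressWarnings(cor(imputed[, pos], imputed[, kept, drop = FALSE]))
        r[is.na(r)] <- 0
        if (max(r^2) > ld_r2_max) {
          n_ld <- n_ld + 1L
          next
        }
      }
      kept <- c(kept, pos)
    }
  }
  removed <- c(removed, ld = n_ld, size_cap = n_cap)
  idx <- keep[kept]
  if (length(idx) == 0L) {
    abort("No markers satisfy the panel criteria; relax the thresholds.")
  }
  panel <- tibble::tibble(
    marker = colnames(G)[idx],
    call_rate = unname(call_rate[idx]),
    maf = unname(maf[idx]),
    hwe_p = unname(hwe_p[idx])
  )
  attr(panel, "removed") <- removed
  class(panel) <- c("marker_panel", class(panel))
  panel
}

#' @exportS3Method base::print
print.marker_panel <- function(x, ...) {
  cat("Parentage marker panel:", nrow(x), "markers\n")
  rem <- attr(x, "removed")
  if (!is.null(rem)) {
    cat("removed -", paste(names(rem), rem, sep = ": ", collapse = ", "), "\n")
  }
  NextMethod()
}

# Exact two-sided Hardy-Weinberg test (conditional on allele counts) for one
# biallelic marker; returns the probability of genotype configurations no
# more likely than the observed one.
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0L) return(NA_real_)
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) - lgamma(hom_common + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs + 1e-12])
}

# 3 x 3 x 3 lookup: excl[g1+1, g2+1, prog+1] is TRUE when progeny genotype
# `prog` cannot arise from one transmitted allele of each of g1 and g2.
trio_exclusion_table <- function() {
  tab <- array(TRUE, dim = c(3L, 3L, 3L))
  transmitted <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (g1 in 0:2) for (g2 in 0:2) {
    possible <- unique(outer(transmitted[[g1 + 1L]], transmitted[[g2 + 1L]], "+"))
    tab[g1 + 1L, g2 + 1L, possible + 1L] <- FALSE
  }
  tab
}
.trio_tab <- trio_exclusion_table()

#' Count Mendelian exclusions for one progeny-parent-parent trio
#'
#' A marker is informative when the progeny and both candidate parents are
#' genotyped there. At each informative marker, an exclusion is scored when
#' the progeny genotype is not among the (at most four) genotypes obtainable
#' by combining one transmitted allele from each candidate parent.
#'
#' @param progeny_g,p1_g,p2_g Equal-length genotype vectors over
#'   `{0, 1, 2, NA}`.
#' @return Named integer vector `c(exclusions = , informative = )`.
#' @export
trio_exclusions <- function(progeny_g, p1_g, p2_g) {
  if (length(p1_g) != length(progeny_g) || length(p2_g) != length(progeny_g)) {
    abort("Genotype vectors must have equal length.")
  }
  informative <- !is.na(progeny_g) & !is.na(p1_g) & !is.na(p2_g)
  excl <- .trio_tab[cbind(p1_g[informative] + 1L,
                          p2_g[informative] + 1L,
                          progeny_g[informative] + 1L)]
  c(exclusions = sum(excl), informative = sum(informative))
}

#' Assign parents to progeny by minimum trio exclusions
#'
#' For each progeny, every unordered pair of candidate parents (self-pairs
#' included, to allow selfing) is scored by [trio_exclusions()] over the
#' panel markers, and the pair with the fewest exclusions is assigned. Ties
#' favour the documented pair, then the pair with more informative markers,
#' then lexicographic order of the pair labels. A progeny whose best pair
#' still shows more than `max_exclusion_rate` exclusions per informative
#' marker is left `unassigned`.
#'
#' @param progeny Character vector of progeny ids to assign.
#' @param candidates Character vector of candidate parent ids (all genotyped).
#' @param G Genotype matrix covering progeny and candidates.
#' @param panel A `marker_panel` from [select_panel()] (or a character vector
#'   of marker ids).
#' @param documented Documented pedigree used to label assignments
#'   `confirmed` (assigned pair equals the documented pair, unordered) or
#'   `reassigned`.
#' @param max_exclusion_rate Tolerated exclusions per informative marker
#'   before declaring `unassigned`. A trio reads three genotype calls per
#'   marker, so with a per-call error rate `e` around 5% roughly
#'   `1 - (1 - e)^3 = 14%` of a true trio's markers carry at least one wrong
#'   call; the default 0.15 tolerates that while still rejecting unrelated
#'   pairs, whose exclusion rates sit far higher.
#' @return A tibble with one row per progeny: `progeny`, `documented_sire`,
#'   `documented_dam`, `parent1`, `parent2`, `exclusions`, `informative`,
#'   `status`.
#' @export
assign_parentage <- function(progeny, candidates, G, panel, documented,
                             max_exclusion_rate = 0.15) {
  G <- check_genotypes(G)
  markers <- if (is.data.frame(panel)) panel$marker else as.character(panel)
  missing_m <- setdiff(markers, colnames(G))
  if (length(missing_m) > 0L) {
    abort(paste0("Panel marker(s) not genotyped: ",
                 paste(head(missing_m, 5L), collapse = ", ")))
  }
  if (length(candidates) == 0L) abort("`candidates` must not be empty.")
  not_geno <- setdiff(c(progeny, candidates), rownames(G))
  if (length(not_geno) > 0L) {
    abort(paste0("Individual(s) not genotyped: ",
                 paste(head(not_geno, 5L), collapse = ", ")))
  }
  documented <- as_pedigree(documented)
  candidates <- sort(unique(candidates))
  P <- G[candidates, markers, drop = FALSE]

  # all unordered candidate pairs (self-pairs allowed)
  pair_idx <- which(upper.tri(diag(length(candidates)), diag = TRUE), arr.ind = TRUE)
  i1 <- pair_idx[, 1L]; i2 <- pair_idx[, 2L]
  n_pairs <- length(i1); L <- length(markers)
  # per-pair per-marker 9-state parent key, NA when either parent is missing
  key <- matrix(3L * P[i1, , drop = FALSE] + P[i2, , drop = FALSE], n_pairs, L)
  parents_ok <- !is.na(key)
  key0 <- key; key0[!parents_ok] <- 0L

  excl_tab <- .trio_tab
  out <- purrr::map_dfr(progeny, function(pr) {
    g <- G[pr, markers]
    g_ok <- !is.na(g)
    inf <- parents_ok & rep(g_ok, each = n_pairs)
    g0 <- ifelse(g_ok, g, 0L)
    flags <- matrix(
      excl_tab[cbind(as.vector(key0 %/% 3L) + 1L,
                     as.vector(key0 %% 3L) + 1L,
                     rep(g0 + 1L, each = n_pairs))],
      n_pairs, L)
    excl <- rowSums(flags & inf)
    informative <- rowSums(inf)

    doc <- documented[documented$id == pr, ]
    doc_pair <- if (nrow(doc) == 1L) sort(c(doc$sire, doc$dam)) else c(NA_character_, NA_character_)
    is_doc <- !anyNA(doc_pair) &
      candidates[i1] == doc_pair[1L] & candidates[i2] == doc_pair[2L]

    best <- min(excl)
    tied <- which(excl == best)
    if (length(tied) > 1L) {
      tied_doc <- tied[is_doc[tied]]
      if (length(tied_doc) > 0L) {
        tied <- tied_doc
      } else {
        tied <- tied[informative[tied] == max(informative[tied])]
      }
    }
    pick <- tied[1L] # pairs are generated in lexicographic candidate order
    rate_ok <- informative[pick] > 0L && best / informative[pick] <= max_exclusion_rate
    pair <- sort(c(candidates[i1[pick]], candidates[i2[pick]]))
    status <- if (!rate_ok) {
      "unassigned"
    } else if (!anyNA(doc_pair) && identical(pair, doc_pair)) {
      "confirmed"
    } else {
      "reassigned"
    }
    tibble::tibble(
      progeny = pr,
      documented_sire = doc_pair[1L], documented_dam = doc_pair[2L],
      parent1 = pair[1L], parent2 = pair[2L],
      exclusions = as.integer(best), informative = as.integer(informative[pick]),
      status = status
    )
  })
  class(out) <- c("trio_assignment", class(out))
  out
}

#' Correct a documented pedigree from trio assignments
#'
#' Substitutes the assigned parent pair for the documented pair of every
#' assigned progeny; unassigned progeny keep their documented parents (and
#' are flagged in the log). Parents introduced by reassignment are added as
#' founder records.
#'
#' @param documented Documented pedigree tibble.
#' @param assignments Output of [assign_parentage()].
#' @return A list with `pedigree` (corrected tibble) and `summary`, a one-row
#'   tibble with `n_progeny`, `pct_confirmed`, `pct_parents_reassigned`,
#'   `n_parents_before`, `n_parents_after`, `n_unassigned`.
#' @export
correct_pedigree <- function(documented, assignments) {
  documented <- as_pedigree(documented)
  unknown <- setdiff(assignments$progeny, documented$id)
  if (length(unknown) > 0L) {
    abort(paste0("Assignment(s) for progeny absent from the pedigree: ",
                 paste(head(unknown, 5L), collapse = ", ")))
  }
  ped <- documented
  assigned <- assignments[assignments$status != "unassigned", , drop = FALSE]
  if (nrow(assignments) > nrow(assigned)) {
    pipeline_log("parentage", nrow(assignments) - nrow(assigned),
                 " progeny unassigned; documented parents kept.")
  }
  idx <- match(assigned$progeny, ped$id)
  # keep the documented sire/dam orientation when the unordered pair matches
  keep_order <- !is.na(ped$sire[idx]) & !is.na(ped$dam[idx]) &
    ped$sire[idx] == assigned$parent2 & ped$dam[idx] == assigned$parent1
  ped$sire[idx] <- ifelse(keep_order, assigned$parent2, assigned$parent1)
  ped$dam[idx] <- ifelse(keep_order, assigned$parent1, assigned$parent2)
  new_parents <- setdiff(stats::na.omit(unique(c(ped$sire, ped$dam))), ped$id)
  if (length(new_parents) > 0L) {
    ped <- dplyr::bind_rows(
      tibble::tibble(id = new_parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }

  doc_pairs <- cbind(assignments$documented_sire, assignments$documented_dam)
  new_pairs <- cbind(assignments$parent1, assignments$parent2)
  slots_changed <- vapply(seq_len(nrow(assignments)), function(i) {
    if (assignments$status[i] == "unassigned") return(0L)
    d <- sort(doc_pairs[i, ]); a <- sort(new_pairs[i, ])
    2L - sum(!is.na(match(d, a))) # unordered slot overlap
  }, integer(1))

  parents_of <- function(p) stats::na.omit(unique(c(p$sire, p$dam)))
  summary <- tibble::tibble(
    n_progeny = nrow(assignments),
    pct_confirmed = 100 * mean(assignments$status == "confirmed"),
    pct_parents_reassigned = 100 * sum(slots_changed) / (2 * nrow(assignments)),
    n_parents_before = length(parents_of(documented)),
    n_parents_after = length(parents_of(ped)),
    n_unassigned = sum(assignments$status == "unassigned")
  )
  list(pedigree = sort_pedigree(ped), summary = summary)
}

#' Write a trio-assignment report TSV
#'
#' @param assignments Tibble from [assign_parentage()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  readr::write_tsv(assignments, path)
  invisible(path)
}
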