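#' Coerce a data frame to a pedigree table
#'
#' A pedigree is a tibble with character columns `id`, `sire` and `dam`.
#' Unknown parents are `NA` internally; on disk they are written as `0`
#' (empty fields are also accepted on read). Individuals that appear only as
#' parents are appended as founder records, with a warning, so that a file
#' listing only progeny rows is still a complete pedigree.
#'
#' @param x A data frame with columns `id`, `sire`, `dam` (character or
#'   coercible). `0`, `""` and `NA` all denote an unknown parent.
#' @return A tibble with columns `id`, `sire`, `dam`.
#' @export
as_pedigree <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame with columns id, sire, dam.")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x))) {
    abort(paste0("Pedigree is missing column(s): ",
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  ped <- tibble::tibble(
    id   = as.character(x$id),
    sire = normalize_parent(x$sire),
    dam  = normalize_parent(x$dam)
  )
  if (anyNA(ped$id) || any(ped$id == "")) abort("Pedigree ids must be non-missing.")
  dup <- unique(ped$id[duplicated(ped$id)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate pedigree id(s): ", paste(head(dup, 5L), collapse = ", ")))
  }
  parents <- setdiff(stats::na.omit(unique(c(ped$sire, ped$dam))), ped$id)
  if (length(parents) > 0L) {
    warn(paste0(length(parents),
                " individual(s) appear only as parents; added as founders."))
    ped <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }
  ped
}

normalize_parent <- function(p) {
  p <- as.character(p)
  p[!is.na(p) & (p == "0" | p == "")] <- NA_character_
  p
}

#' Sort a pedigree so parents precede their offspring
#'
#' Topological (generation) ordering by Kahn's algorithm. The set of
#' `(id, sire, dam)` records is unchanged; only row order may differ. An
#' already-ordered pedigree is returned in the same order.
#'
#' @param ped A pedigree table (see [as_pedigree()]).
#' @return The reordered pedigree tibble.
#' @export
sort_pedigree <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n) # children lists by parent index
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (j in kids[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(order) < n) {
    on_cycle <- ped$id[setdiff(seq_len(n), order)][1L]
    abort(paste0("Pedigree contains a cycle involving individual '", on_cycle, "'."))
  }
  # keep the original order when it is already topological
  if (is_parent_ordered(ped)) return(ped)
  ped[order, , drop = FALSE]
}

is_parent_ordered <- function(ped) {
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  all(is.na(si) | si < pos) && all(is.na(di) | di < pos)
}

#' Numerator relationship matrix from a sorted pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: `a_ii = 1 + a(s,d)/2` (0 when either parent is unknown) and
#' `a_ij = (a(j,s) + a(j,d))/2` for earlier individuals `j`. An unknown
#' parent contributes as an unrelated, non-inbred founder.
#'
#' @param ped A pedigree in parent-before-offspring order (see
#'   [sort_pedigree()]).
#' @return A dense symmetric matrix with `ped$id` dimnames. Diagonal entries
#'   are `1 + F` with `F` the inbreeding coefficient.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  if (!is_parent_ordered(ped)) {
    abort("Pedigree is not parent-ordered; call sort_pedigree() first.")
  }
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  A
}

#' Inbreeding coefficients from a relationship matrix
#'
#' @param A Numerator relationship matrix from [build_A()].
#' @return Named vector `F = diag(A) - 1`.
#' @export
inbreeding <- function(A) {
  diag(A) - 1
}

#' Status-number effective population size of a group
#'
#' `Ns = 0.5 / theta`, where `theta` is the group coancestry: the mean of
#' pairwise coancestries `f_ij = a_ij / 2` over all ordered pairs of group
#' members, self-pairs included. A group of n unrelated non-inbred
#' individuals has `Ns = n`.
#'
#' @param ped A pedigree table.
#' @param group Character vector of ids; defaults to every individual.
#' @return Scalar status number.
#' @export
status_number <- function(ped, group = NULL) {
  ped <- sort_pedigree(ped)
  group <- group %||% ped$id
  if (length(group) == 0L) abort("`group` must contain at least one id.")
  missing_ids <- setdiff(group, ped$id)
  if (length(missing_ids) > 0L) {
    abort(paste0("Group id(s) not in pedigree: ",
                 paste(head(missing_ids, 5L), collapse = ", ")))
  }
  A <- build_A(ped)
  theta <- mean(A[group, group, drop = FALSE]) / 2
  0.5 / theta
}

#' Read / write pedigree CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header `id,sire,dam`; `0` or an
#' empty field denotes an unknown parent.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a pedigree tibble.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped Pedigree tibble to write.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  readr::write_csv(out, path)
  invisible(path)
}
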