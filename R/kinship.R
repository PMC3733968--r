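#' Numerator relationship matrix from a pedigree
#'
#' Builds the expected additive (numerator) relationship matrix **A** with
#' the Henderson tabular method: processing animals so that parents precede
#' offspring,
#' \deqn{a_{ii} = 1 + \tfrac{1}{2} a_{sd}, \qquad
#'       a_{ij} = \tfrac{1}{2}(a_{js} + a_{jd}),\; j < i,}
#' where \eqn{s,d} are the sire and dam of animal \eqn{i} and terms
#' involving an unknown parent are zero.  Diagonals equal one plus the
#' inbreeding coefficient; founders with both parents unknown have diagonal
#' exactly 1.  The input is topologically sorted on load, so pre-sorted
#' records are not required.
#'
#' @param pedigree A data frame with columns `id`, `sire`, `dam`.  Parent
#'   columns use `NA` or `0` for an unknown parent; ids may be integers or
#'   character labels.
#' @return A dense symmetric numeric matrix in the *input* id order, with
#'   ids as dimnames.
#' @export
#' @examples
#' ped <- tibble::tibble(id = c("s", "d", "o1", "o2"),
#'                       sire = c(NA, NA, "s", "s"),
#'                       dam  = c(NA, NA, "d", "d"))
#' A <- kinship_matrix(ped)
#' A["o1", "o2"]  # full sibs: 0.5
kinship_matrix <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  ord <- pedigree_toposort(ped)
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)[ord]
  dam <- match(ped$dam, ped$id)[ord]
  # re-express parent pointers in sorted positions
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  sire <- ifelse(is.na(sire), NA_integer_, pos[sire])
  dam <- ifelse(is.na(dam), NA_integer_, pos[dam])

  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  ids_sorted <- ped$id[ord]
  dimnames(A) <- list(ids_sorted, ids_sorted)
  # return in the caller's original id order
  A[as.character(ped$id), as.character(ped$id), drop = FALSE]
}

# Validate ids/parents and coerce unknown-parent codes ("0", "", NA) to NA.
normalize_pedigree <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) {
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  clean <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", "NA") | is.na(p)] <- NA_character_
    p
  }
  sire <- clean(pedigree$sire)
  dam <- clean(pedigree$dam)
  missing_par <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(missing_par)) {
    stop("parent id(s) absent from the pedigree: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE)) {
    stop("an animal is recorded as its own parent", call. = FALSE)
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# Kahn topological sort (parents before offspring); errors on cycles,
# naming the animals involved.
pedigree_toposort <- function(ped) {
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), ord)], collapse = ", "),
         call. = FALSE)
  }
  ord
}

#' Per-animal inbreeding coefficients
#'
#' Convenience wrapper: `diag(kinship_matrix(ped)) - 1`.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `id` and `inbreeding`.
#' @export
inbreeding_coefficients <- function(pedigree) {
  A <- kinship_matrix(pedigree)
  tibble::tibble(id = rownames(A), inbreeding = diag(A) - 1)
}
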