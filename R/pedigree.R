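# Pedigree utilities: topological ordering and the numerator (additive)
# relationship matrix by the tabular method.

# Order animals parents-before-offspring; error on cycles naming them.
topo_sort_pedigree <- function(ped) {
  ids <- ped$animal
  if (anyDuplicated(ids)) abort("duplicate animal ids in pedigree")
  sire <- ifelse(ped$sire %in% ids, ped$sire, "0")
  dam <- ifelse(ped$dam %in% ids, ped$dam, "0")
  placed <- setNames(rep(FALSE, length(ids)), ids)
  order_out <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining) > 0) {
    ready <- remaining[
      (sire[remaining] == "0" | placed[sire[remaining]]) &
        (dam[remaining] == "0" | placed[dam[remaining]])]
    if (length(ready) == 0) {
      abort(sprintf("pedigree contains a cycle involving: %s",
                    paste(head(ids[remaining], 10), collapse = ", ")),
            class = "hapblup_structure_error")
    }
    order_out <- c(order_out, ids[ready])
    placed[ids[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  order_out
}

# Restrict a pedigree to `animals` and their ancestors up to `depth`
# generations back; parents beyond the cut become unknown.
prune_pedigree <- function(ped, animals, depth = Inf) {
  keep <- unique(animals)
  frontier <- keep
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    rows <- ped[ped$animal %in% frontier, , drop = FALSE]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c("0", keep))
    parents <- parents[parents %in% ped$animal]
    keep <- c(keep, parents)
    frontier <- parents
    d <- d + 1
  }
  out <- ped[ped$animal %in% keep, , drop = FALSE]
  out$sire <- ifelse(out$sire %in% keep, out$sire, "0")
  out$dam <- ifelse(out$dam %in% keep, out$dam, "0")
  out
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular-method additive (numerator) relationship matrix:
#' `A_ij = 0.5 * (A_i,sire(j) + A_i,dam(j))` filled in
#' parents-before-offspring order, and `A_ii = 1 + F_i` with the inbreeding
#' coefficient `F_i = 0.5 * A_sire(i),dam(i)`. Unknown parents (coded `"0"`)
#' contribute nothing. The result is symmetric positive semidefinite.
#'
#' @param ped Pedigree tibble with columns `animal`, `sire`, `dam` (`"0"` =
#'   unknown). Parents referenced but absent from `animal` are treated as
#'   unknown.
#' @return Symmetric matrix with animal ids as dimnames, in topological
#'   order.
#' @export
build_additive_relationship <- function(ped) {
  ped <- as_tibble(ped)
  ord <- topo_sort_pedigree(ped)
  n <- length(ord)
  pos <- setNames(seq_len(n), ord)
  ped_ord <- ped[match(ord, ped$animal), ]
  si <- ifelse(ped_ord$sire %in% ord, pos[ped_ord$sire], NA_integer_)
  di <- ifelse(ped_ord$dam %in% ord, pos[ped_ord$dam], NA_integer_)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else rep(0, i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else rep(0, i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}
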