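#' Read a pedigree table
#'
#' Reads a three-column TSV (individual, sire, dam) with header. Unknown
#' parents may be coded as `0`, `NA` or the empty string.
#'
#' @param path file path.
#' @return A `data.frame` with character columns `individual`, `sire`, `dam`
#'   (unknown parent = `NA`).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(ped) < 3) stop("pedigree file needs columns individual, sire, dam")
  names(ped)[1:3] <- c("individual", "sire", "dam")
  for (col in c("sire", "dam")) {
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA_character_
  }
  ped[, 1:3]
}

# Topological order of a pedigree: parents before offspring. Errors on cycles.
pedigree_order <- function(individual, sire, dam) {
  n <- length(individual)
  idx <- stats::setNames(seq_len(n), individual)
  parent_idx <- cbind(
    ifelse(is.na(sire), NA_integer_, idx[sire]),
    ifelse(is.na(dam), NA_integer_, idx[dam])
  )
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- !placed & apply(parent_idx, 1, function(p) {
      all(is.na(p) | placed[p])
    })
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle or an individual that is its own ancestor")
  }
  order_out
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: individuals are processed parents-first, with
#' `A[i,i] = 1 + 0.5 * A[sire, dam]` and
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])`, unknown parents contributing 0
#' (treated as unrelated, non-inbred founders).
#'
#' @param ped data.frame with columns `individual`, `sire`, `dam` (as from
#'   [read_pedigree()]); parents that appear only as sire/dam are added as
#'   founders.
#' @return Symmetric positive semi-definite matrix with dimnames set to the
#'   individual identifiers, in the input order of `ped` (founders that were
#'   added implicitly come first).
#' @export
build_numerator_relationship <- function(ped) {
  stopifnot(all(c("individual", "sire", "dam") %in% names(ped)))
  ids <- as.character(ped$individual)
  if (anyDuplicated(ids)) stop("duplicated individual in pedigree")
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ids)
  if (length(parents)) {
    ped <- rbind(
      data.frame(individual = parents, sire = NA_character_,
                 dam = NA_character_),
      ped[, c("individual", "sire", "dam")]
    )
    ids <- as.character(ped$individual)
  }
  ord <- pedigree_order(ids, as.character(ped$sire), as.character(ped$dam))
  idx <- stats::setNames(seq_along(ids), ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    si <- if (is.na(s)) NA_integer_ else idx[[s]]
    di <- if (is.na(d)) NA_integer_ else idx[[d]]
    rel_s <- if (is.na(si)) numeric(n) else A[, si]
    rel_d <- if (is.na(di)) numeric(n) else A[, di]
    row_i <- 0.5 * (rel_s + rel_d)
    A[i, ] <- row_i
    A[, i] <- row_i
    A[i, i] <- 1 + if (is.na(si) || is.na(di)) 0 else 0.5 * A[si, di]
  }
  A
}
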