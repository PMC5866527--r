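#' Phenotype table container
#'
#' Holds an individuals-by-traits matrix of trait values together with
#' positive per-record error weights (the diagonal of the inverse error
#' covariance scale, used for weighted heteroscedastic analyses; default 1).
#'
#' @param y numeric matrix or data.frame, `n` individuals x `t` traits.
#' @param weights matrix of positive error weights, same shape as `y`
#'   (recycled from a vector or a scalar).
#' @param individual_ids row identifiers.
#' @param trait_names column names.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(y, weights = 1, individual_ids = NULL,
                            trait_names = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  t <- ncol(y)
  if (is.null(trait_names)) {
    trait_names <- colnames(y)
    if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(t))
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(y)
    if (is.null(individual_ids)) individual_ids <- paste0("id", seq_len(n))
  }
  w <- matrix(weights, n, t)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  dimnames(y) <- list(individual_ids, trait_names)
  dimnames(w) <- dimnames(y)
  structure(
    list(y = y, weights = w, individual_ids = as.character(individual_ids),
         trait_names = as.character(trait_names)),
    class = "phenotype_table"
  )
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d individuals x %d traits (%s)\n",
              nrow(x$y), ncol(x$y), paste(x$trait_names, collapse = ", ")))
  invisible(x)
}

#' Read a phenotype table from TSV
#'
#' Expects a header row with an `id` column, one column per trait and,
#' optionally, one weight column per trait named `<trait>_weight`.
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!"id" %in% names(tab)) stop("phenotype file needs an 'id' column")
  wcols <- grep("_weight$", names(tab), value = TRUE)
  tcols <- setdiff(names(tab), c("id", wcols))
  y <- as.matrix(tab[, tcols, drop = FALSE])
  w <- matrix(1, nrow(y), ncol(y))
  for (j in seq_along(tcols)) {
    wc <- paste0(tcols[j], "_weight")
    if (wc %in% wcols) w[, j] <- tab[[wc]]
  }
  phenotype_table(y, weights = w, individual_ids = tab$id,
                  trait_names = tcols)
}

#' Write a phenotype table to TSV
#'
#' @param Y a [phenotype_table()].
#' @param path output file path.
#' @param write_weights include `<trait>_weight` columns when any weight
#'   differs from 1.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(Y, path, write_weights = NULL) {
  stopifnot(inherits(Y, "phenotype_table"))
  if (is.null(write_weights)) write_weights <- any(Y$weights != 1)
  out <- data.frame(id = Y$individual_ids, check.names = FALSE)
  for (j in seq_along(Y$trait_names)) out[[Y$trait_names[j]]] <- Y$y[, j]
  if (write_weights) {
    for (j in seq_along(Y$trait_names)) {
      out[[paste0(Y$trait_names[j], "_weight")]] <- Y$weights[, j]
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
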