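#' Build a pairwise LD (r-squared) reference
#'
#' Constructs the symmetric lookup of pairwise r-squared values used by LD
#' pruning and proxy search. Pairs absent from the input are treated as
#' r-squared 0; the diagonal is always 1.
#'
#' @param pairs A data frame in long format with columns `id_a`, `id_b`, `r2`,
#'   or a square numeric matrix with variant ids as dimnames.
#' @param variant_ids Optional character vector of additional variant ids to
#'   include (isolated variants with no listed pairs).
#' @return An object of class `ld_reference`.
#' @examples
#' ld <- ld_reference(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.5))
#' ld_r2(ld, "rs1", "rs2")
#' @export
ld_reference <- function(pairs, variant_ids = NULL) {
  if (is.matrix(pairs)) {
    m <- pairs
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop_domain("Square LD matrix must carry variant ids as dimnames.")
    }
    if (!identical(rownames(m), colnames(m))) {
      stop_domain("Square LD matrix rownames and colnames must agree.")
    }
    if (any(m < 0 | m > 1, na.rm = TRUE)) {
      stop_domain("r2 values must lie in [0, 1].")
    }
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
      stop_domain("LD matrix must be symmetric.")
    }
    ids <- union(rownames(m), variant_ids %||% character())
    full <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    full[rownames(m), colnames(m)] <- m
    diag(full) <- 1
    return(structure(list(ids = ids, r2 = full), class = "ld_reference"))
  }
  check_assoc_table(pairs, "pairs", c("id_a", "id_b", "r2"))
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    stop_domain("r2 values must lie in [0, 1].")
  }
  ids <- unique(c(pairs$id_a, pairs$id_b, variant_ids))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(pairs$id_a, pairs$id_b)] <- pairs$r2
  m[cbind(pairs$id_b, pairs$id_a)] <- pairs$r2
  diag(m) <- 1
  structure(list(ids = ids, r2 = m), class = "ld_reference")
}

#' Read an LD reference from TSV
#'
#' Accepts either long format (columns `id_a`, `id_b`, `r2`) or a square
#' matrix with an id header column.
#'
#' @param path TSV file path.
#' @return An `ld_reference` object.
#' @export
read_ld_reference <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("id_a", "id_b", "r2") %in% names(x))) {
    return(ld_reference(as.data.frame(x)))
  }
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_reference(m)
}

#' Look up pairwise r-squared values
#'
#' Vectorized over `a` and `b`. Variants absent from the reference contribute
#' r-squared 0 against everything (1 with themselves) unless `strict = TRUE`.
#'
#' @param ld An `ld_reference`.
#' @param a,b Character vectors of variant ids (recycled).
#' @param strict Error on ids absent from the reference.
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b, strict = FALSE) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  ia <- match(a, ld$ids)
  ib <- match(b, ld$ids)
  if (strict && (anyNA(ia) || anyNA(ib))) {
    abort(sprintf("Variant(s) absent from LD reference: %s",
                  paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", ")),
          class = "cardiomr_error_unknown_variant")
  }
  out <- ifelse(a == b, 1, 0)
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- ld$r2[cbind(ia[ok], ib[ok])]
  out
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variant(s), %d nonzero off-diagonal pair(s)\n",
              length(x$ids), (sum(x$r2 > 0) - length(x$ids)) / 2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
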