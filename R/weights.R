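#' Queen (or rook) contiguity weights on a regular grid
#'
#' Cells are neighbors if their squares share an edge (rook) or an edge or a
#' corner (queen). The binary relation is symmetric; the returned weight
#' matrix is row-standardized so every row sums to 1 (all grid cells have at
#' least 3 neighbors on a 2x2-or-larger lattice).
#'
#' @param grid An `fs_grid` with at least 2 cells.
#' @param type `"queen"` (default) or `"rook"`.
#' @return An object of class `fs_weights`: list with `W` (row-standardized
#'   sparse `dgCMatrix`), `B` (binary symmetric neighbor matrix), `d` (neighbor
#'   counts), `n`, `type`, `nrows`, `ncols`.
#' @examples
#' w <- build_queen_weights(generate_grid(3, 3))
#' Matrix::rowSums(w$W)   # all 1
#' w$d[5]                 # center cell has 8 neighbors
#' @export
build_queen_weights <- function(grid, type = c("queen", "rook")) {
  stopifnot(is_fs_grid(grid))
  type <- match.arg(type)
  n <- n_cells(grid)
  if (n < 2L) stop("contiguity weights need at least 2 cells", call. = FALSE)
  offs <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  if (type == "queen") {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  row <- grid$cells$row
  col <- grid$cells$col
  ii <- integer(0); jj <- integer(0)
  for (o in offs) {
    r2 <- row + o[1L]; c2 <- col + o[2L]
    ok <- r2 >= 0L & r2 < grid$nrows & c2 >= 0L & c2 < grid$ncols
    ii <- c(ii, grid$cells$cell_id[ok])
    jj <- c(jj, cell_id_at(grid, r2[ok], c2[ok]))
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  d <- Matrix::rowSums(B)
  W <- Matrix::Diagonal(x = 1 / d) %*% B
  structure(
    list(W = methods::as(W, "CsparseMatrix"), B = B, d = d, n = n, type = type,
         nrows = grid$nrows, ncols = grid$ncols),
    class = "fs_weights"
  )
}

#' @export
print.fs_weights <- function(x, ...) {
  cat(sprintf("<fs_weights> %s contiguity, %d cells, row-standardized\n",
              x$type, x$n))
  invisible(x)
}

# Session cache: eigenvalues depend only on lattice shape and contiguity type,
# so parameter-recovery loops over many simulated cities pay for them once.
.fs_cache <- new.env(parent = emptyenv())

#' Eigenvalues of a row-standardized contiguity matrix
#'
#' `W = D^-1 B` with `B` symmetric is similar to the symmetric matrix
#' `D^-1/2 B D^-1/2`, so its spectrum is real and computed by a symmetric
#' dense eigendecomposition. Used for the SEM log-determinant
#' `log|I - lambda W| = sum(log(1 - lambda * ev))`.
#'
#' @param w An `fs_weights`.
#' @return Numeric vector of `w$n` real eigenvalues (descending).
#' @export
weights_eigenvalues <- function(w) {
  stopifnot(inherits(w, "fs_weights"))
  key <- sprintf("ev_%d_%d_%s", w$nrows, w$ncols, w$type)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  s <- 1 / sqrt(w$d)
  M <- Matrix::Diagonal(x = s) %*% w$B %*% Matrix::Diagonal(x = s)
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  .fs_cache[[key]] <- ev
  ev
}
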