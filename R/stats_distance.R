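#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis index of compositional dissimilarity,
#' \eqn{d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)}, over the rows of an
#' abundance table. Rows may be read counts, relative read abundances, or any
#' nonnegative composition (e.g. vegetation-structure proportions); values lie
#' in \[0, 1\] and the matrix is symmetric with a zero diagonal.
#'
#' @param x numeric matrix or data.frame; rows are samples, columns taxa or
#'   classes. Row names label the output.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' bray_curtis(rbind(a = c(2, 1, 0), b = c(1, 1, 1)))["a", "b"] # 1/3
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundance table must be finite and nonnegative")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero row(s): ", paste(bad, collapse = ", "))
  }
  man <- as.matrix(stats::dist(x, method = "manhattan"))
  d <- man / outer(rs, rs, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# Validate a square symmetric hollow dissimilarity matrix; returns the matrix.
as_dist_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
  D
}

# Strictly-lower-triangle vector of a square matrix.
lower_vec <- function(D) D[lower.tri(D)]
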