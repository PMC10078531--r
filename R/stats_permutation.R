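# Permutation machinery: blocked perMANOVA with sequential (Type-I) sums of
# squares on the Gower-centered matrix, pairwise contrasts with Holm
# adjustment, and the Mantel test. All permutation p-values use the plus-one
# rule p = (#{stat_perm >= stat_obs} + 1) / (n_perm + 1), so p is never 0.

# Hat (projection) matrix of the column space of X, tolerant to rank
# deficiency (dummy coding of nested/aliased factors).
hat_matrix <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  tcrossprod(Q)
}

# Permutation of 1..n, optionally restricted within strata levels.
strata_perm <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  p <- seq_len(n)
  for (lv in unique(strata)) {
    idx <- which(strata == lv)
    p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

#' Permutational multivariate analysis of variance (perMANOVA)
#'
#' Partitions a dissimilarity matrix by a grouping factor, optionally after a
#' blocking factor, and assesses the group pseudo-F by permutation. The
#' partition is sequential (Type I) on the Gower-centered matrix
#' \eqn{G = -\tfrac12 C D^{(2)} C}: the block term (if any) is fitted first,
#' then the grouping factor; pseudo-F for the group term is
#' \eqn{(SS_g/df_g)/(SS_{res}/df_{res})} and \eqn{R^2 = SS_g/SS_{tot}}.
#'
#' Blocking is honoured twice, matching the standard treatment of a known
#' nuisance stratification (e.g. sampling year): the block enters the model
#' as the first sequential term, and label permutations are restricted within
#' block strata. Either half can be switched off.
#'
#' @param D dissimilarity matrix (square symmetric, zero diagonal) or `dist`.
#' @param group factor-like main predictor, one entry per row of `D`.
#' @param block optional factor-like blocking variable (e.g. year).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param strata if `TRUE` (default) permutations are restricted within
#'   `block` levels.
#' @param block_term if `TRUE` (default) the block is also fitted as the
#'   first model term.
#' @return object of class `"permanova"`: a list with a `terms` data.frame
#'   (term, df, SS, pseudo_F, R2, p_perm), residual and total rows, `n_perm`,
#'   and `seed`.
#' @export
permanova <- function(D, group, block = NULL, n_perm = 9999, seed = 1L,
                      strata = TRUE, block_term = TRUE) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  group <- factor(group)
  if (length(group) != n) stop("length(group) must match nrow(D)")
  if (nlevels(group) < 2L) stop("group needs at least 2 levels")
  if (any(table(group) < 2L)) stop("every group level needs >= 2 members")
  has_block <- !is.null(block)
  if (has_block) {
    block <- factor(block)
    if (length(block) != n) stop("length(block) must match nrow(D)")
    if (nlevels(block) < 2L) { has_block <- FALSE; block <- NULL }
  }

  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (D^2) %*% C
  ss_total <- sum(diag(G))

  H0 <- matrix(1 / n, n, n)
  use_block_term <- has_block && block_term
  H1 <- if (use_block_term) hat_matrix(stats::model.matrix(~block)) else H0
  H2 <- hat_matrix(if (use_block_term) stats::model.matrix(~ block + group)
                   else stats::model.matrix(~group))
  Mb <- H1 - H0
  Mf <- H2 - H1
  Mr <- diag(n) - H2

  df_block <- if (use_block_term) nlevels(block) - 1L else 0L
  df_group <- nlevels(group) - 1L
  df_res <- n - 1L - df_block - df_group

  ss_block <- sum(Mb * G)
  ss_group <- sum(Mf * G)
  ss_res <- sum(Mr * G)
  f_obs <- (ss_group / df_group) / (ss_res / df_res)

  perm_strata <- if (has_block && strata) block else NULL
  f_perm <- with_seed(op_seed(seed, "permanova"), {
    vapply(seq_len(n_perm), function(i) {
      p <- strata_perm(n, perm_strata)
      Gp <- G[p, p]
      (sum(Mf * Gp) / df_group) / (sum(Mr * Gp) / df_res)
    }, numeric(1L))
  })
  p_val <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)

  terms <- data.frame(
    term = c(if (use_block_term) "block", "group"),
    df = c(if (use_block_term) df_block, df_group),
    SS = c(if (use_block_term) ss_block, ss_group),
    pseudo_F = c(if (use_block_term) NA_real_, f_obs),
    R2 = c(if (use_block_term) ss_block / ss_total, ss_group / ss_total),
    p_perm = c(if (use_block_term) NA_real_, p_val),
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms,
                 residual = list(df = df_res, SS = ss_res,
                                 R2 = ss_res / ss_total),
                 total = list(df = n - 1L, SS = ss_total),
                 n = n, n_perm = n_perm, seed = seed,
                 blocks = if (has_block) levels(block) else NULL),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("perMANOVA (", x$n_perm, " permutations",
      if (!is.null(x$blocks)) paste0(", blocked by ", length(x$blocks), " strata"),
      ")\n", sep = "")
  tab <- x$terms
  tab$SS <- round(tab$SS, 4); tab$R2 <- round(tab$R2, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: df = %d, SS = %.4f, R2 = %.4f\n",
              x$residual$df, x$residual$SS, x$residual$R2))
  invisible(x)
}

#' Pairwise perMANOVA contrasts with Holm adjustment
#'
#' Runs one perMANOVA per unordered pair of `group` levels on the
#' corresponding submatrix of `D` and Holm-adjusts the permutation p-values
#' over the whole family of pairs. Pairs where either side has fewer than two
#' samples are skipped with a warning. A block with fewer than two levels
#' inside a pair's subset is dropped for that pair.
#'
#' @inheritParams permanova
#' @param n_perm permutations per contrast. The default keeps the study-wide
#'   9999: with m contrasts the smallest achievable Holm-adjusted p is
#'   m/(n_perm + 1), so a large family needs this resolution to reject at all.
#' @return data.frame with one row per tested pair: `level_a`, `level_b`,
#'   `pseudo_F`, `R2`, `p_perm`, `p_holm`.
#' @export
pairwise_permanova <- function(D, group, block = NULL, n_perm = 9999,
                               seed = 1L, strata = TRUE, block_term = TRUE) {
  D <- as_dist_matrix(D)
  group <- factor(group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2L)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    idx <- which(group %in% c(a, b))
    ga <- droplevels(group[idx])
    if (any(table(ga) < 2L)) {
      warning("skipping pair ", a, " vs ", b, ": fewer than 2 samples per side")
      next
    }
    bl <- if (!is.null(block)) droplevels(factor(block)[idx]) else NULL
    if (!is.null(bl) && nlevels(bl) < 2L) bl <- NULL
    fit <- permanova(D[idx, idx], ga, block = bl, n_perm = n_perm,
                     seed = op_seed(seed, paste("pair", a, b)),
                     strata = strata, block_term = block_term)
    g <- fit$terms[fit$terms$term == "group", ]
    rows[[j]] <- data.frame(level_a = a, level_b = b, df = g$df,
                            pseudo_F = g$pseudo_F, R2 = g$R2,
                            p_perm = g$p_perm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no testable pairs")
  out$p_holm <- holm_adjust(out$p_perm)
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' `adj_(i) = max_(j<=i) min(1, (m - j + 1) * p_(j))` over the ascending
#' order statistics, returned in the input order. Dominates plain Bonferroni.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-sided (greater) permutation test that jointly permutes rows and
#' columns of the second matrix.
#'
#' @param D1,D2 square symmetric matrices with matching dimensions/labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return object of class `"mantel"`: list with `r`, `p_perm`, `n_perm`,
#'   `seed`.
#' @export
mantel <- function(D1, D2, n_perm = 9999, seed = 1L) {
  D1 <- as_dist_matrix(D1); D2 <- as_dist_matrix(D2)
  if (nrow(D1) != nrow(D2)) stop("matrices must have matching dimensions")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("matrix labels must match in order")
  v1 <- lower_vec(D1)
  if (stats::sd(v1) == 0 || stats::sd(lower_vec(D2)) == 0)
    stop("Mantel r undefined: zero variance in a distance triangle")
  r_obs <- stats::cor(v1, lower_vec(D2))
  n <- nrow(D1)
  r_perm <- with_seed(op_seed(seed, "mantel"), {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(v1, lower_vec(D2[p, p]))
    }, numeric(1L))
  })
  p_val <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p_perm = p_val, n_perm = n_perm, seed = seed),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, one-sided)\n",
              x$r, x$p_perm, x$n_perm))
  invisible(x)
}
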