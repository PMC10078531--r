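# Model-based statistics: NMDS ordination, OLS with coefficient tests, AICc
# model ranking with Akaike weights, Welch's t, and the PCA condition index.

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Visualization-grade NMDS: starts from a classical-scaling (Torgerson)
#' configuration and alternates monotone (isotonic) regression of the
#' configuration distances on the dissimilarities with a Guttman-transform
#' configuration update. The reported stress sequence is nonincreasing (the
#' best configuration so far is kept).
#'
#' @param D dissimilarity matrix.
#' @param k embedding dimension (default 2); must be < n.
#' @param max_iter maximum iterations (default 200).
#' @param seed seed for the jitter used when the classical start is rank
#'   deficient.
#' @param tol relative stress-improvement tolerance for convergence.
#' @return list with `points` (n x k configuration), `stress` (final
#'   stress-1), `stress_trace`, `iterations`, `converged`.
#' @export
nmds <- function(D, k = 2L, max_iter = 200L, seed = 1L, tol = 1e-7) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of points")
  lt <- lower.tri(D)
  delta <- D[lt]
  ord <- order(delta)

  X <- suppressWarnings(stats::cmdscale(D, k = k))
  if (ncol(X) < k) { # degenerate start: pad with tiny jitter
    X <- cbind(X, with_seed(op_seed(seed, "nmds"),
                            matrix(stats::rnorm(n * (k - ncol(X)), sd = 1e-6),
                                   n)))
  }

  stress1 <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))
  d <- as.matrix(stats::dist(X))[lt]
  fit <- stats::isoreg(d[ord])
  dhat <- numeric(length(d)); dhat[ord] <- fit$yf
  s_best <- stress1(d, dhat)
  X_best <- X
  trace <- s_best
  converged <- FALSE
  it <- 0L
  Dhat <- matrix(0, n, n)
  while (it < max_iter) {
    it <- it + 1L
    # Guttman transform towards the monotone targets
    Dhat[lt] <- dhat; Dhat <- Dhat + t(Dhat)
    Dfull <- as.matrix(stats::dist(X))
    ratio <- ifelse(Dfull > 0, Dhat / Dfull, 0)
    B <- -ratio
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    d <- as.matrix(stats::dist(X))[lt]
    fit <- stats::isoreg(d[ord])
    dhat[ord] <- fit$yf
    s <- stress1(d, dhat)
    if (s < s_best) {
      if (s_best - s < tol * s_best) { s_best <- s; X_best <- X; trace <- c(trace, s); converged <- TRUE; break }
      s_best <- s; X_best <- X
      trace <- c(trace, s)
    } else { converged <- TRUE; break }
  }
  colnames(X_best) <- paste0("NMDS", seq_len(k))
  rownames(X_best) <- rownames(D)
  list(points = X_best, stress = s_best, stress_trace = trace,
       iterations = it, converged = converged)
}

#' Ordinary least squares with coefficient t-tests
#'
#' @param y numeric response.
#' @param X predictor matrix or data.frame (an intercept is added; factors in
#'   a data.frame are dummy-coded).
#' @return object of class `"diet_ols"`: coefficient table (`estimate`, `se`,
#'   `t`, `p`), `r_squared`, `adj_r_squared`, `rss`, `n`, `n_coef`, fitted
#'   values and residuals.
#' @export
ols_fit <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xd <- if (is.data.frame(X)) X else as.data.frame(X)
    Xm <- stats::model.matrix(~., data = Xd)
  }
  if (nrow(Xm) != n) stop("nrow(X) must equal length(y)")
  p <- ncol(Xm)
  if (n <= p) stop("need n > number of coefficients")
  qrX <- qr(Xm)
  if (qrX$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qrX, y)
  fitted <- drop(Xm %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  coef_tab <- data.frame(estimate = beta, se = se, t = tval, p = pval)
  rownames(coef_tab) <- colnames(Xm)
  structure(list(coefficients = coef_tab, r_squared = r2,
                 adj_r_squared = adj_r2, rss = rss, n = n, n_coef = p,
                 df_residual = df_res, fitted = fitted, residuals = res),
            class = "diet_ols")
}

#' @export
print.diet_ols <- function(x, ...) {
  cat("OLS fit (n =", x$n, ")\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Rank competing OLS models by AICc with Akaike weights
#'
#' AIC is computed as \eqn{n \log(RSS/n) + 2k} with \eqn{k} counting the
#' regression coefficients plus the residual-variance parameter, and
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}. Weights are
#' \eqn{w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)}.
#'
#' @param models named list of `"diet_ols"` fits to the same response.
#' @return data.frame of class `"model_rank"`, sorted by AICc: `model`, `k`,
#'   `AICc`, `delta_AICc`, `weight`, `adj_r_squared`.
#' @export
aicc_rank <- function(models) {
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  n <- unique(vapply(models, function(m) m$n, numeric(1L)))
  if (length(n) != 1L) stop("all models must be fit to the same n")
  k <- vapply(models, function(m) m$n_coef + 1L, numeric(1L)) # + sigma^2
  if (any(n - k - 1 <= 0)) stop("n - k - 1 must be positive for AICc")
  rss <- vapply(models, function(m) m$rss, numeric(1L))
  aic <- n * log(rss / n) + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = names(models), k = k, AICc = aicc,
                    delta_AICc = delta, weight = w,
                    adj_r_squared = vapply(models, function(m) m$adj_r_squared,
                                           numeric(1L)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  class(out) <- c("model_rank", "data.frame")
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
welch_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (v1 == 0 && v2 == 0) stop("both group variances are zero")
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p, mean1 = mean(x1), mean2 = mean(x2))
}

#' PCA-based nutritional condition index
#'
#' Columns (morphometric and adiposity measurements) are z-scored and the
#' first principal component is used as a relative condition score. The sign
#' of PC1 is arbitrary, so the component is oriented so that the loading of
#' an anchor variable (by default the rump-fat measurement, the most direct
#' adiposity signal) is positive: higher score = better condition.
#'
#' @param measurements numeric matrix or data.frame, rows = individuals.
#' @param anchor column name whose loading is forced positive; defaults to
#'   the first column whose name contains "rump", else the first column.
#' @return list with `scores` (named per individual), `loadings`,
#'   `var_explained` (fraction of total variance on PC1), `dropped`
#'   (constant columns removed).
#' @export
condition_index <- function(measurements, anchor = NULL) {
  m <- as.matrix(as.data.frame(measurements))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 individuals and >= 2 variables")
  if (any(!is.finite(m))) stop("measurements must be complete and finite")
  sds <- apply(m, 2L, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 informative variables remain")
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  if (is.null(anchor)) {
    hit <- grep("rump", colnames(m), ignore.case = TRUE)
    anchor <- if (length(hit)) colnames(m)[hit[1L]] else colnames(m)[1L]
  }
  if (!anchor %in% colnames(m)) stop("anchor variable not found: ", anchor)
  if (loadings[anchor] < 0) { scores <- -scores; loadings <- -loadings }
  names(scores) <- rownames(m)
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev[1L]^2 / sum(pc$sdev^2), dropped = dropped)
}
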