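# Individual-level diet summarization: bootstrap-standardized diets,
# richness/diversity, exact species-accumulation, digestible-protein diet
# quality, and the single-sample comparison.

#' Bootstrap-standardized diet of one individual
#'
#' Controls for unequal sampling effort across individuals: each of `B`
#' iterations draws `k` of the individual's samples (without replacement by
#' default) and records the iteration's mean RRA vector, taxon count, and
#' Shannon index. The standardized diet is the across-iteration mean RRA,
#' renormalized to sum to 1.
#'
#' @param rra matrix of the individual's sample profiles (samples x taxa,
#'   rows summing to 1), or a `"diet_profiles"` object restricted to one
#'   individual.
#' @param k samples drawn per iteration (default 6).
#' @param B iterations (default 1000).
#' @param seed integer seed.
#' @param replace draw with replacement (default `FALSE`; sensitivity switch).
#' @param individual_id label carried through to results.
#' @return object of class `"standardized_diet"`: `mean_rra` (named, sums to
#'   1), `richness_draws`, `shannon_draws` (length `B`), `n_samples`, `k`,
#'   `B`, `seed`, `individual_id`.
#' @export
standardize_diet <- function(rra, k = 6L, B = 1000L, seed = 1L,
                             replace = FALSE, individual_id = NA_character_) {
  if (inherits(rra, "diet_profiles")) rra <- rra$rra
  rra <- as.matrix(rra)
  n <- nrow(rra)
  if (!replace && n < k)
    stop("individual ", individual_id, " has ", n, " samples (< k = ", k, ")")
  acc <- numeric(ncol(rra))
  rich <- integer(B)
  shan <- numeric(B)
  with_seed(op_seed(seed, paste0("standardize_diet_", individual_id)), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, k, replace = replace)
      m <- colMeans(rra[idx, , drop = FALSE])
      acc <- acc + m
      pos <- m > 0
      rich[b] <- sum(pos)
      p <- m[pos]
      shan[b] <- -sum(p * log(p))
    }
  })
  mean_rra <- acc / B
  mean_rra <- mean_rra / sum(mean_rra)
  names(mean_rra) <- colnames(rra)
  structure(list(individual_id = individual_id, mean_rra = mean_rra,
                 richness_draws = rich, shannon_draws = shan,
                 n_samples = n, k = k, B = B, seed = seed),
            class = "standardized_diet")
}

#' @export
print.standardized_diet <- function(x, ...) {
  cat(sprintf("standardized_diet[%s]: k=%d of %d samples, B=%d, richness %.1f +/- %.2f\n",
              x$individual_id, x$k, x$n_samples, x$B,
              mean(x$richness_draws), stats::sd(x$richness_draws)))
  invisible(x)
}

#' Standardize diets for all individuals in a profile set
#'
#' Individuals with fewer than `k` samples are excluded with a message.
#'
#' @param profiles a `"diet_profiles"` object whose sample metadata carries
#'   `individual_id`.
#' @inheritParams standardize_diet
#' @param exclude_samples character vector of sample_ids to drop before
#'   standardization (e.g. capture samples of relocating animals).
#' @return named list of `"standardized_diet"` objects.
#' @export
standardize_all <- function(profiles, k = 6L, B = 1000L, seed = 1L,
                            replace = FALSE, exclude_samples = character()) {
  stopifnot(inherits(profiles, "diet_profiles"))
  meta <- profiles$samples
  if (is.null(meta) || !"individual_id" %in% names(meta))
    stop("profiles need individual_id metadata")
  keep <- !(meta$sample_id %in% exclude_samples)
  rra <- profiles$rra[keep, , drop = FALSE]
  ind <- meta$individual_id[keep]
  out <- list()
  for (id in unique(ind)) {
    sub <- rra[ind == id, , drop = FALSE]
    if (nrow(sub) < k && !replace) {
      message("excluding ", id, ": ", nrow(sub), " samples < k = ", k)
      next
    }
    out[[id]] <- standardize_diet(sub, k = k, B = B,
                                  seed = op_seed(seed, paste0("ind_", id)),
                                  replace = replace, individual_id = id)
  }
  out
}

#' Mean and SD of bootstrap dietary richness
#'
#' @param sd a `"standardized_diet"`.
#' @return named numeric `c(mean, sd)` over the `B` richness draws.
#' @export
dietary_richness <- function(sd) {
  stopifnot(inherits(sd, "standardized_diet"))
  c(mean = mean(sd$richness_draws), sd = stats::sd(sd$richness_draws))
}

#' Population-level bootstrap dietary richness
#'
#' Per iteration, draws `k` samples from every individual and counts the
#' union of taxa across all individuals' iteration diets.
#'
#' @param profiles_by_individual named list of per-individual RRA matrices
#'   (or occurrence matrices), each samples x taxa over a common taxon set.
#' @inheritParams standardize_diet
#' @return list with `mean`, `sd`, and the per-iteration `draws`.
#' @export
population_richness <- function(profiles_by_individual, k = 6L, B = 1000L,
                                seed = 1L) {
  mats <- lapply(profiles_by_individual, as.matrix)
  mats <- mats[vapply(mats, nrow, 1L) >= k]
  if (!length(mats)) stop("no individual passes the >= k sample filter")
  nt <- unique(vapply(mats, ncol, 1L))
  if (length(nt) != 1L) stop("individuals must share one taxon set")
  draws <- integer(B)
  with_seed(op_seed(seed, "population_richness"), {
    for (b in seq_len(B)) {
      present <- logical(nt)
      for (m in mats) {
        idx <- sample.int(nrow(m), k)
        present <- present | colSums(m[idx, , drop = FALSE]) > 0
      }
      draws[b] <- sum(present)
    }
  })
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
}

#' Mean Shannon diversity of a standardized diet
#'
#' \eqn{H = -\sum p \log p} of each iteration's mean RRA, averaged over
#' iterations (natural log).
#'
#' @param sd a `"standardized_diet"`.
#' @return scalar mean Shannon index.
#' @export
shannon_diversity <- function(sd) {
  stopifnot(inherits(sd, "standardized_diet"))
  mean(sd$shannon_draws)
}

#' Exact species-accumulation curve
#'
#' Analytic expectation of cumulative richness when `j` of an individual's
#' `N` samples are drawn without replacement:
#' \eqn{E[S_j] = \sum_i (1 - \binom{N - f_i}{j} / \binom{N}{j})}, where
#' \eqn{f_i} is the number of samples containing taxon i. Deterministic,
#' no permutation averaging.
#'
#' @param occurrence 0/1 matrix, samples x taxa, for one individual.
#' @return data.frame with columns `n_samples` and `expected_richness`;
#'   nondecreasing and concave in `n_samples`.
#' @export
species_accumulation <- function(occurrence) {
  occ <- as.matrix(occurrence) > 0
  N <- nrow(occ)
  if (N < 2L) stop("need >= 2 samples")
  f <- colSums(occ)
  f <- f[f > 0]
  ks <- seq_len(N)
  ES <- vapply(ks, function(j)
    sum(1 - exp(lchoose(N - f, j) - lchoose(N, j))), numeric(1L))
  data.frame(n_samples = ks, expected_richness = ES)
}

#' Digestible-protein diet quality
#'
#' RRA-weighted mean digestible protein (DP, % dry mass) of a standardized
#' diet. Taxa without DP data are excluded and the weights renormalized;
#' `coverage` reports the diet fraction with DP data. The occurrence-weighted
#' variant weights every covered taxon equally.
#'
#' @param sd a `"standardized_diet"`.
#' @param traits data.frame with columns `motu_id` and `dp`.
#' @param weighting `"rra"` (default) or `"occurrence"`.
#' @return list with `individual_id`, `dp_weighted`, `coverage`, `weighting`.
#' @export
diet_quality_dp <- function(sd, traits, weighting = c("rra", "occurrence")) {
  stopifnot(inherits(sd, "standardized_diet"))
  weighting <- match.arg(weighting)
  if (!all(c("motu_id", "dp") %in% names(traits)))
    stop("traits needs motu_id and dp columns")
  rra <- sd$mean_rra
  dp <- stats::setNames(traits$dp, traits$motu_id)[names(rra)]
  covered <- !is.na(dp) & rra > 0
  coverage <- sum(rra[covered])
  if (coverage == 0)
    stop("no DP data covers the diet of individual ", sd$individual_id)
  dp_weighted <- if (weighting == "rra") {
    sum(rra[covered] * dp[covered]) / sum(rra[covered])
  } else {
    mean(dp[covered])
  }
  list(individual_id = sd$individual_id, dp_weighted = dp_weighted,
       coverage = coverage, weighting = weighting)
}

#' Expected richness of a single randomly drawn sample
#'
#' Mean occurrence richness over `B` uniform draws of one sample; the
#' single-sample counterpart to [standardize_diet()] used to quantify how
#' much longitudinal sampling adds.
#'
#' @param occurrence 0/1 matrix, samples x taxa, for one individual.
#' @param B random trials (default 1000).
#' @param seed integer seed.
#' @return scalar mean richness.
#' @export
single_sample_richness <- function(occurrence, B = 1000L, seed = 1L) {
  occ <- as.matrix(occurrence) > 0
  n <- nrow(occ)
  rich <- rowSums(occ)
  with_seed(op_seed(seed, "single_sample_richness"), {
    mean(rich[sample.int(n, B, replace = TRUE)])
  })
}
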