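# Post-bioinformatic processing of metabarcoding read tables. The pipeline
# order is fixed to: PCR-replicate averaging -> within-sample <1% filter ->
# rarefaction to a common depth -> RRA/occurrence profiles. The filter is
# computed on replicate-averaged counts, within sample.

#' Construct a read-count table with PCR-replicate substructure
#'
#' @param counts nonnegative integer matrix; one row per (sample, replicate),
#'   columns are mOTU identifiers.
#' @param sample_id,pcr_rep vectors, one entry per row of `counts`.
#' @param samples data.frame of per-sample metadata keyed by `sample_id`
#'   (typically `individual_id`, `collection_date`, `habitat_at_collection`).
#' @return object of class `"read_count_table"`.
#' @export
read_count_table <- function(counts, sample_id, pcr_rep, samples = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("read counts must be finite and nonnegative")
  if (length(sample_id) != nrow(counts) || length(pcr_rep) != nrow(counts))
    stop("sample_id and pcr_rep must match nrow(counts)")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("motu", seq_len(ncol(counts)))
  sample_id <- as.character(sample_id)
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
    if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
    if ("individual_id" %in% names(samples)) {
      # each physical sample belongs to exactly one individual
      stopifnot(!anyDuplicated(samples$sample_id))
    }
    missing <- setdiff(unique(sample_id), samples$sample_id)
    if (length(missing)) stop("samples metadata missing: ",
                              paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(counts = counts, sample_id = sample_id,
                 pcr_rep = as.character(pcr_rep), samples = samples,
                 averaged = FALSE),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat("read_count_table:", length(unique(x$sample_id)), "samples,",
      nrow(x$counts), "rows (replicates),", ncol(x$counts), "mOTUs",
      if (x$averaged) "[replicate-averaged]", "\n")
  invisible(x)
}

# Deterministic half-up rounding (round() in R is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

#' Average read counts across PCR replicates
#'
#' Collapses a read-count table to one row per physical sample, each cell
#' the arithmetic mean of that sample's retained replicate counts. By default
#' means are rounded half-up to integers so that downstream rarefaction (a
#' hypergeometric draw) has integer counts to work on.
#'
#' @param table a `"read_count_table"`.
#' @param round round means half-up to integers (default `TRUE`).
#' @return a `"read_count_table"` with one row per sample and `pcr_rep = "mean"`.
#' @export
average_pcr_replicates <- function(table, round = TRUE) {
  stopifnot(inherits(table, "read_count_table"))
  if (table$averaged) return(table)
  ids <- unique(table$sample_id)
  out <- matrix(0, length(ids), ncol(table$counts),
                dimnames = list(ids, colnames(table$counts)))
  for (s in ids) {
    rows <- which(table$sample_id == s)
    out[s, ] <- colMeans(table$counts[rows, , drop = FALSE])
  }
  if (round) out <- round_half_up(out)
  res <- read_count_table(out, ids, rep("mean", length(ids)), table$samples)
  res$averaged <- TRUE
  res
}

#' Remove taxa below a within-sample read-fraction threshold
#'
#' Zeroes, per sample, every mOTU whose share of that sample's reads is
#' strictly below `threshold` (default 1%). Taxa at exactly the threshold
#' are kept. Intended to run on replicate-averaged counts, before
#' rarefaction.
#'
#' @param table a `"read_count_table"` (or bare count matrix).
#' @param threshold fraction in `[0, 1)`; default 0.01.
#' @return object of the same type with sub-threshold cells set to 0.
#' @export
filter_rare_motus <- function(table, threshold = 0.01) {
  if (!(is.numeric(threshold) && threshold >= 0 && threshold < 1))
    stop("threshold must lie in [0, 1)")
  mat <- if (inherits(table, "read_count_table")) table$counts else as.matrix(table)
  tot <- rowSums(mat)
  frac <- mat / ifelse(tot > 0, tot, 1)
  mat[frac < threshold] <- 0
  if (inherits(table, "read_count_table")) { table$counts <- mat; table }
  else mat
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric draw)
#' so the returned counts sum to exactly `depth`.
#'
#' @param counts nonnegative integer vector.
#' @param depth target read depth (default 7000).
#' @param seed integer seed.
#' @return integer vector summing to `depth`; errors if the total is below
#'   `depth` (table-level rarefaction drops such samples instead).
#' @export
rarefy_sample <- function(counts, depth = 7000L, seed = 1L) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  total <- sum(counts)
  if (total < depth) stop("sample total ", total, " is below depth ", depth)
  if (total == depth) return(counts)
  with_seed(op_seed(seed, "rarefy_sample"), {
    pool <- rep.int(seq_along(counts), counts)
    keep <- pool[sample.int(total, depth)]
    out <- tabulate(keep, nbins = length(counts))
    names(out) <- names(counts)
    out
  })
}

#' Rarefy every sample of a read-count table
#'
#' Samples whose total read count falls below `depth` are dropped with a
#' warning (no upsampling with replacement).
#'
#' @inheritParams rarefy_sample
#' @param table replicate-averaged `"read_count_table"`.
#' @return a `"read_count_table"` whose rows all sum to `depth`.
#' @export
rarefy_table <- function(table, depth = 7000L, seed = 1L) {
  stopifnot(inherits(table, "read_count_table"), table$averaged)
  tot <- rowSums(table$counts)
  drop <- tot < depth
  if (any(drop))
    warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(table$counts)[drop], 5L), collapse = ", "))
  keep <- which(!drop)
  if (!length(keep)) stop("no samples reach depth ", depth)
  mat <- table$counts[keep, , drop = FALSE]
  for (i in seq_len(nrow(mat)))
    mat[i, ] <- rarefy_sample(mat[i, ], depth,
                              seed = op_seed(seed, paste0("rarefy_row_", rownames(mat)[i])))
  res <- table
  res$counts <- mat
  res$sample_id <- table$sample_id[keep]
  res$pcr_rep <- table$pcr_rep[keep]
  res
}

#' Convert a rarefied table to RRA and occurrence profiles
#'
#' @param table rarefied, replicate-averaged `"read_count_table"`.
#' @return object of class `"diet_profiles"`: list with `rra` (samples x
#'   taxa, rows sum to 1), `occurrence` (0/1), `depth` per sample, and the
#'   sample metadata.
#' @export
to_profiles <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  mat <- table$counts
  tot <- rowSums(mat)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) dropped")
    mat <- mat[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  rra <- mat / tot
  occ <- (rra > 0) * 1L
  samples <- table$samples
  if (!is.null(samples))
    samples <- samples[match(rownames(mat), samples$sample_id), , drop = FALSE]
  structure(list(rra = rra, occurrence = occ, depth = tot, samples = samples),
            class = "diet_profiles")
}

#' Full read-table processing pipeline
#'
#' Replicate averaging, within-sample rare-taxon filter, rarefaction, and
#' profile conversion, in that order by default. `order = "rarefy_first"`
#' swaps the filter and rarefaction steps (sensitivity switch).
#'
#' @param table a `"read_count_table"` with replicate rows.
#' @param threshold within-sample RRA filter (default 0.01).
#' @param depth rarefaction depth (default 7000).
#' @param seed integer seed.
#' @param order `"filter_first"` (default) or `"rarefy_first"`.
#' @return a `"diet_profiles"` object.
#' @export
process_read_table <- function(table, threshold = 0.01, depth = 7000L,
                               seed = 1L, order = c("filter_first", "rarefy_first")) {
  order <- match.arg(order)
  avg <- average_pcr_replicates(table)
  if (order == "filter_first") {
    out <- rarefy_table(filter_rare_motus(avg, threshold), depth, seed)
  } else {
    out <- filter_rare_motus(rarefy_table(avg, depth, seed), threshold)
    # re-rarefy is not applied after filtering in this order; totals may be
    # below depth by the filtered mass, so renormalization happens in
    # to_profiles via the per-sample total.
  }
  to_profiles(out)
}
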