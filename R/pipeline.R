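# Pipeline orchestration: compose the diet, space-use and statistics modules
# into the full analysis battery (population and per-habitat perMANOVA with
# pairwise contrasts, distance/structure Mantel tests, condition regressions
# with AICc ranking, the single-vs-longitudinal comparison, accumulation
# curves, NMDS), from either an in-memory synthetic world or CSV inputs.

#' Default analysis configuration
#'
#' Parameter defaults are the standard analysis settings: rarefaction depth
#' 7000, within-sample RRA filter 1%, k = 6 samples per bootstrap iteration,
#' B = 1000 iterations, 9999 permutations, 21-day movement window, 95% MCP,
#' and LiDAR height-class boundaries at 0.3 m and 1.6 m.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(depth = 7000L, rra_threshold = 0.01, k = 6L, B = 1000L,
       n_perm = 9999L, pairwise_n_perm = 9999L, window_days = 21,
       mcp_level = 0.95, ground_tol = 0.05, height_breaks = c(0.3, 1.6),
       seed = 1L, exclude_samples = character(), nmds_dim = 2L)
}

#' Validate (and complete) an analysis configuration
#'
#' Unknown keys are rejected; parameters must be positive and in documented
#' ranges. Missing keys take defaults.
#'
#' @param config partial named list (possibly read from YAML).
#' @return completed configuration list.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  stopifnot(cfg$depth > 0, cfg$rra_threshold >= 0, cfg$rra_threshold < 1,
            cfg$k >= 1, cfg$B >= 1, cfg$n_perm >= 1, cfg$window_days > 0,
            cfg$mcp_level > 0, cfg$mcp_level <= 1, cfg$ground_tol >= 0,
            length(cfg$height_breaks) == 2L, diff(cfg$height_breaks) > 0,
            cfg$nmds_dim >= 1)
  cfg
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with a subset of [default_config()] keys.
#' @return validated configuration list.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

# ---- input loading -------------------------------------------------------

load_world_dir <- function(dir) {
  fp <- function(f) file.path(dir, f)
  reads <- data.table::fread(fp("reads.csv"))
  wide <- data.table::dcast(reads, sample_id + pcr_rep ~ motu_id,
                            value.var = "count", fill = 0L)
  counts <- as.matrix(wide[, -(1:2)])
  animals <- as.data.frame(data.table::fread(fp("animals.csv")))
  samples <- if (file.exists(fp("samples.csv"))) {
    as.data.frame(data.table::fread(fp("samples.csv")))
  } else {
    sid <- unique(wide$sample_id)
    data.frame(sample_id = sid, individual_id = sub("_s[0-9]+$", "", sid),
               stringsAsFactors = FALSE)
  }
  if (!"year" %in% names(samples) && "year" %in% names(animals))
    samples$year <- animals$year[match(samples$individual_id, animals$individual_id)]
  rt <- read_count_table(counts, wide$sample_id, wide$pcr_rep, samples)
  gps <- as.data.frame(data.table::fread(fp("gps.csv")))
  tracks <- split(gps, gps$individual_id)
  lidar <- as.data.frame(data.table::fread(fp("lidar.csv")))
  traits <- as.data.frame(data.table::fread(fp("traits.csv")))
  names(traits)[names(traits) == "taxon_id"] <- "motu_id"
  names(traits)[names(traits) == "dp_percent"] <- "dp"
  poly <- if (file.exists(fp("floodplain.csv")))
    as.matrix(data.table::fread(fp("floodplain.csv"))) else NULL
  list(read_table = rt, tracks = tracks, lidar = lidar, traits = traits,
       animals = animals, floodplain = poly)
}

world_inputs <- function(world) {
  animals <- as.data.frame(world$individuals)
  animals$year <- world$truth$year[animals$individual_id]
  lid <- do.call(rbind, world$lidar)
  traits <- world$landscape$taxa[, c("taxon_id", "dp")]
  names(traits)[1L] <- "motu_id"
  list(read_table = world$read_table, tracks = world$tracks,
       lidar = lid, traits = traits, animals = animals,
       floodplain = floodplain_polygon(world$landscape))
}

# Run `expr`; on error return NULL annotated with the message (used for
# strata that are too small, e.g. an empty floodplain).
section_or_na <- function(expr) {
  tryCatch(expr, error = function(e) structure(list(), not_applicable = TRUE,
                                               reason = conditionMessage(e)))
}

is_na_section <- function(x) isTRUE(attr(x, "not_applicable"))

# ---- the pipeline --------------------------------------------------------

#' Run the full individual-diet-variation analysis
#'
#' Executes read-table processing, diet standardization, space-use
#' covariates, and the statistical battery, and returns a result bundle.
#' Inputs come either from an in-memory synthetic `world` or from a
#' directory of CSVs as written by [write_world()].
#'
#' @param world a `"world"` object (takes precedence), or `NULL`.
#' @param data_dir directory with `reads.csv`, `gps.csv`, `lidar.csv`,
#'   `traits.csv`, `animals.csv` (and optionally `samples.csv`,
#'   `floodplain.csv` with the habitat polygon vertices).
#' @param config partial configuration list (see [default_config()]).
#' @return object of class `"dietscape_bundle"`.
#' @export
run_pipeline <- function(world = NULL, data_dir = NULL, config = list()) {
  cfg <- validate_config(config)
  inp <- if (!is.null(world)) world_inputs(world)
         else if (!is.null(data_dir)) load_world_dir(data_dir)
         else stop("supply a world or a data_dir")
  seed <- cfg$seed

  ## -- diet branch --------------------------------------------------------
  profiles <- process_read_table(inp$read_table, threshold = cfg$rra_threshold,
                                 depth = cfg$depth, seed = seed)
  sds <- standardize_all(profiles, k = cfg$k, B = cfg$B, seed = seed,
                         exclude_samples = cfg$exclude_samples)
  if (!length(sds)) stop("diet stage: no individual passes the >= k filter")
  ids <- names(sds)

  meta <- profiles$samples
  keep_samp <- meta$individual_id %in% ids &
    !(meta$sample_id %in% cfg$exclude_samples)
  rra <- profiles$rra[keep_samp, , drop = FALSE]
  occ <- profiles$occurrence[keep_samp, , drop = FALSE]
  meta <- meta[keep_samp, , drop = FALSE]

  richness <- t(vapply(sds, dietary_richness, numeric(2L)))
  per_ind_rra <- lapply(ids, function(id)
    rra[meta$individual_id == id, , drop = FALSE])
  names(per_ind_rra) <- ids
  pop_rich <- population_richness(per_ind_rra, k = cfg$k, B = cfg$B, seed = seed)
  single <- vapply(ids, function(id)
    single_sample_richness(occ[meta$individual_id == id, , drop = FALSE],
                           B = cfg$B, seed = op_seed(seed, paste0("single_", id))),
    numeric(1L))
  accumulation <- lapply(ids, function(id)
    species_accumulation(occ[meta$individual_id == id, , drop = FALSE]))
  names(accumulation) <- ids
  quality <- vapply(ids, function(id)
    diet_quality_dp(sds[[id]], inp$traits)$dp_weighted, numeric(1L))
  shannon <- vapply(sds, shannon_diversity, numeric(1L))

  ## -- space-use branch ---------------------------------------------------
  ranges <- list(); iu <- numeric(); habitat <- character()
  fp_frac <- numeric(); struct <- NULL
  for (id in ids) {
    tr <- inp$tracks[[id]]
    if (is.null(tr)) stop("space stage: no track for ", id)
    ranges[[id]] <- home_range(tr, id, level = cfg$mcp_level)
    iu[id] <- intensity_of_use(tr, cfg$window_days)
    if (!is.null(inp$floodplain)) {
      aff <- habitat_affiliation(ranges[[id]], inp$floodplain, tr)
      habitat[id] <- aff$habitat
      fp_frac[id] <- aff$time_fraction
    } else {
      habitat[id] <- "unknown"; fp_frac[id] <- NA_real_
    }
    inside <- points_in_polygon(cbind(inp$lidar$x, inp$lidar$y),
                                ranges[[id]]$mcp95$polygon)
    prof <- if (any(inside))
      structure_profile(inp$lidar$height[inside], cfg$ground_tol,
                        cfg$height_breaks)
    else rep(NA_real_, 4L)
    struct <- rbind(struct, prof)
  }
  rownames(struct) <- ids
  cent_dist <- centroid_distances(ranges)
  struct_ok <- stats::complete.cases(struct)
  struct_dis <- if (sum(struct_ok) >= 2L)
    structure_dissimilarity(struct[struct_ok, , drop = FALSE]) else NULL

  ## -- condition ----------------------------------------------------------
  animals <- inp$animals
  condition <- stats::setNames(animals$condition, animals$individual_id)[ids]
  repro <- stats::setNames(as.character(animals$reproductive_class),
                           animals$individual_id)[ids]

  ## -- statistics ---------------------------------------------------------
  bc_samples <- bray_curtis(rra)
  year <- if ("year" %in% names(meta)) factor(meta$year) else NULL
  if (!is.null(year) && nlevels(year) < 2L) year <- NULL
  perm_pop <- permanova(bc_samples, meta$individual_id, block = year,
                        n_perm = cfg$n_perm, seed = seed)
  perm_hab <- list()
  for (hb in c("woodland", "floodplain")) {
    sub <- meta$individual_id %in% ids[habitat == hb]
    perm_hab[[hb]] <- section_or_na({
      yy <- if (!is.null(year)) droplevels(year[sub]) else NULL
      if (!is.null(yy) && nlevels(yy) < 2L) yy <- NULL
      permanova(bc_samples[sub, sub], meta$individual_id[sub], block = yy,
                n_perm = cfg$n_perm, seed = op_seed(seed, paste0("perm_", hb)))
    })
  }
  pairwise <- pairwise_permanova(bc_samples, meta$individual_id, block = year,
                                 n_perm = cfg$pairwise_n_perm, seed = seed)

  sd_rra <- t(vapply(sds, function(s) s$mean_rra,
                     numeric(length(sds[[1L]]$mean_rra))))
  rownames(sd_rra) <- ids
  bc_diet <- bray_curtis(sd_rra)

  scales <- list(population = ids,
                 woodland = ids[habitat == "woodland"],
                 floodplain = ids[habitat == "floodplain"])
  mantel_dist <- list(); mantel_struct <- list()
  ols_iu <- list(); ols_dp <- list(); ols_rich <- list()
  for (sc in names(scales)) {
    ss <- scales[[sc]]
    mantel_dist[[sc]] <- section_or_na(
      mantel(bc_diet[ss, ss], cent_dist[ss, ss], n_perm = cfg$n_perm,
             seed = op_seed(seed, paste0("mantel_d_", sc))))
    mantel_struct[[sc]] <- section_or_na({
      if (is.null(struct_dis)) stop("no structure matrix")
      s2 <- intersect(ss, rownames(struct_dis))
      mantel(bc_diet[s2, s2], struct_dis[s2, s2], n_perm = cfg$n_perm,
             seed = op_seed(seed, paste0("mantel_s_", sc)))
    })
    ols_iu[[sc]] <- section_or_na(
      ols_fit(iu[ss], data.frame(condition = condition[ss])))
    ols_dp[[sc]] <- section_or_na(
      ols_fit(quality[ss], data.frame(condition = condition[ss])))
    ols_rich[[sc]] <- section_or_na(
      ols_fit(richness[ss, "mean"], data.frame(condition = condition[ss])))
  }

  model_rank <- section_or_na({
    preds <- data.frame(condition = condition,
                        habitat = factor(habitat),
                        lactation = factor(repro))
    y <- richness[, "mean"]
    spec7 <- list(
      "Nutritional condition" = "condition",
      "Nutritional condition + habitat" = c("condition", "habitat"),
      "Nutritional condition + lactation" = c("condition", "lactation"),
      "Nutritional condition + habitat + lactation" =
        c("condition", "habitat", "lactation"),
      "Habitat" = "habitat",
      "Lactation" = "lactation",
      "Habitat + lactation" = c("habitat", "lactation"))
    fits <- lapply(spec7, function(v) ols_fit(y, preds[, v, drop = FALSE]))
    aicc_rank(fits)
  })

  welch_single <- section_or_na(welch_t(single, richness[, "mean"]))
  ord <- section_or_na(nmds(bc_samples, k = cfg$nmds_dim,
                            seed = op_seed(seed, "nmds")))

  structure(list(
    config = cfg, individuals = ids,
    profiles = profiles,
    standardized = sds,
    richness = data.frame(individual_id = ids, mean = richness[, "mean"],
                          sd = richness[, "sd"], single_sample = single,
                          shannon = shannon, dp_weighted = quality,
                          condition = condition, habitat = habitat,
                          reproductive_class = repro, iu = iu,
                          floodplain_fraction = fp_frac,
                          row.names = NULL, stringsAsFactors = FALSE),
    population_richness = pop_rich[c("mean", "sd")],
    accumulation = accumulation,
    ranges = ranges, centroid_distances = cent_dist,
    structure_profiles = struct, structure_dissimilarity = struct_dis,
    permanova = c(list(population = perm_pop), perm_hab),
    pairwise = pairwise,
    mantel = list(centroid = mantel_dist, structure = mantel_struct),
    ols = list(iu = ols_iu, dp = ols_dp, richness = ols_rich),
    model_rank = model_rank,
    welch_single_vs_longitudinal = welch_single,
    nmds = ord,
    diet_dissimilarity = bc_diet,
    sample_dissimilarity = bc_samples,
    seed = seed), class = "dietscape_bundle")
}

#' @export
print.dietscape_bundle <- function(x, ...) {
  cat("dietscape result bundle:", length(x$individuals), "individuals,",
      nrow(x$sample_dissimilarity), "samples, seed", x$seed, "\n")
  invisible(x)
}

# ---- reporting -----------------------------------------------------------

fmt_permanova <- function(p) {
  if (is_na_section(p)) return("not applicable")
  g <- p$terms[p$terms$term == "group", ]
  sprintf("pseudo-F(%d, %d) = %.2f, R2 = %.2f, p = %.4g (%d perms)",
          g$df, p$residual$df, g$pseudo_F, g$R2, g$p_perm, p$n_perm)
}

fmt_mantel <- function(m) {
  if (is_na_section(m)) return("not applicable")
  sprintf("r = %.3f, p = %.4g", m$r, m$p_perm)
}

fmt_ols <- function(f) {
  if (is_na_section(f)) return("not applicable")
  co <- f$coefficients
  sprintf("slope = %.3f, p = %.4g, R2 = %.2f",
          co["condition", "estimate"], co["condition", "p"], f$r_squared)
}

#' Summarize a result bundle
#'
#' Produces a human-readable markdown report and a machine summary that
#' serializes losslessly to JSON.
#'
#' @param bundle a `"dietscape_bundle"`.
#' @param out_dir optional directory; if given, writes `report.md` and
#'   `report.json` there.
#' @return list with `markdown` (character) and `summary` (list), invisibly
#'   if `out_dir` was written.
#' @export
report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "dietscape_bundle"))
  required <- c("richness", "permanova", "pairwise", "mantel", "ols",
                "model_rank", "welch_single_vs_longitudinal",
                "population_richness")
  missing <- required[!required %in% names(bundle)]
  if (length(missing)) stop("incomplete bundle, missing: ",
                            paste(missing, collapse = ", "))
  b <- bundle
  md <- c(
    "# Individual dietary niche variation — analysis report", "",
    sprintf("Individuals analyzed: %d (%s); seed %d; %d permutations; k = %d, B = %d.",
            length(b$individuals),
            paste(table(b$richness$habitat) |> (\(t) paste0(t, " ", names(t)))(),
                  collapse = ", "),
            b$seed, b$config$n_perm, b$config$k, b$config$B), "",
    "## Dietary richness", "",
    sprintf("Population-level richness: %.1f +/- %.2f taxa (mean +/- SD over %d iterations).",
            b$population_richness$mean, b$population_richness$sd, b$config$B),
    sprintf("Individual richness: %.1f to %.1f taxa (mean of means %.1f +/- %.2f).",
            min(b$richness$mean), max(b$richness$mean),
            mean(b$richness$mean), stats::sd(b$richness$mean)), "",
    "## Diet composition: perMANOVA (individual ID, year-blocked)", "",
    paste0("- population: ", fmt_permanova(b$permanova$population)),
    paste0("- woodland: ", fmt_permanova(b$permanova$woodland)),
    paste0("- floodplain: ", fmt_permanova(b$permanova$floodplain)),
    sprintf("- pairwise contrasts: %d of %d significant at Holm-adjusted p < 0.05",
            sum(b$pairwise$p_holm < 0.05), nrow(b$pairwise)), "",
    "## Distance decay (Mantel)", "",
    paste0("- diet ~ centroid distance: population ",
           fmt_mantel(b$mantel$centroid$population), "; woodland ",
           fmt_mantel(b$mantel$centroid$woodland), "; floodplain ",
           fmt_mantel(b$mantel$centroid$floodplain)),
    paste0("- diet ~ vegetation structure: population ",
           fmt_mantel(b$mantel$structure$population), "; woodland ",
           fmt_mantel(b$mantel$structure$woodland), "; floodplain ",
           fmt_mantel(b$mantel$structure$floodplain)), "",
    "## Condition regressions (OLS)", "",
    paste0("- intensity of use ~ condition: ", fmt_ols(b$ols$iu$population)),
    paste0("- digestible protein ~ condition: ", fmt_ols(b$ols$dp$population)),
    paste0("- dietary richness ~ condition: ", fmt_ols(b$ols$richness$population)), "",
    "## Single vs longitudinal sampling", "",
    if (is_na_section(b$welch_single_vs_longitudinal)) "not applicable" else
      sprintf("single-sample mean richness %.1f vs standardized %.1f (Welch t = %.2f, df = %.1f, p = %.4g)",
              b$welch_single_vs_longitudinal$mean1,
              b$welch_single_vs_longitudinal$mean2,
              b$welch_single_vs_longitudinal$t,
              b$welch_single_vs_longitudinal$df,
              b$welch_single_vs_longitudinal$p), ""
  )
  if (!is_na_section(b$model_rank)) {
    md <- c(md, "## AICc model ranking (dietary richness)", "",
            utils::capture.output(print.data.frame(
              within(as.data.frame(b$model_rank), {
                AICc <- round(AICc, 2); delta_AICc <- round(delta_AICc, 3)
                weight <- round(weight, 3); adj_r_squared <- round(adj_r_squared, 2)
              }), row.names = FALSE)), "")
  }
  summary <- list(
    n_individuals = length(b$individuals),
    seed = b$seed,
    population_richness = b$population_richness,
    individual_richness = b$richness,
    permanova = lapply(b$permanova, function(p) if (is_na_section(p)) NULL else
      list(terms = p$terms, residual = p$residual, n_perm = p$n_perm, seed = p$seed)),
    pairwise_n = nrow(b$pairwise),
    pairwise_sig = sum(b$pairwise$p_holm < 0.05),
    mantel = lapply(b$mantel, function(g) lapply(g, function(m)
      if (is_na_section(m)) NULL else list(r = m$r, p = m$p_perm, n_perm = m$n_perm))),
    ols = lapply(b$ols, function(g) lapply(g, function(f)
      if (is_na_section(f)) NULL else list(
        slope = unname(f$coefficients["condition", "estimate"]),
        p = unname(f$coefficients["condition", "p"]),
        r_squared = f$r_squared))),
    model_rank = if (is_na_section(b$model_rank)) NULL else as.data.frame(b$model_rank),
    welch_single_vs_longitudinal =
      if (is_na_section(b$welch_single_vs_longitudinal)) NULL else
        b$welch_single_vs_longitudinal,
    checks = list(
      rarefied_depth_uniform = length(unique(b$profiles$depth)) == 1L,
      pairwise_expected = choose(length(b$individuals), 2L) == nrow(b$pairwise))
  )
  md_text <- paste(md, collapse = "\n")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(md_text, file.path(out_dir, "report.md"))
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(list(markdown = md_text, summary = summary)))
  }
  list(markdown = md_text, summary = summary)
}
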