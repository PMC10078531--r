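# Synthetic-world generator. Emulates the statistical structure of a
# two-habitat floodplain/woodland landscape with GPS-collared browsers:
# distinct species pools with different digestible-protein (DP)
# distributions, distance-decay of plant-community similarity, mean-reverting
# movement, condition-dependent diet selectivity, and multinomial
# metabarcoding read noise with PCR replicates and rare contaminant mOTUs.
# All coordinates are planar km; all generators are reproducible under a
# fixed seed via per-operation RNG streams.

#' Generate a two-habitat plant landscape
#'
#' Taxon availability is a normalized Gaussian-kernel mixture: each taxon has
#' `n_centers` kernel centers placed inside its habitat pool (floodplain
#' strip `x < floodplain_fraction * extent[1]`, woodland elsewhere, shared
#' anywhere), so community composition decays smoothly with distance and the
#' two habitats hold distinct pools. Floodplain taxa are drawn with a higher
#' mean DP than woodland taxa (enforced strictly).
#'
#' @param n_taxa number of plant taxa (>= 2).
#' @param extent `c(xmax, ymax)` of the rectangular study area, km (origin 0).
#' @param floodplain_fraction fraction of the x-extent forming the
#'   floodplain strip (default 0.3).
#' @param bandwidth kernel bandwidth, km (> 0).
#' @param dp_params list with `floodplain_mean`, `woodland_mean`,
#'   `shared_mean`, `sd`, `min` for the DP draws (% dry mass).
#' @param seed integer master seed.
#' @param n_centers kernel centers per taxon (default 3).
#' @param pool_fractions proportions of taxa in the floodplain/woodland/
#'   shared pools.
#' @return object of class `"landscape"`.
#' @export
make_landscape <- function(n_taxa = 60L, extent = c(10, 10),
                           floodplain_fraction = 0.3, bandwidth = 1.2,
                           dp_params = list(floodplain_mean = 25,
                                            woodland_mean = 14,
                                            shared_mean = 18, sd = 4, min = 2),
                           seed = 1L, n_centers = 3L,
                           pool_fractions = c(floodplain = 0.3,
                                              woodland = 0.5, shared = 0.2)) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (any(extent <= 0) || bandwidth <= 0)
    stop("extent and bandwidth must be positive")
  fp_x <- floodplain_fraction * extent[1L]
  with_seed(op_seed(seed, "make_landscape"), {
    pools <- sample(rep(c("floodplain", "woodland", "shared"),
                        times = round_half_up(pool_fractions * n_taxa))[seq_len(n_taxa)])
    pools <- c(pools, rep("shared", n_taxa - length(pools)))[seq_len(n_taxa)]
    repeat { # enforce: floodplain pool mean DP strictly above woodland pool
      dp <- numeric(n_taxa)
      for (p in c("floodplain", "woodland", "shared")) {
        idx <- pools == p
        mu <- switch(p, floodplain = dp_params$floodplain_mean,
                     woodland = dp_params$woodland_mean,
                     shared = dp_params$shared_mean)
        dp[idx] <- pmax(dp_params$min, stats::rnorm(sum(idx), mu, dp_params$sd))
      }
      if (!any(pools == "floodplain") || !any(pools == "woodland") ||
          mean(dp[pools == "floodplain"]) > mean(dp[pools == "woodland"]))
        break
    }
    centers <- vector("list", n_taxa)
    for (i in seq_len(n_taxa)) {
      xr <- switch(pools[i],
                   floodplain = c(0, fp_x),
                   woodland = c(fp_x, extent[1L]),
                   shared = c(0, extent[1L]))
      centers[[i]] <- cbind(stats::runif(n_centers, xr[1L], xr[2L]),
                            stats::runif(n_centers, 0, extent[2L]))
    }
    structure(list(extent = extent, floodplain_x = fp_x,
                   taxa = data.frame(taxon_id = sprintf("motu%02d", seq_len(n_taxa)),
                                     habitat_pool = pools, dp = dp,
                                     stringsAsFactors = FALSE),
                   centers = centers, bandwidth = bandwidth, baseline = 1e-3,
                   seed = seed),
              class = "landscape")
  })
}

#' Relative availability of every taxon at given locations
#'
#' @param landscape a `"landscape"`.
#' @param xy two-column matrix of locations (km).
#' @return matrix locations x taxa; every row sums to 1.
#' @export
availability <- function(landscape, xy) {
  stopifnot(inherits(landscape, "landscape"))
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2L)
  n_taxa <- nrow(landscape$taxa)
  A <- matrix(landscape$baseline, nrow(xy), n_taxa)
  b2 <- 2 * landscape$bandwidth^2
  for (i in seq_len(n_taxa)) {
    cc <- landscape$centers[[i]]
    for (j in seq_len(nrow(cc))) {
      d2 <- (xy[, 1L] - cc[j, 1L])^2 + (xy[, 2L] - cc[j, 2L])^2
      A[, i] <- A[, i] + exp(-d2 / b2)
    }
  }
  A <- A / rowSums(A)
  colnames(A) <- landscape$taxa$taxon_id
  A
}

#' Floodplain polygon of a synthetic landscape
#'
#' @param landscape a `"landscape"`.
#' @return CCW rectangle covering the floodplain strip.
#' @export
floodplain_polygon <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  rbind(c(0, 0), c(landscape$floodplain_x, 0),
        c(landscape$floodplain_x, landscape$extent[2L]),
        c(0, landscape$extent[2L]))
}

#' Generate individual specifications
#'
#' Floodplain-affiliated individuals get range centroids inside the
#' floodplain strip (with an interior margin), woodland individuals outside
#' it. Condition is drawn i.i.d. from `condition_dist`; diet selectivity is
#' the DP-power exponent `beta = beta0 + beta1 * condition` (state-dependent
#' foraging: better condition, stronger preference for protein-rich taxa).
#'
#' @param n number of individuals.
#' @param floodplain_count how many are floodplain-affiliated (0..n).
#' @param landscape a `"landscape"` supplying the strip geometry.
#' @param condition_dist function of `n` returning condition draws
#'   (default standard normal).
#' @param seed integer master seed.
#' @param beta0,beta1 selectivity intercept/slope on condition (`beta1 >= 0`).
#' @param margin centroid margin from the area edges, km.
#' @return data.frame of class `"individuals"`: `individual_id`, `x`, `y`,
#'   `condition`, `reproductive_class`, `habitat_true`, `beta`.
#' @export
make_individuals <- function(n = 15L, floodplain_count = 7L, landscape,
                             condition_dist = stats::rnorm, seed = 1L,
                             beta0 = 2, beta1 = 2, margin = 0.8) {
  if (floodplain_count > n || floodplain_count < 0)
    stop("floodplain_count must lie in [0, n]")
  if (beta1 < 0) stop("beta1 must be >= 0")
  stopifnot(inherits(landscape, "landscape"))
  ex <- landscape$extent; fx <- landscape$floodplain_x
  with_seed(op_seed(seed, "make_individuals"), {
    habitat <- c(rep("floodplain", floodplain_count),
                 rep("woodland", n - floodplain_count))
    x <- numeric(n); y <- stats::runif(n, margin, ex[2L] - margin)
    fp <- habitat == "floodplain"
    x[fp] <- stats::runif(sum(fp), min(margin, fx / 4), max(fx - margin, fx / 2))
    x[!fp] <- stats::runif(sum(!fp), fx + margin, ex[1L] - margin)
    cond <- condition_dist(n)
    repro <- sample(c("lactating", "non-lactating", "male"), n, replace = TRUE,
                    prob = c(0.3, 0.35, 0.35))
    out <- data.frame(individual_id = sprintf("ind%02d", seq_len(n)),
                      x = x, y = y, condition = cond,
                      reproductive_class = repro, habitat_true = habitat,
                      beta = beta0 + beta1 * cond, stringsAsFactors = FALSE)
    class(out) <- c("individuals", "data.frame")
    out
  })
}

#' Simulate a mean-reverting GPS track
#'
#' Discrete Ornstein-Uhlenbeck-style walk around the individual's range
#' centroid: `x[t+1] = x[t] + theta * (centroid - x[t]) + sigma * eps`. The
#' reversion strength `theta` increases with condition
#' (`theta = theta0 + beta_theta * condition`, clamped), while the step noise
#' is scaled so the stationary range spread stays `range_sd` — so
#' better-condition animals travel longer paths inside a same-sized range,
#' and intensity of use rises with condition in expectation.
#'
#' @param spec one row of an `"individuals"` frame (list-like with `x`, `y`,
#'   `condition`, `individual_id`).
#' @param n_days days of tracking (default 21).
#' @param fixes_per_day fixes per day (default 24, hourly).
#' @param ou_params list: `range_sd` (km), `theta0`, `beta_theta`,
#'   `theta_range` clamp.
#' @param seed integer master seed.
#' @return data.frame track: `individual_id`, `timestamp` (days), `x`, `y`.
#' @export
simulate_track <- function(spec, n_days = 21L, fixes_per_day = 24L,
                           ou_params = list(range_sd = 0.35, theta0 = 0.35,
                                            beta_theta = 0.18,
                                            theta_range = c(0.05, 0.9)),
                           seed = 1L) {
  if (n_days < 1L || fixes_per_day < 1L) stop("n_days and fixes_per_day must be >= 1")
  n <- n_days * fixes_per_day
  theta <- min(max(ou_params$theta0 + ou_params$beta_theta * spec$condition,
                   ou_params$theta_range[1L]), ou_params$theta_range[2L])
  sigma <- ou_params$range_sd * sqrt(theta * (2 - theta))
  mu <- c(spec$x, spec$y)
  xy <- matrix(0, n, 2L)
  xy[1L, ] <- mu
  with_seed(op_seed(seed, paste0("simulate_track_", spec$individual_id)), {
    if (sigma > 0) {
      eps <- matrix(stats::rnorm(2L * (n - 1L), sd = sigma), n - 1L, 2L)
      for (t in seq_len(n - 1L))
        xy[t + 1L, ] <- xy[t, ] + theta * (mu - xy[t, ]) + eps[t, ]
    } else {
      xy[-1L, ] <- rep(mu, each = n - 1L)
    }
  })
  data.frame(individual_id = spec$individual_id,
             timestamp = (seq_len(n) - 1L) / fixes_per_day,
             x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
}

#' Simulate true diet-proportion vectors for one individual
#'
#' Each fecal sample is anchored at a random fix of the individual's track;
#' its expected diet is local availability re-weighted by `dp^beta`
#' (condition-dependent selectivity), perturbed by Dirichlet noise with
#' concentration `dirichlet_conc` (larger = less sample-to-sample noise;
#' `Inf` = no noise).
#'
#' @param spec one row of an `"individuals"` frame (uses `beta`).
#' @param track the individual's track.
#' @param landscape a `"landscape"`.
#' @param n_samples number of fecal samples (>= 1).
#' @param dirichlet_conc Dirichlet concentration (default 40).
#' @param seed integer master seed.
#' @return matrix `n_samples x n_taxa` of proportions (rows sum to 1), with
#'   sample locations in `attr(, "locations")`.
#' @export
simulate_diet_samples <- function(spec, track, landscape, n_samples = 10L,
                                  dirichlet_conc = 40, seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  with_seed(op_seed(seed, paste0("simulate_diet_", spec$individual_id)), {
    fix_idx <- sort(sample.int(nrow(track), n_samples, replace = TRUE))
    loc <- cbind(track$x[fix_idx], track$y[fix_idx])
    A <- availability(landscape, loc)
    if (any(rowSums(A) == 0)) stop("all-zero availability at a sampled location")
    logdp <- log(pmax(landscape$taxa$dp, 1e-12))
    out <- matrix(0, n_samples, ncol(A), dimnames = list(NULL, colnames(A)))
    for (s in seq_len(n_samples)) {
      lw <- log(A[s, ]) + spec$beta * logdp
      lw <- lw - max(lw)
      p <- exp(lw); p <- p / sum(p)
      if (is.finite(dirichlet_conc)) {
        g <- stats::rgamma(length(p), shape = dirichlet_conc * p)
        if (sum(g) == 0) g[which.max(p)] <- 1
        p <- g / sum(g)
      }
      out[s, ] <- p
    }
    attr(out, "locations") <- loc
    out
  })
}

#' Simulate a metabarcoding read table from true diet proportions
#'
#' Each PCR replicate is an independent multinomial draw at its own read
#' depth. Rare contaminant mOTUs are mixed in per physical sample from a
#' global nuisance pool at expected within-sample RRA between `contam_rra[1]`
#' and `contam_rra[2]` (default 0.1-0.9%), straddling nothing: all below the
#' 1% filter in expectation, so the filter removes them.
#'
#' @param diet_proportions matrix samples x taxa of true proportions; row
#'   names become sample ids (default `s01...`).
#' @param n_pcr PCR replicates per sample (default 3).
#' @param depth_range integer range of per-replicate read depths, drawn
#'   uniformly (default 8000-16000).
#' @param contaminant_rate per-sample presence probability of each
#'   contaminant (0 disables; default 0.5).
#' @param n_contaminants size of the global nuisance pool (default 8).
#' @param contam_rra expected-RRA band for a present contaminant.
#' @param seed integer master seed.
#' @param samples optional per-sample metadata data.frame.
#' @return a `"read_count_table"` with `n_pcr` rows per sample.
#' @export
simulate_read_table <- function(diet_proportions, n_pcr = 3L,
                                depth_range = c(8000L, 16000L),
                                contaminant_rate = 0.5, n_contaminants = 8L,
                                contam_rra = c(0.001, 0.009), seed = 1L,
                                samples = NULL) {
  if (n_pcr < 1L) stop("n_pcr must be >= 1")
  if (any(depth_range <= 0)) stop("read depth must be positive")
  P <- as.matrix(diet_proportions)
  if (is.null(rownames(P))) rownames(P) <- sprintf("s%02d", seq_len(nrow(P)))
  ncont <- if (contaminant_rate > 0) n_contaminants else 0L
  taxa <- c(colnames(P), if (ncont) sprintf("contam%02d", seq_len(ncont)))
  ns <- nrow(P)
  counts <- matrix(0L, ns * n_pcr, length(taxa),
                   dimnames = list(NULL, taxa))
  sample_id <- rep(rownames(P), each = n_pcr)
  pcr_rep <- rep(paste0("rep", seq_len(n_pcr)), times = ns)
  with_seed(op_seed(seed, "simulate_read_table"), {
    for (s in seq_len(ns)) {
      p <- P[s, ]
      cmass <- numeric(ncont)
      if (ncont) {
        present <- stats::runif(ncont) < contaminant_rate
        cmass[present] <- stats::runif(sum(present), contam_rra[1L], contam_rra[2L])
      }
      full <- c(p * (1 - sum(cmass)), cmass)
      for (r in seq_len(n_pcr)) {
        depth <- if (depth_range[1L] == depth_range[2L]) depth_range[1L] else
          sample(seq(depth_range[1L], depth_range[2L]), 1L)
        counts[(s - 1L) * n_pcr + r, ] <- stats::rmultinom(1L, depth, full)[, 1L]
      }
    }
  })
  rownames(counts) <- paste(sample_id, pcr_rep, sep = ":")
  read_count_table(counts, sample_id, pcr_rep, samples)
}

#' Simulate classified LiDAR point clouds over home ranges
#'
#' Points are placed uniformly inside each home-range polygon. Heights follow
#' the habitat: floodplain-strip points are overwhelmingly ground/low
#' vegetation (treeless), woodland points mix all four classes with
#' probabilities driven by a spatially autocorrelated canopy field (Gaussian
#' bumps), so nearby woodland ranges get similar structure profiles.
#'
#' @param landscape a `"landscape"`.
#' @param home_ranges named list of `"home_range"` objects (or CCW polygons).
#' @param points_per_range points per range (>= 4).
#' @param seed integer master seed.
#' @return named list of data.frames (`x`, `y`, `height`).
#' @export
simulate_lidar_points <- function(landscape, home_ranges,
                                  points_per_range = 400L, seed = 1L) {
  if (points_per_range < 4L) stop("points_per_range must be >= 4")
  stopifnot(inherits(landscape, "landscape"))
  ex <- landscape$extent; fx <- landscape$floodplain_x
  with_seed(op_seed(seed, "simulate_lidar_points"), {
    nb <- 40L # canopy bumps in woodland
    bumps <- cbind(stats::runif(nb, fx, ex[1L]), stats::runif(nb, 0, ex[2L]))
    amp <- stats::runif(nb, 0.4, 1)
    canopy <- function(x, y) {
      v <- 0
      for (j in seq_len(nb))
        v <- v + amp[j] * exp(-((x - bumps[j, 1L])^2 + (y - bumps[j, 2L])^2) / (2 * 0.8^2))
      1 - exp(-v) # squash to [0, 1)
    }
    out <- list()
    for (nm in names(home_ranges)) {
      hr <- home_ranges[[nm]]
      poly <- if (inherits(hr, "home_range")) hr$mcp95$polygon else as.matrix(hr)
      if (nrow(poly) < 3L || polygon_area(poly) <= 0)
        stop("empty or degenerate home-range polygon: ", nm)
      bb <- rbind(range(poly[, 1L]), range(poly[, 2L]))
      pts <- matrix(0, 0, 2L)
      while (nrow(pts) < points_per_range) {
        cand <- cbind(stats::runif(points_per_range * 2L, bb[1L, 1L], bb[1L, 2L]),
                      stats::runif(points_per_range * 2L, bb[2L, 1L], bb[2L, 2L]))
        pts <- rbind(pts, cand[points_in_polygon(cand, poly), , drop = FALSE])
      }
      pts <- pts[seq_len(points_per_range), , drop = FALSE]
      h <- numeric(points_per_range)
      for (i in seq_len(points_per_range)) {
        if (pts[i, 1L] < fx) {
          pr <- c(ground = 0.55, low = 0.40, medium = 0.05, high = 0)
        } else {
          cv <- canopy(pts[i, 1L], pts[i, 2L])
          p_high <- 0.05 + 0.45 * cv
          p_med <- 0.15 + 0.25 * cv
          rest <- 1 - p_high - p_med
          pr <- c(ground = 0.5 * rest, low = 0.5 * rest,
                  medium = p_med, high = p_high)
        }
        cls <- sample(names(pr), 1L, prob = pr)
        h[i] <- switch(cls,
                       ground = stats::runif(1L, 0, 0.05),
                       low = stats::runif(1L, 0.051, 0.299),
                       medium = stats::runif(1L, 0.3, 1.6),
                       high = stats::runif(1L, 1.61, 12))
      }
      out[[nm]] <- data.frame(x = pts[, 1L], y = pts[, 2L], height = h)
    }
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Composes the landscape, individuals, tracks, diet samples, read table and
#' LiDAR clouds into one world with known ground truth. Defaults emulate the
#' study design the package targets: 15 individuals (7 floodplain, 8
#' woodland), 6-14 fecal samples each over two habitats, hourly fixes for 21
#' days, triplicate PCR, and a capture year split across two field seasons.
#'
#' @param seed integer master seed (all stage seeds derive from it).
#' @param n_individuals,floodplain_count population design.
#' @param n_taxa,extent,floodplain_fraction,bandwidth landscape parameters.
#' @param samples_range inclusive range of fecal samples per individual.
#' @param n_days,fixes_per_day tracking design.
#' @param ou_params movement parameters (see [simulate_track()]).
#' @param beta0,beta1 selectivity parameters (see [make_individuals()]).
#' @param dirichlet_conc diet sample noise (see [simulate_diet_samples()]).
#' @param n_pcr,depth_range,contaminant_rate read-table parameters.
#' @param lidar_points LiDAR points per home range.
#' @return object of class `"world"`: list with `landscape`, `individuals`,
#'   `tracks`, `diet_proportions`, `read_table`, `lidar`, `truth`.
#' @export
simulate_world <- function(seed = 1L, n_individuals = 15L,
                           floodplain_count = 7L, n_taxa = 60L,
                           extent = c(10, 10), floodplain_fraction = 0.3,
                           bandwidth = 1.6, n_centers = 4L,
                           samples_range = c(6L, 14L),
                           n_days = 21L, fixes_per_day = 24L,
                           ou_params = list(range_sd = 0.35, theta0 = 0.35,
                                            beta_theta = 0.3,
                                            theta_range = c(0.05, 0.9)),
                           beta0 = 2, beta1 = 2, dirichlet_conc = 60,
                           n_pcr = 3L, depth_range = c(8000L, 16000L),
                           contaminant_rate = 0.5, lidar_points = 400L) {
  land <- make_landscape(n_taxa = n_taxa, extent = extent,
                         floodplain_fraction = floodplain_fraction,
                         bandwidth = bandwidth, n_centers = n_centers,
                         seed = seed)
  inds <- make_individuals(n = n_individuals,
                           floodplain_count = floodplain_count,
                           landscape = land, seed = seed,
                           beta0 = beta0, beta1 = beta1)
  n_samp <- with_seed(op_seed(seed, "samples_per_individual"),
                      sample(seq(samples_range[1L], samples_range[2L]),
                             n_individuals, replace = TRUE))
  year <- with_seed(op_seed(seed, "capture_year"),
                    sample(rep(c(2018L, 2019L),
                               c(ceiling(n_individuals / 2), floor(n_individuals / 2)))))
  tracks <- list(); props <- list(); meta <- list()
  for (i in seq_len(n_individuals)) {
    spec <- inds[i, ]
    tracks[[spec$individual_id]] <-
      simulate_track(spec, n_days, fixes_per_day, ou_params, seed)
    P <- simulate_diet_samples(spec, tracks[[spec$individual_id]], land,
                               n_samples = n_samp[i],
                               dirichlet_conc = dirichlet_conc, seed = seed)
    rownames(P) <- sprintf("%s_s%02d", spec$individual_id, seq_len(n_samp[i]))
    props[[spec$individual_id]] <- P
    loc <- attr(P, "locations")
    meta[[i]] <- data.frame(sample_id = rownames(P),
                            individual_id = spec$individual_id,
                            year = year[i],
                            habitat_at_collection =
                              ifelse(loc[, 1L] < land$floodplain_x,
                                     "floodplain", "woodland"),
                            stringsAsFactors = FALSE)
  }
  all_props <- do.call(rbind, props)
  samples <- do.call(rbind, meta)
  reads <- simulate_read_table(all_props, n_pcr = n_pcr,
                               depth_range = depth_range,
                               contaminant_rate = contaminant_rate,
                               seed = seed, samples = samples)
  ranges <- lapply(tracks, function(tr)
    home_range(tr, individual_id = tr$individual_id[1L]))
  lidar <- simulate_lidar_points(land, ranges, points_per_range = lidar_points,
                                 seed = seed)
  structure(list(landscape = land, individuals = inds, tracks = tracks,
                 diet_proportions = all_props, read_table = reads,
                 lidar = lidar, home_ranges = ranges,
                 truth = list(seed = seed, beta0 = beta0, beta1 = beta1,
                              ou_params = ou_params,
                              dirichlet_conc = dirichlet_conc,
                              floodplain_count = floodplain_count,
                              samples_per_individual = stats::setNames(
                                n_samp, inds$individual_id),
                              year = stats::setNames(year, inds$individual_id))),
            class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat("synthetic world:", nrow(x$individuals), "individuals,",
      nrow(x$diet_proportions), "diet samples,",
      nrow(x$landscape$taxa), "taxa, seed", x$truth$seed, "\n")
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Emits `reads.csv` (sample_id, pcr_rep, motu_id, count — long format),
#' `gps.csv`, `lidar.csv`, `traits.csv`, `animals.csv` and `truth.json`
#' into `dir`.
#'
#' @param world a `"world"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rt <- world$read_table
  long <- data.table::as.data.table(rt$counts)
  long[, `:=`(sample_id = rt$sample_id, pcr_rep = rt$pcr_rep)]
  long <- data.table::melt(long, id.vars = c("sample_id", "pcr_rep"),
                           variable.name = "motu_id", value.name = "count")
  long <- long[long$count > 0, ]
  data.table::fwrite(long, file.path(dir, "reads.csv"))
  gps <- data.table::rbindlist(world$tracks)
  data.table::fwrite(gps[, c("individual_id", "timestamp", "x", "y")],
                     file.path(dir, "gps.csv"),
                     col.names = TRUE)
  lid <- data.table::rbindlist(world$lidar)
  data.table::fwrite(lid, file.path(dir, "lidar.csv"))
  data.table::fwrite(world$read_table$samples, file.path(dir, "samples.csv"))
  data.table::fwrite(world$landscape$taxa[, c("taxon_id", "dp")],
                     file.path(dir, "traits.csv"))
  animals <- world$individuals
  animals$year <- world$truth$year[animals$individual_id]
  data.table::fwrite(animals[, c("individual_id", "condition",
                                 "reproductive_class", "year")],
                     file.path(dir, "animals.csv"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
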