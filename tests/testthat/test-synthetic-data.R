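# Generator properties: determinism, neutral limits, and the statistical
# structure the downstream analyses assume.

test_that("world generation is reproducible under a fixed seed", {
  w1 <- tiny_world(seed = 11)
  w2 <- tiny_world(seed = 11)
  expect_identical(w1$read_table$counts, w2$read_table$counts)
  expect_identical(w1$tracks, w2$tracks)
  expect_identical(w1$landscape$taxa, w2$landscape$taxa)
  expect_identical(w1$lidar, w2$lidar)
  w3 <- tiny_world(seed = 12)
  expect_false(identical(w1$read_table$counts, w3$read_table$counts))
})

test_that("landscape availability is a proper composition with habitat pools", {
  land <- make_landscape(n_taxa = 30, seed = 5)
  xy <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  A <- availability(land, xy)
  expect_equal(rowSums(A), rep(1, 20), tolerance = 1e-9)
  expect_true(all(A >= 0))
  expect_setequal(unique(land$taxa$habitat_pool),
                  c("floodplain", "woodland", "shared"))
  fp <- land$taxa$habitat_pool == "floodplain"
  wl <- land$taxa$habitat_pool == "woodland"
  expect_gt(mean(land$taxa$dp[fp]), mean(land$taxa$dp[wl]))
  expect_error(make_landscape(n_taxa = 1), "n_taxa")
  expect_error(make_landscape(bandwidth = 0), "positive")
})

test_that("infinite-bandwidth limit flattens the landscape", {
  land <- make_landscape(n_taxa = 20, bandwidth = 1e6, seed = 3)
  A <- availability(land, rbind(c(0.5, 0.5), c(9.5, 9.5), c(2, 8)))
  expect_equal(A[1, ], A[2, ], tolerance = 1e-9)
  expect_equal(bray_curtis(A)[1, 2], 0, tolerance = 1e-9)
})

test_that("plant-community dissimilarity increases with site distance", {
  land <- make_landscape(n_taxa = 50, seed = 9)
  set.seed(9)
  sites <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  A <- availability(land, sites)
  rownames(A) <- paste0("s", 1:30)
  geo <- as.matrix(dist(sites)); dimnames(geo) <- dimnames(bray_curtis(A))
  m <- mantel(bray_curtis(A), geo, n_perm = 999, seed = 9)
  expect_gt(m$r, 0)
  expect_lt(m$p_perm, 0.05)
})

test_that("individual specs respect counts, habitat strips, and condition", {
  land <- make_landscape(seed = 2)
  inds <- make_individuals(n = 15, floodplain_count = 7, landscape = land,
                           seed = 2)
  expect_identical(sum(inds$habitat_true == "floodplain"), 7L)
  expect_identical(sum(inds$habitat_true == "woodland"), 8L)
  expect_true(all(inds$x[inds$habitat_true == "floodplain"] <= land$floodplain_x))
  expect_true(all(inds$x[inds$habitat_true == "woodland"] >= land$floodplain_x))
  expect_error(make_individuals(n = 3, floodplain_count = 4, landscape = land),
               "floodplain_count")

  one <- make_individuals(n = 1, floodplain_count = 0, landscape = land,
                          condition_dist = function(n) rep(0, n), seed = 1)
  expect_identical(one$condition, 0)

  # CLT check on the condition draw
  many <- make_individuals(n = 100, floodplain_count = 50, landscape = land,
                           condition_dist = function(n) rnorm(n, 2, 1), seed = 4)
  expect_lt(abs(mean(many$condition) - 2), 3 / sqrt(100))
})

test_that("tracks count fixes, order timestamps, and honour the zero-noise limit", {
  land <- make_landscape(seed = 1)
  spec <- make_individuals(n = 1, floodplain_count = 0, landscape = land,
                           seed = 1)[1, ]
  tr <- simulate_track(spec, n_days = 21, fixes_per_day = 24, seed = 1)
  expect_identical(nrow(tr), 504L)
  expect_true(all(diff(tr$timestamp) > 0))

  still <- simulate_track(spec, n_days = 2, fixes_per_day = 12,
                          ou_params = list(range_sd = 0, theta0 = 0.3,
                                           beta_theta = 0,
                                           theta_range = c(0.05, 0.9)),
                          seed = 1)
  expect_true(all(still$x == spec$x & still$y == spec$y))
  expect_equal(sum(sqrt(diff(still$x)^2 + diff(still$y)^2)), 0)
})

test_that("diet samples honour the neutral-selectivity and argmax limits", {
  land <- make_landscape(n_taxa = 25, seed = 6)
  spec <- make_individuals(n = 1, floodplain_count = 0, landscape = land,
                           beta0 = 0, beta1 = 0, seed = 6)[1, ]
  tr <- simulate_track(spec, n_days = 2, fixes_per_day = 12, seed = 6)

  neutral <- simulate_diet_samples(spec, tr, land, n_samples = 4,
                                   dirichlet_conc = Inf, seed = 6)
  A <- availability(land, attr(neutral, "locations"))
  expect_equal(unname(neutral), unname(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(neutral), rep(1, 4), tolerance = 1e-9)

  greedy_spec <- spec; greedy_spec$beta <- 200
  greedy <- simulate_diet_samples(greedy_spec, tr, land, n_samples = 3,
                                  dirichlet_conc = Inf, seed = 6)
  expect_true(all(apply(greedy, 1, max) > 0.99))
})

test_that("read tables have replicate structure and multinomial accuracy", {
  P <- rbind(s1 = c(mA = 1, mB = 0))
  rt <- simulate_read_table(P, n_pcr = 3, contaminant_rate = 0, seed = 2)
  expect_identical(sum(rt$pcr_rep == "rep1"), 1L)
  expect_identical(nrow(rt$counts), 3L)
  expect_true(all(rt$counts[, "mB"] == 0))
  expect_true(all(rowSums(rt$counts) == rt$counts[, "mA"]))

  P2 <- rbind(s1 = c(a = 0.5, b = 0.5))
  rt2 <- simulate_read_table(P2, n_pcr = 1, depth_range = c(100000L, 100000L),
                             contaminant_rate = 0, seed = 3)
  rra <- rt2$counts[1, ] / sum(rt2$counts[1, ])
  expect_lt(abs(rra[["a"]] - 0.5), 0.01) # ~6 binomial SE at depth 1e5

  expect_error(simulate_read_table(P, depth_range = c(0, 0)), "positive")
})

test_that("contaminants stay below the 1% filter in expectation", {
  w <- tiny_world(seed = 21)
  rt <- w$read_table
  contam <- grepl("^contam", colnames(rt$counts))
  expect_true(any(contam))
  rra <- rt$counts / rowSums(rt$counts)
  expect_lt(mean(rra[, contam]), 0.01)
  # the standard filter wipes them out
  prof <- process_read_table(rt, seed = 21)
  expect_true(all(prof$rra[, grepl("^contam", colnames(prof$rra))] == 0))
})

test_that("lidar clouds reflect habitat structure and are reproducible", {
  w <- tiny_world(seed = 8)
  land <- w$landscape
  fp_ids <- w$individuals$individual_id[w$individuals$habitat_true == "floodplain"]
  wl_ids <- w$individuals$individual_id[w$individuals$habitat_true == "woodland"]

  fp_pts <- w$lidar[[fp_ids[1]]]
  if (all(fp_pts$x < land$floodplain_x)) {
    prof <- structure_profile(fp_pts$height)
    expect_lt(prof[["high"]], 0.02) # treeless floodplain
  }
  wl_prof <- structure_profile(w$lidar[[wl_ids[1]]]$height)
  expect_gt(wl_prof[["high"]], 0)

  again <- simulate_lidar_points(land, w$home_ranges, points_per_range = 150,
                                 seed = 8)
  expect_identical(w$lidar, again)
  expect_error(simulate_lidar_points(land, w$home_ranges, points_per_range = 2),
               "points_per_range")
})

test_that("distant woodland ranges are more dissimilar in structure than adjacent ones", {
  land <- make_landscape(seed = 30)
  sq <- function(cx, cy, s = 0.6) rbind(c(cx - s, cy - s), c(cx + s, cy - s),
                                        c(cx + s, cy + s), c(cx - s, cy + s))
  polys <- list(a = sq(4.5, 5), b = sq(5.2, 5), c = sq(9, 1.2))
  d_adj <- d_far <- numeric(40)
  for (i in 1:40) {
    lid <- simulate_lidar_points(land, polys, points_per_range = 150, seed = 30 + i)
    profs <- t(sapply(lid, function(p) structure_profile(p$height)))
    D <- structure_dissimilarity(profs)
    d_adj[i] <- D["a", "b"]; d_far[i] <- D["a", "c"]
  }
  expect_gt(mean(d_far), mean(d_adj))
})
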