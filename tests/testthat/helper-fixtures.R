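# Shared fixtures, built in code. `tiny_world()` keeps everything the
# default stated world is, but trims counts that only cost time (taxa,
# LiDAR density) so unit tests stay fast.

tiny_world <- function(seed = 1L, ...) {
  simulate_world(seed = seed, n_taxa = 40L, lidar_points = 150L,
                 samples_range = c(6L, 10L), ...)
}

# A hand-sized read table: 2 samples x 3 PCR replicates x 4 mOTUs.
toy_read_table <- function() {
  counts <- rbind(
    c(10, 20, 0, 1), c(20, 20, 0, 0), c(30, 20, 3, 2),   # sample a
    c(100, 0, 50, 0), c(110, 0, 52, 0), c(90, 0, 48, 3)) # sample b
  colnames(counts) <- paste0("m", 1:4)
  read_count_table(counts,
                   sample_id = rep(c("a", "b"), each = 3L),
                   pcr_rep = rep(paste0("rep", 1:3), 2L),
                   samples = data.frame(sample_id = c("a", "b"),
                                        individual_id = c("i1", "i2")))
}

# Random occurrence matrix with guaranteed nonempty samples.
random_occurrence <- function(n_samples, n_taxa, p = 0.4, seed = 1L) {
  set.seed(seed)
  occ <- matrix(rbinom(n_samples * n_taxa, 1L, p), n_samples)
  occ[rowSums(occ) == 0, 1L] <- 1L
  colnames(occ) <- paste0("t", seq_len(n_taxa))
  occ
}

# Track tracing a known path: square of side `s` km walked point-by-point.
square_track <- function(s = 1, n_loops = 2, id = "x") {
  corners <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  pts <- corners[rep(1:4, n_loops + 1L), ][seq_len(4 * n_loops + 1L), ]
  data.frame(individual_id = id, timestamp = seq_len(nrow(pts)) / 24,
             x = pts[, 1L], y = pts[, 2L])
}
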