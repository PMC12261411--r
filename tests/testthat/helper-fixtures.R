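# Shared fixtures, all generated in code.

# random symmetric non-negative contact map
rand_map <- function(n = 20, seed = 1, density = 0.6, max_count = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- which(upper.tri(m, diag = TRUE))
  keep <- sample(up, round(density * length(up)))
  m[keep] <- sample.int(max_count, length(keep), replace = TRUE)
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_map(m)
}

# random 3D structure
rand_structure <- function(n = 30, seed = 1) {
  set.seed(seed)
  structure_3d(matrix(stats::rnorm(n * 3, sd = 2), n, 3))
}

# random rigid transform of a coordinate matrix (proper rotation)
random_rigid <- function(coords, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(coords %*% q, 2, stats::rnorm(3, sd = 5), `+`)
}

# independent two-pass product-moment correlation (test oracle)
pearson_bruteforce <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# noiseless map + ground truth structure from the generator
sim_truth <- function(n_loci = 60, alpha_true = 1.0, seed = 42) {
  sc <- sim_config(n_loci = n_loci, alpha_true = alpha_true, count_scale = 1,
                   noise = "none", seed = seed)
  s <- generate_structure(sc)
  list(config = sc, structure = s, map = structure_to_contacts(s, sc))
}

# synthetic training world: TAD-structured Poisson maps
demo_map <- function(seed, n = 80) {
  blocks <- list(c(round(0.06 * n), round(0.31 * n), 3),
                 c(round(0.38 * n), round(0.69 * n), 2.5),
                 c(round(0.75 * n), round(0.97 * n), 3))
  sc <- sim_config(n_loci = n, alpha_true = 1, count_scale = 40,
                   noise = "poisson", tad_blocks = blocks, seed = seed)
  structure_to_contacts(generate_structure(sc), sc)
}

# one trained demo model per test run (training is deterministic; cached
# so several test files can share it)
.demo_cache <- new.env(parent = emptyenv())
trained_demo <- function() {
  if (!is.null(.demo_cache$fit)) return(.demo_cache$fit)
  maps <- lapply(1:3, demo_map)
  sc <- sim_config(n_loci = 80, thinning_range = c(0.3, 0.95), seed = 11)
  pairs <- make_training_pairs(maps, sc, patch_side = 40, stride = 20)
  val <- make_training_pairs(lapply(104:106, demo_map),
                             sim_config(n_loci = 80,
                                        thinning_range = c(0.5, 0.8),
                                        seed = 55),
                             patch_side = 40, stride = 40)
  fit <- train_enhancer(pairs, train_config(steps = 400, batch = 2, seed = 11),
                        val_pairs = val, checkpoint_every = 100)
  fit$val_pairs <- val
  .demo_cache$fit <- fit
  fit
}

# held-out test pairs drawn from fresh maps with a distinct seed
heldout_pairs <- function() {
  maps <- lapply(101:103, demo_map)
  sc <- sim_config(n_loci = 80, thinning_range = c(0.5, 0.8), seed = 202)
  make_training_pairs(maps, sc, patch_side = 40, stride = 40)
}
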