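## Shared fixtures, memoised for the whole test run. All are pure functions
## of fixed seeds, so caching cannot leak state between tests.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, fun) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, fun(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_grid <- c(48, 48, 8)   # fast unit-test lattice
reg_grid <- c(64, 64, 12)   # registration / recon lattice

fx_canonical <- function() get_fixture("canonical", function()
  make_canonical_pelvis(reg_grid, seed = 10))

fx_deformed <- function() get_fixture("deformed", function()
  apply_random_deformation(fx_canonical(), amplitude_mm = 6, seed = 11))

fx_subject <- function() get_fixture("subject", function()
  make_subject_cohort(1, seed = 7, grid_shape = reg_grid)[[1]])

fx_templates <- function() get_fixture("templates", function()
  make_template_database(3, seed = 1, grid_shape = tiny_grid))

fx_tiny_subject <- function() get_fixture("tiny_subject", function()
  make_subject_cohort(1, seed = 99, grid_shape = tiny_grid)[[1]])

fx_adj_geom <- function() get_fixture("adj_geom", function()
  pet_geometry(c(64, 64), c(4, 4), 40))

## independent oracle: weighted median by direct application of the
## definition (smallest value whose cumulative weight reaches half)
oracle_weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  half <- sum(weights) / 2
  for (v in sort(unique(values))) {
    if (sum(weights[values <= v]) >= half) return(v)
  }
  stop("unreachable")
}

## independent oracle: exact two-sided signed-rank p-value by explicit
## bitmask enumeration of all sign assignments
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    vs[m + 1] <- sum(r[bits == 1L])
  }
  tol <- 1e-9
  min(1, 2 * min(mean(vs >= V - tol), mean(vs <= V + tol)))
}

bone_labels <- function() {
  lg <- tissue_legend()
  c(lg[["bone_cortical"]], lg[["bone_trabecular"]])
}
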