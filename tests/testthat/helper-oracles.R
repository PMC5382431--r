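# Independent oracles and tiny fixture builders shared across tests.

# small grid with uniform random dose
random_grid <- function(seed, dim = c(12L, 12L, 12L), max_dose = 300,
                        spacing = c(2, 2, 2)) {
  set.seed(seed)
  dose_grid(array(runif(prod(dim), 0, max_dose), dim), spacing = spacing)
}

# mask of a random voxel subset
random_mask <- function(grid, seed, frac = 0.3, name = "m") {
  set.seed(seed)
  n <- prod(grid$dim)
  structure_mask(name, sample.int(n, max(1, round(frac * n))), grid)
}

as_eqd2 <- function(grid, alpha_beta = 3) {
  structure(list(values = grid$values, origin = grid$origin,
                 spacing = grid$spacing, dim = grid$dim,
                 frame_id = grid$frame_id, alpha_beta = alpha_beta,
                 provenance = list("x")),
            class = "eqd2_grid")
}

# O(n^2) concordance-count AUC with ties counted one half
concordance_auc <- function(values, outcomes) {
  pos <- values[outcomes]; neg <- values[!outcomes]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# hand-computed two-group log-rank chi-square (hypergeometric variance)
hand_logrank <- function(groups, times, events) {
  g <- as.integer(factor(groups)) - 1L   # 0/1
  o_e <- 0; v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    d <- sum(events & times == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d1 <- sum(events & times == t & g == 1L)
    e1 <- d * n1 / n
    o_e <- o_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# Cox partial log-likelihood for one covariate, Breslow ties
cox_pll <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events])) {
    dead <- events & times == t
    at_risk <- times >= t
    ll <- ll + sum(beta * x[dead]) -
      sum(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# small complete cohort for pipeline-level tests (coarser grid for speed)
small_cohort <- function(n = 60L, seed = 42L, ...) {
  simulate_cohort(cohort_config(
    n_patients = n, n_lesions = n, seed = seed,
    grid = grid_spec(dim = c(96L, 96L, 96L), spacing = c(2, 2, 2)),
    chest_wall_x_mm = 150, ...))
}
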