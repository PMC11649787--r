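# Shared helpers: small fixtures built in code and independent oracles.

# tiny synthetic dataset for fast tests
tiny_dataset <- function(seed = 1, n_items = 40, n_annotators = 4,
                         preset = "exp1") {
  cfg <- experiment_preset(preset, n_items = n_items,
                          n_annotators = n_annotators)
  simulate_experiment(cfg, seed = seed)
}

# 2-D Simpson quadrature of g(mu, sigma) over a box (independent oracle for
# population expectations of annotator accuracy)
quadrature_box_mean <- function(g, mu_support, sigma_support, n_nodes = 201) {
  stopifnot(n_nodes %% 2 == 1)
  simpson_w <- function(m) {
    w <- rep(c(2, 4), length.out = m); w[1] <- 1; w[m] <- 1
    w
  }
  mu <- seq(mu_support[1], mu_support[2], length.out = n_nodes)
  sg <- seq(sigma_support[1], sigma_support[2], length.out = n_nodes)
  wmu <- simpson_w(n_nodes) * diff(mu_support) / (3 * (n_nodes - 1))
  wsg <- simpson_w(n_nodes) * diff(sigma_support) / (3 * (n_nodes - 1))
  vals <- outer(mu, sg, g)
  sum(outer(wmu, wsg) * vals) / (diff(mu_support) * diff(sigma_support))
}

# log-odds weighted vote with known annotator reliabilities (test-only
# oracle that knows the truth-generating parameters)
weighted_vote_oracle <- function(y, sensitivity, specificity) {
  w1 <- log(sensitivity) - log(1 - specificity)  # evidence of y = 1 for z = 1
  w0 <- log(1 - sensitivity) - log(specificity)
  llr <- y %*% w1 + (1 - y) %*% w0               # log odds of z = 1
  ifelse(as.numeric(llr) > 0, 1L, 0L)
}

# continuity-corrected Monte-Carlo estimate of hit probability and mean
# decision time (oracle for the closed forms; removes the O(sqrt(dt))
# first-passage bias of discrete crossing detection)
mc_ddm_oracle <- function(mu, sigma, n_paths, dt = 1e-3) {
  b <- 1 - 0.5826 * sigma * sqrt(dt)
  sim <- ddmcrowd:::simulate_paths(mu, sigma, n = n_paths, dt = dt,
                                   boundary = b)
  p <- mean(sim$hit_upper)
  list(p = p, p_se = sqrt(p * (1 - p) / n_paths),
       t = mean(sim$rt), t_se = stats::sd(sim$rt) / sqrt(n_paths))
}

# central finite-difference gradient of the full variational objective
fd_gradient <- function(y, par, control, rtsum = NULL, h = 1e-6) {
  g <- lapply(par, function(v) numeric(length(v)))
  for (blk in names(par)) {
    for (i in seq_along(par[[blk]])) {
      pp <- par; pp[[blk]][i] <- pp[[blk]][i] + h
      pm <- par; pm[[blk]][i] <- pm[[blk]][i] - h
      g[[blk]][i] <-
        (ddmcrowd:::vb_objective_full(y, pp, control, rtsum) -
           ddmcrowd:::vb_objective_full(y, pm, control, rtsum)) / (2 * h)
    }
  }
  g
}

random_vb_state <- function(n, k, seed) {
  set.seed(seed)
  list(q = runif(n, 0.15, 0.85), f = runif(n, -1, 1.5),
       mu0 = runif(k, 0.2, 0.8), sigma0 = runif(k, 0.3, 0.9),
       mu1 = runif(k, 0.2, 0.8), sigma1 = runif(k, 0.3, 0.9))
}
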