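# Independent brute-force oracle for the four-state cycle: builds the
# one-cycle transition matrix by enumerating the discrete event outcomes
# (death -> edentulism onset -> caries incidence -> recovery) for each
# starting state, then computes occupancy by explicit enumeration over all
# state paths, summing path probabilities. No arithmetic is shared with
# the engine's sequential occupancy updates.
oracle_step_matrix <- function(q, e, h, r, m = 1) {
  P <- matrix(0, 4, 4, dimnames = list(state_names(), state_names()))
  P["dead", "dead"] <- 1
  P["edentulous", "dead"] <- q
  P["edentulous", "edentulous"] <- 1 - q
  P["caries", "dead"] <- q
  P["caries", "edentulous"] <- (1 - q) * e
  P["caries", "caries_free"] <- (1 - q) * (1 - e) * r
  P["caries", "caries"] <- (1 - q) * (1 - e) * (1 - r)
  inc <- (1 - q) * (1 - e) * h * m
  P["caries_free", "dead"] <- q
  P["caries_free", "edentulous"] <- (1 - q) * e
  P["caries_free", "caries_free"] <- (1 - q) * (1 - e) * (1 - h * m) + inc * r
  P["caries_free", "caries"] <- inc * (1 - r)
  P
}

# occupancy at every cycle by explicit enumeration: occupancy of state s
# at cycle t is the sum of path probabilities over all length-t state
# sequences ending in s
oracle_trace <- function(state0, hazards) {
  Tn <- length(hazards)
  occ <- matrix(0, Tn + 1, 4, dimnames = list(NULL, state_names()))
  mats <- lapply(hazards, function(hz)
    oracle_step_matrix(hz$q, hz$e, hz$h, hz$r, if (is.null(hz$m)) 1 else hz$m))
  for (t in 0:Tn) {
    pre <- as.matrix(expand.grid(rep(list(1:4), t + 1)))
    for (p in seq_len(nrow(pre))) {
      pr <- state0[pre[p, 1]]
      if (t > 0)
        for (k in seq_len(t)) pr <- pr * mats[[k]][pre[p, k], pre[p, k + 1]]
      occ[t + 1, pre[p, t + 1]] <- occ[t + 1, pre[p, t + 1]] + pr
    }
  }
  occ
}

# random hazard set for property tests
random_hazards <- function(n, rng_max = 1) {
  lapply(seq_len(n), function(i)
    list(q = runif(1, 0, rng_max), e = runif(1, 0, rng_max),
         h = runif(1, 0, rng_max), r = runif(1, 0, rng_max),
         m = runif(1, 0, 1)))
}

# engine-side trace from the same hazards, via transition()
engine_trace <- function(state0, hazards) {
  st <- stats::setNames(state0, state_names())
  occ <- matrix(0, length(hazards) + 1, 4,
                dimnames = list(NULL, state_names()))
  occ[1, ] <- st
  for (t in seq_along(hazards)) {
    hz <- hazards[[t]]
    st <- transition(st, hz$q, hz$e, hz$h, hz$r,
                     if (is.null(hz$m)) 1 else hz$m)$state
    occ[t + 1, ] <- st
  }
  occ
}
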