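# Shared fixtures: small networks and conservation-law coefficient vectors.

fentanyl_net <- function() mor_network(mor_rates(k1 = 2.81e-3))
nfepp_net <- function() mor_network(mor_rates(k1 = 1.79e-4))

# coefficient vectors of the three conservation laws, species order
cons_vectors <- function() {
  sp <- mor_species()
  list(
    alpha = as.numeric(sp %in% c("aGDPbg", "aGTP", "aGDP")),
    betagamma = as.numeric(sp %in% c("aGDPbg", "bg", "Ca_off")),
    channel = as.numeric(sp %in% c("Ca_on", "Ca_off"))
  )
}

# apply a random sequence of feasible reactions, returning the final state
random_walk_state <- function(net, state, n_steps, seed) {
  set.seed(seed)
  for (i in seq_len(n_steps)) {
    f <- propensities(state, net)
    if (sum(f) == 0) break
    j <- sample.int(11, 1, prob = f)
    state <- apply_reaction(state, j, net)
  }
  state
}
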