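#' @useDynLib mornet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.ssa_core <- function(stoich, reactants, rates, init, t_end, grid_dt)
  .Call("mornet_ssa_core", stoich, reactants, rates, init, t_end, grid_dt,
        PACKAGE = "mornet")

#' Species of the MOR signalling network
#'
#' The fixed ordering of the 11 species: ligand `L`, receptor `R`,
#' receptor-ligand complex `RL`, internalised receptor `RL_w`, intact
#' (undissociated) G-protein `aGDPbg`, free GDP- and GTP-loaded alpha subunits
#' `aGDP` / `aGTP`, free betagamma subunit `bg`, internalisation partner `M`
#' (e.g. arrestin), and open / closed calcium channels `Ca_on` / `Ca_off`.
#' All state vectors in the package follow this order.
#'
#' @return Character vector of length 11.
#' @export
mor_species <- function() {
  c("L", "R", "RL", "RL_w", "aGDPbg", "aGDP", "aGTP", "bg", "M",
    "Ca_on", "Ca_off")
}

#' Rate constants of the MOR signalling network
#'
#' Constructs the vector of stochastic rate constants `k1..k11` (units s^-1,
#' acting directly on molecule counts; the reaction volume is folded into the
#' bimolecular constants). Defaults are the fitted intracellular constants
#' `k2..k10`, the fentanyl / pH 7.4 binding rate `k1`, and `k11 = 0`
#' (no constitutive G-protein activation, i.e. no radicals).
#'
#' @param k1 Ligand-receptor binding rate (s^-1). See [k1_reference()] for the
#'   ligand/pH-specific values.
#' @param k2 G-protein activation by the receptor-ligand complex.
#' @param k3 GTP hydrolysis, releasing the internalisation partner M.
#' @param k4 Receptor internalisation (RL + M -> RL_w).
#' @param k5 Calcium-channel closing by the betagamma subunit.
#' @param k6 Channel reopening and G-protein reassociation.
#' @param k7 Recycling of internalised receptor to the membrane.
#' @param k8 Degradation of internalised receptor.
#' @param k9 Degradation of M.
#' @param k10 Extracellular ligand decay.
#' @param k11 Constitutive (ligand-free) G-protein activation; `0` encodes the
#'   absence of reactive oxygen species.
#' @param preselected If `TRUE`, use the literature-preselected values of
#'   `k2..k10` instead of the fitted ones.
#' @return Named numeric vector `k1..k11` of class `"mor_rates"`.
#' @examples
#' mor_rates()
#' mor_rates(k1 = 1.79e-4)           # NFEPP at pH 7.4
#' mor_rates(preselected = TRUE)
#' @export
mor_rates <- function(k1 = 2.81e-3,
                      k2 = 1.3e-2, k3 = 6.4e-3, k4 = 1.1e-2, k5 = 5.2e-2,
                      k6 = 1.0e-1, k7 = 5.0e-4, k8 = 5.0e-5, k9 = 4.7e-3,
                      k10 = 1.9e-2, k11 = 0, preselected = FALSE) {
  if (preselected) {
    pre <- c(k2 = 1.0e-2, k3 = 5.0e-3, k4 = 5.0e-3, k5 = 5.0e-2,
             k6 = 2.5e-2, k7 = 5.0e-4, k8 = 5.0e-5, k9 = 5.0e-3,
             k10 = 2.5e-2)
    supplied <- intersect(names(pre), names(as.list(match.call()))[-1])
    given <- mget(supplied)
    k <- c(k1 = k1, pre, k11 = k11)
    k[supplied] <- unlist(given)
  } else {
    k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
           k7 = k7, k8 = k8, k9 = k9, k10 = k10, k11 = k11)
  }
  if (any(!is.finite(k)) || any(k < 0))
    stop("rate constants must be finite and nonnegative")
  structure(k, class = "mor_rates")
}

# Reactant index pairs for the propensities; 0 = no second reactant.
# R1: L+R; R2: RL, aGDPbg (RL catalytic); R3: aGTP; R4: RL+M; R5: bg+Ca_on;
# R6: aGDP+Ca_off; R7/R8: RL_w; R9: M; R10: L; R11: R, aGDPbg (R catalytic).
.mor_reactants <- function() {
  cbind(
    first  = c(1L, 3L, 7L, 3L, 8L, 6L, 4L, 4L, 9L, 1L, 2L),
    second = c(2L, 5L, 0L, 9L, 10L, 11L, 0L, 0L, 0L, 0L, 5L)
  )
}

# 11 x 11 stoichiometric matrix, species in rows, reactions in columns.
.mor_stoich <- function() {
  sp <- mor_species()
  nu <- matrix(0L, 11L, 11L, dimnames = list(sp, paste0("R", 1:11)))
  add <- function(j, ...) {
    ch <- c(...)
    nu[names(ch), j] <<- nu[names(ch), j] + as.integer(ch)
  }
  add(1L, L = -1, R = -1, RL = 1)
  add(2L, aGDPbg = -1, aGTP = 1, bg = 1)          # RL unchanged (catalyst)
  add(3L, aGTP = -1, aGDP = 1, M = 1)
  add(4L, RL = -1, M = -1, RL_w = 1)
  add(5L, bg = -1, Ca_on = -1, Ca_off = 1)
  add(6L, aGDP = -1, Ca_off = -1, aGDPbg = 1, Ca_on = 1)
  add(7L, RL_w = -1, R = 1)
  add(8L, RL_w = -1)
  add(9L, M = -1)
  add(10L, L = -1)
  add(11L, aGDPbg = -1, aGTP = 1, bg = 1)         # R unchanged (catalyst)
  nu
}

#' Build the MOR signalling reaction network
#'
#' Assembles the 11-reaction mass-action network connecting the receptor
#' cycle (ligand binding R1, internalisation R4, recycling R7, degradation
#' R8), the G-protein cycle (activation R2, hydrolysis R3, reassociation R6,
#' constitutive activation R11) and calcium-channel modulation by the
#' betagamma subunit (closing R5, reopening via R6).
#'
#' @param rates A [mor_rates()] vector.
#' @return An object of class `"mor_network"`: a list with `species`,
#'   `stoich` (11 x 11 integer matrix, species x reactions), `reactants`
#'   (reactant index pairs per reaction), `rates`, and human-readable
#'   reaction strings.
#' @examples
#' net <- mor_network(mor_rates())
#' net$stoich[, 1]   # R1 consumes one L and one R, produces one RL
#' @export
mor_network <- function(rates = mor_rates()) {
  if (!inherits(rates, "mor_rates")) rates <- do.call(mor_rates, as.list(rates))
  structure(list(
    species = mor_species(),
    stoich = .mor_stoich(),
    reactants = .mor_reactants(),
    rates = rates,
    reactions = c(
      "L + R -> RL", "RL + aGDPbg -> RL + aGTP + bg", "aGTP -> aGDP + M",
      "RL + M -> RL_w", "bg + Ca_on -> Ca_off",
      "aGDP + Ca_off -> aGDPbg + Ca_on", "RL_w -> R", "RL_w -> 0", "M -> 0",
      "L -> 0", "R + aGDPbg -> R + aGTP + bg")
  ), class = "mor_network")
}

#' @export
print.mor_network <- function(x, ...) {
  cat("MOR signalling network: 11 species, 11 reactions\n")
  k <- signif(unclass(x$rates), 3)
  for (j in 1:11)
    cat(sprintf("  R%-2d %-32s k%-2d = %g s^-1\n", j, x$reactions[j], j, k[j]))
  invisible(x)
}

#' Canonical initial molecule counts
#'
#' Initial state used for all network simulations: 10 ligands, 20 receptors,
#' 40 G-proteins and 80 calcium channels (ratio 1:2:4 for receptors,
#' G-proteins and channels). Under constitutive activation (`k11 > 0`) a base
#' level of `a` closed channels is pre-equilibrated: `a` G-proteins start
#' dissociated, their betagamma subunits bound to channels and their alpha
#' subunits GDP-loaded, so all three conservation totals are unchanged.
#'
#' @param a Base level of closed calcium channels (0 for `k11 = 0`;
#'   see [steady_state_base_level()]). Must lie in `[0, 40]`.
#' @param L,R,G,Ca Total ligands, receptors, G-proteins, calcium channels.
#' @return Named integer vector of length 11 in [mor_species()] order.
#' @examples
#' initial_state()       # a = 0
#' initial_state(a = 5)  # radical scenario base level
#' @export
initial_state <- function(a = 0, L = 10, R = 20, G = 40, Ca = 80) {
  a <- as.integer(round(a))
  if (a < 0 || a > G || a > Ca)
    stop("base level 'a' must lie between 0 and the G-protein/channel totals")
  x <- c(L = L, R = R, RL = 0, RL_w = 0, aGDPbg = G - a, aGDP = a, aGTP = 0,
         bg = 0, M = 0, Ca_on = Ca - a, Ca_off = a)
  storage.mode(x) <- "integer"
  names(x) <- mor_species()
  x
}

.check_state <- function(state) {
  if (length(state) != 11L)
    stop("state must have exactly 11 species counts")
  if (any(state < 0)) stop("molecule counts must be nonnegative")
  invisible(state)
}

#' Mass-action propensities
#'
#' Evaluates the 11 propensity functions at a population state: `k * x` for
#' unimolecular reactions and `k * x * y` for bimolecular ones, so a reaction
#' with any absent reactant has propensity zero.
#'
#' @param state Integer state vector (length 11, [mor_species()] order).
#' @param net A [mor_network()].
#' @return Named numeric vector of 11 nonnegative rates (s^-1).
#' @examples
#' net <- mor_network(mor_rates(k1 = 2.81e-3))
#' propensities(initial_state(), net)[1]   # k1 * 20 * 10 = 0.562
#' @export
propensities <- function(state, net) {
  .check_state(state)
  re <- net$reactants
  f <- unclass(net$rates) * state[re[, 1]]
  two <- re[, 2] > 0L
  f[two] <- f[two] * state[re[two, 2]]
  names(f) <- paste0("R", 1:11)
  f
}

#' Apply one reaction to a state
#'
#' Jumps the state by the stoichiometric vector of reaction `j`. The reaction
#' must be possible (all reactants present).
#'
#' @inheritParams propensities
#' @param j Reaction index in 1..11.
#' @return The updated state vector.
#' @export
apply_reaction <- function(state, j, net) {
  .check_state(state)
  j <- as.integer(j)
  if (j < 1L || j > 11L) stop("reaction index must be in 1..11")
  if (propensities(state, net)[j] <= 0)
    stop(sprintf("reaction R%d cannot fire: a reactant is absent", j))
  out <- state + net$stoich[, j]
  storage.mode(out) <- "integer"
  out
}

#' Conserved quantities of the network
#'
#' Three linear combinations of counts are invariant under all 11 reactions:
#' the total alpha subunits `aGDPbg + aGTP + aGDP`, the total betagamma
#' subunits `aGDPbg + bg + Ca_off`, and the total calcium channels
#' `Ca_on + Ca_off`. For the canonical initial state these are (40, 40, 80);
#' in particular at most 40 of the 80 channels can ever be closed, bounding
#' calcium-channel inhibition at 50%.
#'
#' @inheritParams propensities
#' @param state Integer state vector of length 11.
#' @return Named numeric vector `(alpha_total, betagamma_total, channel_total)`.
#' @examples
#' conserved_quantities(initial_state())       # 40 40 80
#' conserved_quantities(initial_state(a = 5))  # unchanged
#' @export
conserved_quantities <- function(state) {
  .check_state(state)
  c(alpha_total = sum(state[c("aGDPbg", "aGTP", "aGDP")]),
    betagamma_total = sum(state[c("aGDPbg", "bg", "Ca_off")]),
    channel_total = sum(state[c("Ca_on", "Ca_off")]))
}

# Conservation-law coefficient vectors (rows) on the species ordering.
.conservation_matrix <- function() {
  sp <- mor_species()
  m <- matrix(0, 3, 11, dimnames = list(
    c("alpha_total", "betagamma_total", "channel_total"), sp))
  m["alpha_total", c("aGDPbg", "aGTP", "aGDP")] <- 1
  m["betagamma_total", c("aGDPbg", "bg", "Ca_off")] <- 1
  m["channel_total", c("Ca_on", "Ca_off")] <- 1
  m
}

#' Read rates and initial state from a key-value configuration file
#'
#' Parses a flat text file of `key = value` (or `key: value`) lines with keys
#' `k1..k11`, `a`, `L0`, `R0`, `G0`, `Ca0`; missing keys fall back to the
#' package defaults (fitted rates, canonical totals). Lines starting with `#`
#' are comments.
#'
#' @param path Path to the configuration file.
#' @return List with elements `rates` ([mor_rates()]), `a`, and `init`
#'   (the resolved [initial_state()]).
#' @export
read_mor_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  if (any(lengths(kv) != 2L)) stop("malformed configuration line")
  vals <- vapply(kv, function(p)
    suppressWarnings(as.numeric(trimws(p[2]))), numeric(1))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  if (any(is.na(vals))) stop("non-numeric configuration value")
  kd <- unclass(mor_rates())
  kk <- intersect(names(vals), names(kd))
  kd[kk] <- vals[kk]
  rates <- do.call(mor_rates, as.list(kd))
  get_or <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  a <- get_or("a", 0)
  init <- initial_state(a = a, L = get_or("L0", 10), R = get_or("R0", 20),
                        G = get_or("G0", 40), Ca = get_or("Ca0", 80))
  list(rates = rates, a = a, init = init)
}
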