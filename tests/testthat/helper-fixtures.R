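# Shared helpers: compact constructors and the worked-example compositions.

met <- function(id, smiles = NA_character_, names = NULL,
                formula = NA_character_, charge = NA_real_,
                resolution = NULL) {
  metabolite_entry(id, names = names, formula = formula, charge = charge,
                   smiles = smiles, resolution = resolution)
}

rxn <- function(eq, id = eq) parse_reaction_string(eq, id = id)

# compositions of the biotin-pathway worked example (printed formulas/charges)
dapa_compositions <- function() {
  list(atp = parse_formula("C10H12N5O13P3", charge = -4),
       ATP = parse_formula("C10H12N5O13P3", charge = -4),
       co2 = parse_formula("CO2", charge = 0),
       CO2 = parse_formula("CO2", charge = 0),
       dann = parse_formula("C9H21N2O2", charge = 1),
       DAPA = parse_formula("C9H21N2O2", charge = 1),
       adp = parse_formula("C10H12N5O10P2", charge = -3),
       ADP = parse_formula("C10H12N5O10P2", charge = -3),
       dtbt = parse_formula("C10H17N2O3", charge = -1),
       DTBIOTIN = parse_formula("C10H17N2O3", charge = -1),
       pi = parse_formula("HPO4", charge = -2),
       PI = parse_formula("HPO4", charge = -2),
       h = parse_formula("H", charge = 1))
}

# GTP cyclohydrolase I compositions
gtp_compositions <- function() {
  list(gtp = parse_formula("C10H12N5O14P3", charge = -4),
       h2o = parse_formula("H2O", charge = 0),
       ahdt = parse_formula("C9H12N5O13P3", charge = -4),
       "for" = parse_formula("CHO2", charge = -1),
       h = parse_formula("H", charge = 1))
}

# brute-force oracle for the proton/water repair: exhaustive search over
# (p, w) in [-rng, rng]^2 for integer pairs that balance the reaction,
# keeping those of minimal |p| + |w|
brute_force_repair <- function(delta_elements, delta_charge, rng = 10) {
  get <- function(e) if (e %in% names(delta_elements)) delta_elements[[e]] else 0
  others <- delta_elements[setdiff(names(delta_elements), c("H", "O"))]
  best <- NULL; best_cost <- Inf
  for (p in -rng:rng) {
    for (w in -rng:rng) {
      ok <- length(others) == 0 &&
        get("H") + p + 2 * w == 0 &&
        get("O") + w == 0 &&
        delta_charge + p == 0
      if (ok) {
        cost <- abs(p) + abs(w)
        if (cost < best_cost) { best <- list(c(p, w)); best_cost <- cost }
        else if (cost == best_cost) best <- c(best, list(c(p, w)))
      }
    }
  }
  best
}

# Random small reactions over a fixed composition alphabet. Half of the
# cases corrupt a balanced reaction's proton/water terms (a feasible repair
# exists by construction); the rest are fully random and mostly infeasible.
random_reaction_case <- function() {
  alphabet <- list(
    a = parse_formula("C6H12O6", charge = 0),
    b = parse_formula("C6H11O6", charge = -1),
    c = parse_formula("C3H4O3", charge = -1),
    d = parse_formula("C3H7O6P", charge = -2),
    e = parse_formula("CO2", charge = 0),
    f = parse_formula("C2H4O2", charge = 0),
    h = parse_formula("H", charge = 1),
    h2o = parse_formula("H2O", charge = 0))
  if (stats::runif(1) < 0.5) {
    # balanced deprotonation "a -> b + h", then corrupt h and water terms
    scale <- sample(1:2, 1)
    p <- data.frame(met = c("a", "b"), num = c(-scale, scale), den = 1,
                    stringsAsFactors = FALSE)
    h_coef <- sample(c(-2, -1, 0, 1, 2, 3), 1)     # true value: +scale
    if (h_coef != 0)
      p <- rbind(p, data.frame(met = "h", num = h_coef, den = 1))
    w_coef <- sample(c(-2, -1, 0, 1), 1)           # true value: 0
    if (w_coef != 0)
      p <- rbind(p, data.frame(met = "h2o", num = w_coef, den = 1))
  } else {
    n_l <- sample(1:3, 1); n_r <- sample(1:3, 1)
    first <- sample(setdiff(names(alphabet), c("h", "h2o")), 1)
    mets <- c(first, sample(setdiff(names(alphabet), first), n_l + n_r - 1))
    p <- data.frame(met = mets,
                    num = c(-sample(1:3, n_l, TRUE), sample(1:3, n_r, TRUE)),
                    den = 1, stringsAsFactors = FALSE)
  }
  list(reaction = reaction_entry("rnd", p), comp = alphabet)
}
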