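# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths they verify.

# Faith's PD by explicit path enumeration: union of the edges on each
# present tip's path to the root, summed.
oracle_faith_pd <- function(tree, present) {
  root <- ape::Ntip(tree) + 1L
  edges <- integer(0)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- union(edges, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges])
}

# Pearson r by the explicit product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Shannon index by the bare definition.
oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

default_chain <- function() reactor_chain(c(AC = 500, TC = 800, DC = 600))
default_schedule <- function() feeding_schedule(140)
default_dose <- function(cells = 2.5e10) dose_event("AC", cells)

# Small synthetic scenario for fast pipeline tests.
small_synth_config <- function(seed = 7) {
  synth_config(seed = seed, n_taxa = 20, depth = 2000,
               samples_per_group = 2)
}
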