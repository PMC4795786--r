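## Shared fixtures for the test suite. Everything is built in code.

## a ParameterSet with a single nonzero constant
soloParams <- function(name, value) {
  k <- stats::setNames(numeric(13), paste0("k", 1:13))
  k[name] <- value
  ParameterSet(k)
}

## fabricate a SimulationResult carrying an arbitrary cGMP trajectory on a
## uniform grid (for quadrature tests)
fakeCgmpResult <- function(time, cgmp) {
  traj <- matrix(0, nrow = length(time), ncol = 12,
                 dimnames = list(NULL, speciesNames()))
  traj[, "cGMP"] <- cgmp
  init <- InitialState(stats::setNames(traj[1L, ], speciesNames()))
  methods::new("SimulationResult", time = time, trajectory = traj,
               params = defaultParameters(), init = init,
               solver = list(method = "none", rtol = NA_real_,
                             atol = NA_real_))
}

## closed-form [A](t) for the irreversible bimolecular reaction A + B -> C
## with unequal initial amounts a0 != b0
bimolecularA <- function(t, a0, b0, k) {
  d <- a0 - b0
  a0 * d / (a0 - b0 * exp(-k * d * t))
}

## independent enumeration oracle: count subsets of {1..q} with 1..m members
## via bitmasks (deliberately different from the implementation's combn path)
bitmaskSubsets <- function(q, m) {
  out <- list()
  for (mask in seq_len(2^q - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(q) - 1L)) > 0L)
    if (length(members) <= m) out[[length(out) + 1L]] <- members
  }
  out
}

## moiety sums for conservation checks
moietySums <- function(res) {
  tr <- trajectory(res)
  list(
    sgc = rowSums(tr[, c("sGC", "sGC_H2O2", "NO_sGC", "sGC_GTP",
                         "NO_sGC_GTP")]),
    nucleotide = rowSums(tr[, c("GTP", "sGC_GTP", "NO_sGC_GTP", "cGMP",
                                "cGMP_PDE", "GMP")]),
    pde = rowSums(tr[, c("PDE", "cGMP_PDE")]))
}

relDrift <- function(x) (max(x) - min(x)) / max(abs(x[1L]), .Machine$double.eps)
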