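# shared helpers for the suite

# coarse ground-truth class used for gating comparisons
coarse_truth <- function(cls) {
  ifelse(cls == "empty", "empty",
         ifelse(cls %in% c("single", "permeabilized"), "single", "multi"))
}

# independent Poisson pmf oracle: direct series evaluation
pmf_oracle <- function(k, lam) lam^k * exp(-lam) / factorial(k)

# midpoint gates for the default amplitude table (noise-free traces)
table_gates <- function(target = "single") {
  tab <- default_amplitude_table()
  gate_config(lower_uA = (tab[["empty"]] + tab[["single"]]) / 2,
              upper_uA = (tab[["single"]] + tab[["multi2"]]) / 2,
              target_classes = target)
}

# small deterministic stream with regular arrivals
quick_stream <- function(n = 200, lam = 0.5, seed = 11, cv = 0.03) {
  sample_stream(encapsulation_params(lam = lam, arrival = "regular",
                                     diameter_cv = cv), n, seed = seed)
}

# complete elliptic integral of the first kind (modulus k), by quadrature
ellipK <- function(k) {
  stats::integrate(function(t) 1 / sqrt(1 - k^2 * sin(t)^2), 0, pi / 2,
                   rel.tol = 1e-10)$value
}
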