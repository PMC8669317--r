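# Shared helpers: independent brute-force oracles kept deliberately
# separate from the package's own solution paths.

# Age-classified expansion of the three-stage model: sub-adult ages
# 1..T each surviving at s1, the last age maturing into the breeding
# stage, plus breeding/non-breeding adult stages. Its dominant eigenvalue
# is the reference for the collapsed stage model.
age_classified_lambda <- function(v, T = v$AFR - 1) {
  n <- T + 2
  M <- matrix(0, n, n)
  M[1, T + 1] <- (v$e / 2) * v$h * v$f * v$s0
  if (T > 1) for (j in 1:(T - 1)) M[j + 1, j] <- v$s1
  M[T + 1, T] <- v$s1
  M[T + 1, T + 1] <- v$s2 * v$b
  M[T + 1, T + 2] <- v$s3 * v$b
  M[T + 2, T + 1] <- v$s2 * (1 - v$b)
  M[T + 2, T + 2] <- v$s3 * (1 - v$b)
  max(Re(eigen(M, only.values = TRUE)$values))
}

# reference vital rates used across tests
test_vitals <- function() {
  vital_rates(s0 = 0.6, s1 = 0.8, s2 = 0.92, s3 = 0.9,
              b = 0.85, e = 2, h = 0.75, f = 0.7, AFR = 4)
}

# three-island geometry with moderate separations
test_geometry <- function() {
  colony_geometry(distances = matrix(c(0, 120, 300,
                                       120, 0, 200,
                                       300, 200, 0), 3))
}

# fully deterministic stochasticity settings
det_config <- function() {
  stochasticity_config(sigma_e = c(s0 = 0, s1 = 0, s2 = 0, s3 = 0,
                                   b = 0, h = 0, f = 0),
                       demographic_threshold = 0)
}
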