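# Shared fixtures and small numerical helpers for the suite.

# Baseline channel-scale parameter set used throughout the profile and
# streamline checks (moderate leakage, mildly viscoelastic).
channel_groups <- function(p_i = 3, K = 0.16, A = 1, lambda1 = 0.1,
                           lambda2 = 0.03) {
  dimensionless_groups(p_i = p_i, K = K, A = A, lambda1 = lambda1,
                       lambda2 = lambda2)
}

# Dimensional spec of the bundled flat-plate dialyzer fixture.
rp_spec <- function() {
  as_dimensional_spec(read_flow_config(rp_kidney_config()))
}

rp_groups <- function(K = NA_real_) {
  g <- to_dimensionless(rp_spec(), allow_missing_permeability = TRUE)
  if (!is.na(K)) {
    g$K <- K
    g$xi <- xi_parameter(K, g$lambda1)
  }
  g
}

# central first difference
fd1 <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
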