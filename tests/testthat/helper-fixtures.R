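# shared fixture builders; all data are generated in code at test time

cont_spec <- function(id = "trait", cov = "none")
  trait_spec(id, "continuous", covariate_kind = cov)

bin_spec <- function(id = "trait", K = 2, cov = "none")
  trait_spec(id, "ordinal", n_categories = K, covariate_kind = cov)

null_cfg <- function(n = 500, seed = 1, ...)
  generative_config(n_pairs_per_group = c(MZM = n, MZF = n, DZM = n,
                                          DZF = n, DOS = n),
                    seed = seed, ...)

# slow-but-simple bivariate normal CDF via one-dimensional reduction;
# independent of the package's quadrature implementation
bvn_cdf_oracle <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  integrate(function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
            -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}
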