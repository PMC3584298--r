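# random exponential chains with well-separated decline rates, for
# closed-form vs numeric-oracle property tests
random_chain <- function(n_stores = 2L) {
  repeat {
    a <- sort(stats::runif(n_stores, 0.01, 2), decreasing = TRUE)
    if (n_stores == 1L || min(abs(diff(a))) > 1e-3) break
  }
  chain_params(mu = c(stats::runif(1, 0.2, 5),
                      stats::runif(n_stores - 1L, 0.001, 1)),
               a = a)
}

# a standard two-store configuration used across many tests
demo_chain <- function() chain_params(mu = c(2, 0.1), a = c(0.3, 0))

cho_chain <- function() chain_params(mu = c(1.5, 0.00325), a = c(0.103, 0))

full_lesion <- function() lesion_profile(lambda = c(1, 0))
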