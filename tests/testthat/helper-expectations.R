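# relative-tolerance comparison against a reference value
expect_rel <- function(object, expected, tol) {
  expect_true(abs(object / expected - 1) < tol,
              label = sprintf("%.6g vs %.6g (rel diff %.3g, tol %.3g)",
                              object, expected, abs(object / expected - 1),
                              tol))
}

# strain grid covering all regimes of the default parameterisation
strain_grid <- function(eps_max = 0.6, n = 241) seq(0, eps_max, length.out = n)
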