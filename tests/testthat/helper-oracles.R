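# closed-form oracle for the n = 1 simple-loop steady state:
# beta1*X*(1 + (lambda2*X/(beta2*k))) = lambda1 is a quadratic in X
closed_x_quadratic <- function(lambda1, lambda2, beta1, beta2, k) {
  a <- beta1 * lambda2 / (beta2 * k)
  (-beta1 + sqrt(beta1^2 + 4 * a * lambda1)) / (2 * a)
}

# random positive parameter set drawn on log scales
random_simple_params <- function() {
  circuit_params(lambda1 = 10^stats::runif(1, -2, 2),
                 lambda2 = 10^stats::runif(1, -2, 2),
                 beta1 = 10^stats::runif(1, -1, 1),
                 beta2 = 10^stats::runif(1, -1, 1),
                 k = 10^stats::runif(1, -4, 2),
                 n = 1)
}
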