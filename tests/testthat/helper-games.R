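# Shared fixtures: canonical parameterizations and a generator of random
# affine two-strategy population games for the evolutionary-stability
# property tests.

baseline_game <- function(phi = 0.5) prescribing_game(phi = phi)

residual_game <- function(phi = 0.5, lambda = 0.2)
  prescribing_game(phi = phi, variant = "residual_lambda", lambda = lambda)

crossing_game <- function(phi = 0.5, q_prime = 0.5, cost = 0.05)
  prescribing_game(phi = phi, variant = "crossing", q_prime = q_prime,
                   side_effect_cost = cost)

scaled_game <- function(phi = 0.5, k = 0.4)
  prescribing_game(phi = phi, variant = "scaled_k", k = k)

# a random game with affine pure-strategy payoff curves on q in [0, 1]
rand_affine_game <- function() {
  cf <- runif(4, -1, 1)
  list(piT = function(q) cf[1] + cf[2] * q,
       piU = function(q) cf[3] + cf[4] * q,
       coef = cf)
}

# brute-force argmax of f over a fine grid; returns the grid argmax
grid_argmax <- function(f, step = 1e-6) {
  qs <- seq(0, 1, by = step)
  qs[which.max(f(qs))]
}
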