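# Small model builders shared across the suite.

# one-cell immigration-death model: constant gain c, population l
id_model <- function(l = 50, c = 0.5, tau = 1) {
  p <- uniform_partition(domain(), 1L, l)
  micro_model(p, tau, gain_constant(c), kernel_constant(1))
}

# small sigmoid model on n cells
sigmoid_model <- function(n = 4, l = 50, tau = 1,
                          input = input_constant(0.3),
                          rate_scheme = "unbounded") {
  p <- uniform_partition(domain(), n, l)
  micro_model(p, tau, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
              input, rate_scheme = rate_scheme)
}

# affine model whose clip never activates on visited states
affine_model <- function(n = 4, l = 100, tau = 1) {
  p <- uniform_partition(domain(), n, l)
  micro_model(p, tau, gain_affine(0.4, 0.3, 1), kernel_constant(0.5))
}

# grid field from a function on a default composite Gauss grid
fn_grid_field <- function(f, panels = 8, q = 6, dom = domain()) {
  g <- gauss_grid(dom, panels, q)
  grid_field(g$nodes, g$weights, f(g$nodes[, 1]), dom)
}
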