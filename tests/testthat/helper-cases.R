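# Shared fixtures: small meshes and output grids keep unit tests fast;
# the acceptance suite uses >= 500 nodes.

quick_mesh <- function(n = 300L) release_mesh(n)

quick_opts <- function(params, n_out = 150L, span = c(1e-4, 10), ...) {
  solver_options(output_tau = default_output_grid(params, n_out = n_out,
                                                  span = span), ...)
}

solve_quick <- function(K, G, n, mesh_n = 300L, n_out = 150L,
                        span = c(1e-4, 10)) {
  p <- dimensionless_params(K, G, n)
  solve_release(p, quick_mesh(mesh_n), quick_opts(p, n_out, span))
}
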