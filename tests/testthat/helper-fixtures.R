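# shared fixtures, computed lazily and cached for the session
fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, build) {
  if (is.null(fixtures[[name]])) fixtures[[name]] <- build()
  fixtures[[name]]
}

bone <- function() fix_get("bone", poroelastic_material)

# small standard trabecula solve under pure compression at F_target
compression_solve <- function() {
  fix_get("compression_solve", function() {
    mat <- poroelastic_material()
    g <- build_initial_trabecula()
    mesh <- generate_mesh(g, h = 0.04, h_plate = 0.125)
    pulse <- load_pulse(f_target(mat), theta = pi)
    list(geometry = g, mesh = mesh, pulse = pulse, material = mat,
         result = solve_transient(mesh, mat, pulse, standard_bcs(mesh, pulse)))
  })
}

# fabricate a transient result carrying prescribed flux-magnitude histories
# on a grid of element centroids (for the velocity-statistic oracles)
synthetic_result <- function(centroids, qmag) {
  structure(list(centroids = centroids, qmag = qmag), class = "transient_result")
}
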