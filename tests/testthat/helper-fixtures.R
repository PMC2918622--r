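# Small shared fixtures, built in code at test time.

# coarse straight tube with an analytic Poiseuille solution
tube_mesh_small <- function(ni = 60, nj = 10, radius = 0.01, length = 0.15)
  generate_mesh(tube_geometry(radius, length), ni, nj)

# default aneurysm on a coarse grid (fast)
aneurysm_mesh_small <- function(ni = 48, nj = 14)
  generate_mesh(aneurysm_geometry(), ni, nj)

# memoised coarse flow solutions shared across test files
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tube_flow_small <- function() cached("tube_flow", {
  m <- tube_mesh_small()
  list(mesh = m,
       flow = solve_steady_flow(m, bcs = flow_bcs(reynolds = 100),
                                tol = 1e-6))
})

aneurysm_flow_small <- function() cached("aneurysm_flow", {
  m <- aneurysm_mesh_small()
  list(mesh = m,
       flow = solve_steady_flow(m, bcs = flow_bcs(reynolds = 800),
                                tol = 1e-3))
})
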