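# Shared fixtures, built in code. The small phantom halves the default
# brain in every dimension (32 x 32 x 24 voxels at 0.1 mm) so that forward
# solves take well under a second; geometry and tissue parameters otherwise
# match the defaults.

small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 24),
               brain_semi_axes = c(1.45, 1.45, 1.05), ...)
}

small_ground_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom(small_phantom_spec())
    cache
  }
})

# simulated small phantom at the Table-1 truth, cached across tests
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_truth(small_ground_truth(), transport_params())
    cache
  }
})

# uniform box domain: every voxel in the mask, one subdomain (BT)
box_mesh <- function(dims = c(16, 16, 16), voxel_size = 0.1, factor = 1L) {
  mask <- array(TRUE, dims)
  mesh <- build_mesh(mask, voxel_size, factor = factor)
  labels <- subdomain_labels(array(label_codes()[["BT"]], dims), voxel_size)
  tag_subdomains(mesh, labels)
}
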