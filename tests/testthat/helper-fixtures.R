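# Shared fixtures: renders are deterministic but not cheap, so cache them
# for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full small phantom, XVI-like 1 mm grid, 3 slices per module
fix_ideal_1mm <- function() fixture("ideal_1mm",
  render_ideal_volume(catphan_phantom(), c(1, 1, 1), slices_per_module = 3))

# uniformity module only, 1 mm grid, 3 slices
fix_ctp486_1mm <- function() fixture("ctp486_1mm",
  render_ideal_volume(catphan_phantom("CTP486"), c(1, 1, 1),
                      slices_per_module = 3))

# sensitometry module only, 1 mm grid, 3 slices
fix_ctp404_1mm <- function() fixture("ctp404_1mm",
  render_ideal_volume(catphan_phantom("CTP404"), c(1, 1, 1),
                      slices_per_module = 3))

# a tiny uniform qa_volume for hand-built scenarios
flat_volume <- function(value = 0, n = 40, nz = 1, voxel = 1) {
  qa_volume(array(value, c(n, n, nz)), voxel_size = c(voxel, voxel, 1),
            origin = c(-(n - 1) / 2 * voxel, -(n - 1) / 2 * voxel))
}

python_bin <- Sys.which("python")
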