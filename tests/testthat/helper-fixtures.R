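# Shared fixtures, built once per test session. Everything is generated in
# code from the package's own synthetic-data module; nothing is stored on
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# a straight default-symmetry filament long enough for n_seg segments
segment_model <- function(n_seg, spacing = 42.5, box = 110L, px = 3.44,
                          params = vif_params(), npf = 5L) {
  need <- (n_seg - 1L) * spacing + box * px + 120
  build_filament_model(params = params,
                       n_tetramers = ceiling(need / params$rise),
                       n_protofibrils = npf)
}

# noiseless long projection of a filament with the given symmetry and its
# power spectrum (tall box -> sharp layer lines)
long_spectrum <- function(params, ny = 512L, px = 3.44) {
  m <- build_filament_model(params = params,
                            n_tetramers = ceiling((ny * px + 300) /
                                                    params$rise))
  img <- project_model(m, 110L, ny, px, thickness = 220)
  average_power_spectrum(array(img, c(dim(img), 1L)), pixel_size = px)
}

# density map of the default filament plus central rise-spaced sections
central_sections <- function(n_sections = 50L, px = 3.44,
                             spacing = 8.84) {
  m <- build_filament_model(n_tetramers = 25L)
  map <- render_density_map(m, voxel_size = px, box = c(64L, 64L, 500L))
  zc <- dim(map$grid)[3] * px / 2
  pos <- zc + (seq_len(n_sections) - n_sections / 2) * spacing
  extract_cross_sections(map, thickness = 8.84, size_A = 180,
                         positions = pos)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
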