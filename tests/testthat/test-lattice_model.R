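# The tetramer template, lattice assembly, cross-section stoichiometry and
# the geometric queries.

test_that("the tetramer template realizes the A11 architecture", {
  tet <- build_tetramer()
  expect_equal(length(unique(tet$chain)), 4L)
  # two antiparallel dimers: orientation flags sum to zero
  ori <- tapply(tet$orientation, tet$chain, unique)
  expect_equal(sum(ori), 0)
  # CTE-to-CTE span 650 A (coil2 terminal beads at +-325)
  c2 <- tet[tet$domain == "coil2_2A2B", ]
  expect_equal(diff(range(c2$z)), 650)
  # NTE tips 290 A apart in pairs
  nte <- tet[tet$domain == "coil1_nte", ]
  tips <- as.numeric(tapply(abs(nte$z), nte$chain, max))
  expect_equal(tips, rep(145, 4))
  # every chain carries one full monomer of mass
  expect_equal(sum(tet$mass), 4 * vimentin_monomer_mass(), tolerance = 1e-9)
  expect_equal(as.integer(tapply(tet$nres, tet$chain, sum)), rep(466L, 4L))
  # luminal head beads stay within the 10 A lumen radius
  hd <- tet[tet$domain == "head", ]
  expect_true(all(sqrt(hd$x^2 + hd$y^2) <= 10))
})

test_that("geometry and domain validation reject inconsistent inputs", {
  expect_error(tetramer_geometry(cte_span = 300), "exceed")
  expect_error(tetramer_geometry(cte_span = 200, nte_pair_separation = 290),
               "exceed")
  expect_error(domain_map(coil1_1A1B = c(90L, 253L)), "contiguous")
  expect_error(domain_map(conserved_1A = c(80L, 125L)), "nested")
})

test_that("assembled lattices obey the symmetry bookkeeping", {
  p <- vif_params()
  m <- assemble_filament(8, p)
  b0 <- m$beads[m$beads$tetramer == 0, c("x", "y", "z")]
  for (k in c(1, 4, 7)) {
    bk <- m$beads[m$beads$tetramer == k, c("x", "y", "z")]
    expect_equal(as.matrix(bk), apply_operator(as.matrix(b0), p, k),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
  expect_equal(m$beads$protofibril, m$beads$tetramer %% 5L)
  # successive tetramers of one protofibril sit n_protofibrils * rise apart
  z0 <- tapply(m$beads$z[m$beads$protofibril == 0],
               m$beads$tetramer[m$beads$protofibril == 0], mean)
  expect_equal(unname(diff(z0)), 5 * p$rise, tolerance = 1e-9)
})

test_that("cross-section chain counts follow the assembly pathway", {
  # single tetramer: 4 rod chains at the center
  m1 <- assemble_filament(1, protofibril_params(), n_protofibrils = 1)
  expect_equal(cross_section_chain_count(m1, 0)$count, 4L)
  # two tetramers of one protofibril: 6 chains in the overlap
  m2 <- assemble_filament(2, protofibril_params(), n_protofibrils = 1)
  expect_equal(cross_section_chain_count(m2, 50)$count, 6L)
  # three tetramers: the full octameric repeating unit in the center
  m3 <- assemble_filament(3, protofibril_params(), n_protofibrils = 1)
  expect_equal(cross_section_chain_count(m3, 212.5)$count, 8L)
  # full filament: 40 chains, 8 per protofibril
  m15 <- assemble_filament(15)
  cc <- cross_section_chain_count(m15, mean(range(m15$beads$z)))
  expect_equal(cc$count, 40L)
  expect_equal(unname(cc$by_protofibril), rep(8L, 5L))
  expect_error(cross_section_chain_count(m15, 1e5), "outside")
})

test_that("40 chains is the plateau and never exceeded", {
  m <- assemble_filament(20)
  zs <- vifhelix:::chain_count_breaks(m)
  counts <- vapply(zs, function(z) cross_section_chain_count(m, z)$count,
                   integer(1))
  expect_lte(max(counts), 40L)
  expect_equal(max(counts), 40L)
  # the plateau is contiguous: every z between the first and last 40 is 40
  at40 <- which(counts == 40L)
  expect_true(all(counts[min(at40):max(at40)] == 40L))
})

test_that("minimal tetramer counts match the assembly rules", {
  expect_equal(minimal_tetramer_count("full_filament"), 15L)
  expect_equal(minimal_tetramer_count("protofibril_repeat"), 3L)
  expect_equal(minimal_tetramer_count("unit_length"), 5L)
  expect_error(minimal_tetramer_count("bogus"))
})

test_that("the geometry report reproduces the filament architecture", {
  m15 <- assemble_filament(15)
  r <- geometry_report(m15)
  # interlock sites repeat every 5 x rise = 212.5 A (~21 nm) along a
  # protofibril, a pure symmetry consequence
  expect_equal(r$interlock_spacing_A, 212.5, tolerance = 1e-6)
  expect_equal(round(r$interlock_spacing_nm), 21)
  # NTE pair reaches 32.5 A past the predecessor CTE (printed range 30-40)
  expect_equal(r$a_cn_overlap_A, 32.5, tolerance = 1e-6)
  expect_gt(r$a_cn_overlap_A, 30)
  expect_lt(r$a_cn_overlap_A, 40)
  # ~11 nm outer diameter, ~50.5 kDa/nm
  expect_rel_equal(r$outer_diameter_A, 110, 0.05)
  expect_rel_equal(r$mass_per_length_kda_nm, 50.5, 0.005)
  # interlock spacing is independent of the tetramer geometry details
  g2 <- tetramer_geometry(coil2_length = 200, coil1_length = 215)
  r2 <- geometry_report(assemble_filament(15, geometry = g2))
  expect_equal(r2$interlock_spacing_A, 212.5, tolerance = 0.05)
})

test_that("model extents match the assembly sizes", {
  # 3-tetramer minimal protofibril: 650 + 2 x 212.5 = 1075 A between CTEs
  r3 <- geometry_report(assemble_filament(3, protofibril_params(),
                                          n_protofibrils = 1))
  expect_equal(r3$cte_extent_A, 1075)
  expect_equal(round(r3$cte_extent_nm / 10) * 10, 110)
  # 30 tetramers -> ~190 nm, 5 tetramers (unit length) -> ~82 nm
  expect_rel_equal(geometry_report(assemble_filament(30))$axial_extent_nm,
                   190, 0.03)
  expect_rel_equal(geometry_report(assemble_filament(5))$axial_extent_nm,
                   82, 0.03)
  # mass per length does not change with filament length
  expect_equal(geometry_report(assemble_filament(10))$mass_per_length_kda_nm,
               geometry_report(assemble_filament(25))$mass_per_length_kda_nm)
})

test_that("PDB export round trips beads at PDB precision", {
  m <- assemble_filament(5)
  f <- file.path(tempdir(), "m5.pdb")
  export_model(m, f, "pdb")
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), nrow(m$beads))
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(xyz - as.matrix(m$beads[, c("x", "y", "z")]))), 0.001)
  # > 62 chains split across numbered files with a manifest
  m16 <- assemble_filament(16)
  fs <- export_model(m16, file.path(tempdir(), "m16.pdb"), "pdb")
  expect_length(fs, 3L)
  expect_true(any(grepl("manifest", fs)))
  man <- utils::read.csv(fs[grepl("manifest", fs)])
  n_at <- sum(vapply(man$file, function(p)
    nrow(bio3d::read.pdb(p)$atom), integer(1)))
  expect_equal(n_at, nrow(m16$beads))
})

test_that("MRC export renders a five-protofibril cross-section", {
  m <- assemble_filament(15)
  f <- file.path(tempdir(), "m15.mrc")
  export_model(m, f, "mrc")
  map <- read_mrc(f)
  expect_equal(map$voxel_size, 3.44, tolerance = 1e-6)
  zc <- dim(map$grid)[3] * map$voxel_size / 2
  xs <- extract_cross_sections(map, thickness = 42.5, size_A = 140,
                               positions = zc)
  cnt <- count_protofibrils(xs$sections[, , 1], map$voxel_size)
  expect_equal(cnt$count, 5L)
})
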