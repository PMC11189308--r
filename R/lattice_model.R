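# Tetramer -> protofibril -> filament lattice model.
#
# The asymmetric unit of the filament is the A11 tetramer: two antiparallel,
# axially staggered coiled-coil dimers with their 1B domains aligned. Each
# dimer contributes two rod chains; a chain is represented as a string of
# beads running CTE (2B end) -> rod -> NTE (1A end), with the low-complexity
# head continuing into the filament lumen and the tail sitting at the 2A-2B
# CTE where it bridges to the neighbouring protofibril. Applying the helical
# symmetry operator k times to the template tetramer and assigning tetramer
# k to protofibril k mod n_protofibrils yields the filament: successive
# tetramers of one protofibril are then automatically offset by
# n_protofibrils * rise and build the octameric (8 alpha-helix) repeating
# unit whose cross-section stoichiometry the queries below report.

#' Vimentin domain map
#'
#' Residue intervals of the vimentin domains on the 466-residue chain:
#' intrinsically disordered head, the 1A-1B coiled-coil region, the L12
#' linker, the 2A-2B region and the disordered tail, plus the highly
#' conserved 1A and 2B sub-intervals that form the interlock between
#' successive tetramers of a protofibril.
#'
#' @param head,coil1_1A1B,linker_L12,coil2_2A2B,tail integer length-2
#'   residue intervals; they must be contiguous and cover 1..466.
#' @param conserved_1A,conserved_2B conserved sub-intervals, nested inside
#'   the 1A-1B and 2A-2B intervals respectively.
#' @return A list of class `domain_map`.
#' @export
domain_map <- function(head = c(1L, 85L), coil1_1A1B = c(86L, 253L),
                       linker_L12 = c(254L, 264L), coil2_2A2B = c(265L, 411L),
                       tail = c(412L, 466L), conserved_1A = c(100L, 125L),
                       conserved_2B = c(380L, 411L)) {
  iv <- list(head = head, coil1_1A1B = coil1_1A1B, linker_L12 = linker_L12,
             coil2_2A2B = coil2_2A2B, tail = tail)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || v[1] > v[2]) stop("bad interval for ", nm)
  }
  ord <- do.call(rbind, iv)
  if (ord[1, 1] != 1L) stop("domain map must start at residue 1")
  for (i in 2:nrow(ord))
    if (ord[i, 1] != ord[i - 1, 2] + 1L)
      stop("domain intervals must be contiguous and non-overlapping")
  n_res <- ord[nrow(ord), 2]
  nested <- function(inner, outer) inner[1] >= outer[1] && inner[2] <= outer[2]
  if (!nested(conserved_1A, coil1_1A1B))
    stop("conserved_1A must be nested inside coil1_1A1B")
  if (!nested(conserved_2B, coil2_2A2B))
    stop("conserved_2B must be nested inside coil2_2A2B")
  d <- c(iv, list(conserved_1A = conserved_1A, conserved_2B = conserved_2B,
                  n_res = n_res))
  class(d) <- "domain_map"
  d
}

#' Tetramer geometry
#'
#' Calibration constants of the coarse-grained A11 tetramer, all in
#' Angstrom. The defaults reproduce the measured tetramer architecture: a
#' ~65 nm CTE-to-CTE extent, 1A-1B NTEs protruding toward the lumen ~29 nm
#' apart in pairs, ~21 nm 2A-2B bundles, and a bead envelope reaching the
#' 55 A filament radius (11 nm final diameter). The axial core of each rod
#' chain spans coil1 + L12 + coil2 = 425 A, i.e. exactly two protofibril
#' periods of 5 x 42.5 A, which is what makes the protofibril cross-section
#' octameric.
#'
#' @param cte_span axial extent between the CTEs of the two flanking 2A-2B
#'   dimers (default 650).
#' @param nte_pair_separation axial distance between the paired 1A-1B NTE
#'   tips (default 290).
#' @param coil2_length axial extent of each 2A-2B bundle (default 210).
#' @param coil1_length,linker_length axial extents of the 1A-1B rod section
#'   and the L12 linker (defaults 205 and 10).
#' @param protofibril_center_radius radial position of a protofibril center
#'   (default 38); the 1A-1B and 2A-2B bundles sit at this radius -/+
#'   `coil_radius_offset`.
#' @param filament_radius nominal outer filament radius (default 55).
#' @param coil_radius_offset radial half-separation between the inner
#'   (1A-1B) and outer (2A-2B) bundles (default 10).
#' @param dimer_angle azimuthal half-angle between the two dimers of a
#'   tetramer, degrees (default 8).
#' @param chain_radial_offset radial half-separation of the two chains of a
#'   dimer (default 2.5).
#' @param luminal_radius radius of the head-domain (luminal fiber) bead
#'   string (default 8, i.e. within the <= 10 A lumen).
#' @param head_length axial extent of each head bead string (default 60).
#' @param beads_per_chain rod beads per chain across coil1 + linker + coil2
#'   (default 41, ~10.5 A spacing).
#' @param bead_sigma Gaussian radius of one bead for rendering (default 4).
#' @return A list of class `tetramer_geometry`.
#' @export
tetramer_geometry <- function(cte_span = 650, nte_pair_separation = 290,
                              coil2_length = 210, coil1_length = 205,
                              linker_length = 10,
                              protofibril_center_radius = 38,
                              filament_radius = 55, coil_radius_offset = 10,
                              dimer_angle = 8, chain_radial_offset = 2.5,
                              luminal_radius = 8, head_length = 60,
                              beads_per_chain = 41L, bead_sigma = 4) {
  g <- list(cte_span = cte_span, nte_pair_separation = nte_pair_separation,
            coil2_length = coil2_length, coil1_length = coil1_length,
            linker_length = linker_length,
            protofibril_center_radius = protofibril_center_radius,
            filament_radius = filament_radius,
            coil_radius_offset = coil_radius_offset,
            dimer_angle = dimer_angle,
            chain_radial_offset = chain_radial_offset,
            luminal_radius = luminal_radius, head_length = head_length,
            beads_per_chain = as.integer(beads_per_chain),
            bead_sigma = bead_sigma)
  lens <- unlist(g[c("cte_span", "nte_pair_separation", "coil2_length",
                     "coil1_length", "linker_length",
                     "protofibril_center_radius", "filament_radius",
                     "luminal_radius", "head_length", "bead_sigma")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all tetramer geometry lengths must be positive")
  if (cte_span <= nte_pair_separation)
    stop("cte_span must exceed nte_pair_separation")
  g$rod_span <- coil1_length + linker_length + coil2_length
  if (g$rod_span > cte_span)
    stop("domain lengths exceed the CTE-to-CTE span: coil1 + L12 + coil2 = ",
         g$rod_span, " > ", cte_span)
  if (nte_pair_separation / 2 <= cte_span / 2 - g$rod_span + coil2_length)
    stop("NTE tips would fall inside the opposing 2A-2B bundle")
  if (g$beads_per_chain < 5L) stop("beads_per_chain must be at least 5")
  class(g) <- "tetramer_geometry"
  g
}

# residue counts per bead for a run of `res` residues over `nb` beads
split_residues <- function(res_from, res_to, nb) {
  n <- abs(res_to - res_from) + 1L
  cuts <- round(seq(0, n, length.out = nb + 1L))
  counts <- diff(cuts)
  mids <- res_from + sign(res_to - res_from) * round((cuts[-1] + cuts[-(nb + 1)]) / 2)
  list(counts = counts, resno = pmin(pmax(mids, min(res_from, res_to)),
                                     max(res_from, res_to)))
}

# One rod chain plus its head/tail annotations. orientation +1: CTE at
# z = -cte_span/2, NTE tip at +nte_pair_separation/2; orientation -1 is the
# z-mirror. Coordinates are cylindrical -> Cartesian about the filament
# axis; `azimuth` in degrees.
build_chain <- function(geometry, domains, orientation, azimuth, radial_off,
                        tail_azimuth) {
  g <- geometry
  half <- g$cte_span / 2
  tip <- g$nte_pair_separation / 2
  r_coil1 <- g$protofibril_center_radius - g$coil_radius_offset + radial_off
  r_coil2 <- g$protofibril_center_radius + g$coil_radius_offset + radial_off
  nb <- g$beads_per_chain - 1L
  n_coil2 <- max(2L, round(nb * g$coil2_length /
                             (g$coil1_length + g$coil2_length)))
  n_coil1 <- nb - n_coil2
  # residue spans derived from the domain map: the NTE protrusion is the
  # start of coil1 up to the conserved 1A box
  cte_res <- domains$coil2_2A2B[2]
  nte_res_hi <- domains$conserved_1A[1] - 1L
  seg <- function(domain, z, r, az, res_from, res_to, nb_, rod) {
    rs <- split_residues(res_from, res_to, nb_)
    data.frame(z = z, r = r, az = az, domain = domain, resno = rs$resno,
               nres = rs$counts, rod = rod)
  }
  z2 <- seq(-half, -half + g$coil2_length, length.out = n_coil2)
  coil2 <- seg("coil2_2A2B", z2, r_coil2, azimuth,
               cte_res, domains$coil2_2A2B[1], n_coil2, TRUE)
  zl <- -half + g$coil2_length + g$linker_length / 2
  linker <- seg("linker_L12", zl, (r_coil1 + r_coil2) / 2, azimuth,
                domains$linker_L12[2], domains$linker_L12[1], 1L, TRUE)
  z1 <- seq(-half + g$coil2_length + g$linker_length,
            -half + g$rod_span, length.out = n_coil1)
  coil1 <- seg("coil1_1A1B", z1, r_coil1, azimuth,
               domains$coil1_1A1B[2], domains$conserved_1A[1], n_coil1, TRUE)
  n_nte <- 4L
  znte <- seq(-half + g$rod_span, tip, length.out = n_nte + 1L)[-1L]
  rnte <- seq(r_coil1, g$luminal_radius + 4, length.out = n_nte + 1L)[-1L]
  nte <- seg("coil1_nte", znte, rnte, azimuth,
             nte_res_hi, domains$coil1_1A1B[1], n_nte, FALSE)
  n_head <- 6L
  zh <- seq(tip - 6, tip - g$head_length, length.out = n_head)
  head <- seg("head", zh, g$luminal_radius, azimuth,
              domains$head[2], domains$head[1], n_head, FALSE)
  n_tail <- 3L
  taz <- seq(azimuth, tail_azimuth, length.out = n_tail + 1L)[-1L]
  tail <- seg("tail", -half, g$protofibril_center_radius +
                g$coil_radius_offset + 2, taz,
              domains$tail[1], domains$tail[2], n_tail, FALSE)
  ch <- rbind(coil2, linker, coil1, nte, head, tail)
  if (orientation < 0) ch$z <- -ch$z
  ch$orientation <- orientation
  ch
}

#' Build the coarse-grained A11 tetramer template
#'
#' Places four rod chains as two antiparallel dimers with aligned 1B
#' domains: the 2A-2B bundles flank the assembly at the CTE ends, the
#' 1A-1B section occupies the center at smaller radius, the 1A NTEs
#' protrude toward the lumen where the head beads continue as the luminal
#' fiber, and the tail beads sit at the 2A-2B CTEs directed toward the
#' neighbouring protofibril. Per-bead masses are proportional to the
#' residues each bead represents (monomer total 53.652 kDa).
#'
#' @param geometry a [tetramer_geometry()].
#' @param domains a [domain_map()].
#' @return A data.frame of beads with columns x, y, z (Angstrom), chain
#'   (1..4), domain, resno, nres, mass (kDa), rod (logical), orientation.
#' @export
build_tetramer <- function(geometry = tetramer_geometry(),
                           domains = domain_map()) {
  stopifnot(inherits(geometry, "tetramer_geometry"),
            inherits(domains, "domain_map"))
  a <- geometry$dimer_angle
  dr <- geometry$chain_radial_offset
  layout <- list(list(+1, -a, -dr, -36), list(+1, -a, +dr, -36),
               list(-1, +a, -dr, +36), list(-1, +a, +dr, +36))
  chains <- lapply(seq_along(layout), function(i) {
    s <- layout[[i]]
    ch <- build_chain(geometry, domains, s[[1]], s[[2]], s[[3]], s[[4]])
    ch$chain <- i
    ch
  })
  b <- do.call(rbind, chains)
  b$mass <- b$nres * vimentin_monomer_mass() / domains$n_res
  th <- b$az * pi / 180
  b$x <- b$r * cos(th)
  b$y <- b$r * sin(th)
  rownames(b) <- NULL
  b[, c("x", "y", "z", "chain", "domain", "resno", "nres", "mass", "rod",
        "orientation")]
}

#' Assemble a filament lattice model from tetramers
#'
#' Replicates the tetramer template by powers 0..n-1 of the helical
#' symmetry operator and assigns tetramer k to protofibril k mod
#' `n_protofibrils`. With the default 5-protofibril symmetry, successive
#' tetramers of one protofibril are offset by 5 x rise = 212.5 A, the
#' protofibril repeat. To model a protofibril on its own, assemble with
#' `n_protofibrils = 1` and the protofibril's own symmetry
#' (rise 212.5 A, twist 8.5 deg); see [protofibril_params()].
#'
#' @param n_tetramers number of tetramers (>= 1).
#' @param params a [helical_params()]; default [vif_params()].
#' @param geometry a [tetramer_geometry()].
#' @param domains a [domain_map()].
#' @param n_protofibrils number of protofibrils (default 5).
#' @param with_tails if `FALSE`, tail annotation beads are omitted
#'   (tail-less filament).
#' @return Object of class `lattice_model`: list with `beads` (data.frame
#'   as in [build_tetramer()] plus tetramer, protofibril, chain_uid),
#'   `params`, `geometry`, `domains`, `n_protofibrils`, `chain_spans`.
#' @export
assemble_filament <- function(n_tetramers, params = vif_params(),
                              geometry = tetramer_geometry(),
                              domains = domain_map(), n_protofibrils = 5L,
                              with_tails = TRUE) {
  if (!is.numeric(n_tetramers) || length(n_tetramers) != 1L ||
      n_tetramers < 1 || n_tetramers != round(n_tetramers))
    stop("'n_tetramers' must be a positive integer")
  validate_helical_params(params)
  template <- build_tetramer(geometry, domains)
  if (!with_tails) template <- template[template$domain != "tail", ]
  xyz0 <- as.matrix(template[, c("x", "y", "z")])
  parts <- vector("list", n_tetramers)
  for (k in seq_len(n_tetramers) - 1L) {
    b <- template
    b[, c("x", "y", "z")] <- apply_operator(xyz0, params, k)
    b$tetramer <- k
    b$protofibril <- k %% n_protofibrils
    parts[[k + 1L]] <- b
  }
  beads <- do.call(rbind, parts)
  beads$chain_uid <- beads$tetramer * 4L + beads$chain
  rownames(beads) <- NULL
  rod <- beads[beads$rod, ]
  spans <- data.frame(
    chain_uid = as.integer(names(tapply(rod$z, rod$chain_uid, min))),
    zmin = as.numeric(tapply(rod$z, rod$chain_uid, min)),
    zmax = as.numeric(tapply(rod$z, rod$chain_uid, max)),
    protofibril = as.integer(tapply(rod$protofibril, rod$chain_uid, "[", 1L)),
    tetramer = as.integer(tapply(rod$tetramer, rod$chain_uid, "[", 1L)))
  m <- list(beads = beads, params = params, geometry = geometry,
            domains = domains, n_protofibrils = as.integer(n_protofibrils),
            n_tetramers = as.integer(n_tetramers), chain_spans = spans)
  class(m) <- "lattice_model"
  m
}

#' Symmetry of a single protofibril
#'
#' In an `npf`-protofibril filament with per-tetramer symmetry `params`,
#' one protofibril is itself helical with rise `npf * rise` and twist
#' `npf * twist mod 360` (8.5 deg per 212.5 A for the default filament:
#' protofibrils wind slowly around the axis).
#'
#' @param params filament symmetry ([helical_params()]).
#' @param n_protofibrils protofibril count (default 5).
#' @return A [helical_params()] object.
#' @export
protofibril_params <- function(params = vif_params(), n_protofibrils = 5L) {
  tw <- (n_protofibrils * params$twist) %% 360
  if (tw == 0) tw <- 360
  helical_params(rise = n_protofibrils * params$rise, twist = tw,
                 handedness = params$handedness)
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf(
    "Lattice model: %d tetramers, %d protofibril(s), %d beads\n",
    x$n_tetramers, x$n_protofibrils, nrow(x$beads)))
  print(x$params)
  invisible(x)
}

#' Count rod chains crossing a transverse plane
#'
#' Counts the polypeptide rod chains (coil1 + L12 + coil2 core) whose axial
#' span contains `z`, with a per-protofibril breakdown. Spans are treated as
#' half-open intervals `[zmin, zmax)` so that chains stacked end-to-end
#' along a protofibril tile the axis without double counting. Head, tail
#' and luminal NTE beads are annotations and never counted.
#'
#' @param model a `lattice_model`.
#' @param z axial position, Angstrom; must lie within the model extent.
#' @return List with `count` (total chains) and `by_protofibril` (integer
#'   vector indexed by protofibril).
#' @export
cross_section_chain_count <- function(model, z) {
  stopifnot(inherits(model, "lattice_model"))
  zr <- range(model$beads$z)
  if (!is.numeric(z) || length(z) != 1L || z < zr[1] || z > zr[2])
    stop(sprintf("z = %g outside model extent [%g, %g]",
                 as.numeric(z)[1], zr[1], zr[2]))
  s <- model$chain_spans
  hit <- s$zmin <= z & z < s$zmax
  by_pf <- integer(model$n_protofibrils)
  tb <- table(factor(s$protofibril[hit],
                     levels = 0:(model$n_protofibrils - 1L)))
  by_pf <- as.integer(tb)
  names(by_pf) <- names(tb)
  list(count = sum(hit), by_protofibril = by_pf)
}

# candidate z positions where the chain-count step function can change
chain_count_breaks <- function(model) {
  b <- sort(unique(c(model$chain_spans$zmin, model$chain_spans$zmax)))
  (b[-1] + b[-length(b)]) / 2
}

#' Minimal tetramer count reaching an assembly milestone
#'
#' Searches incrementally for the smallest number of tetramers such that
#' the assembled model attains the requested cross-section occupancy,
#' verified with [cross_section_chain_count()]:
#' \describe{
#'   \item{`full_filament`}{some transverse plane crosses 8 rod chains in
#'     every one of the `n_protofibrils` protofibrils (40 chains total for
#'     the 5-protofibril filament).}
#'   \item{`protofibril_repeat`}{a single protofibril (assembled with its
#'     own symmetry, [protofibril_params()]) attains its full octameric
#'     cross-section of 8 chains.}
#'   \item{`unit_length`}{every protofibril holds at least one tetramer
#'     (the unit-length filament).}
#' }
#'
#' @param target one of `"full_filament"`, `"protofibril_repeat"`,
#'   `"unit_length"`.
#' @param params,geometry,domains,n_protofibrils model defaults.
#' @param max_n search bound (default 40).
#' @return Smallest qualifying tetramer count (integer).
#' @export
minimal_tetramer_count <- function(target = c("full_filament",
                                              "protofibril_repeat",
                                              "unit_length"),
                                   params = vif_params(),
                                   geometry = tetramer_geometry(),
                                   domains = domain_map(),
                                   n_protofibrils = 5L, max_n = 40L) {
  target <- match.arg(target)
  for (n in seq_len(max_n)) {
    if (target == "protofibril_repeat") {
      m <- assemble_filament(n, protofibril_params(params, n_protofibrils),
                             geometry, domains, n_protofibrils = 1L)
      ok <- any(vapply(chain_count_breaks(m), function(z)
        cross_section_chain_count(m, z)$count >= 8L, logical(1)))
    } else if (target == "full_filament") {
      m <- assemble_filament(n, params, geometry, domains, n_protofibrils)
      ok <- any(vapply(chain_count_breaks(m), function(z) {
        cc <- cross_section_chain_count(m, z)
        all(cc$by_protofibril >= 8L)
      }, logical(1)))
    } else {
      m <- assemble_filament(n, params, geometry, domains, n_protofibrils)
      ok <- all(tabulate(m$beads$protofibril + 1L, n_protofibrils) > 0L)
    }
    if (ok) return(n)
  }
  stop("target '", target, "' not reached within max_n = ", max_n,
       " tetramers")
}

#' Geometric and stoichiometric report of a lattice model
#'
#' Measures the assembled model: axial extent, CTE-to-CTE extent, outer
#' diameter, central cross-section chain count, mass per length, the
#' spacing of the conserved-1A/conserved-2B interlock sites along a
#' protofibril, and the A_CN co-extension (how far the 1A NTE pair of a
#' tetramer reaches past the 2A-2B CTE of its protofibril predecessor).
#' Spacing fields require at least two tetramers per protofibril and are
#' reported as `NA` otherwise.
#'
#' @param model a `lattice_model`.
#' @return A list of class `geometry_report` with fields in Angstrom
#'   (`*_A`), nm (`*_nm`) and kDa/nm.
#' @export
geometry_report <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  b <- model$beads
  g <- model$geometry
  zr <- range(b$z)
  rod <- b[b$rod, ]
  outer_d <- 2 * (max(sqrt(rod$x^2 + rod$y^2)) + g$bead_sigma)
  # CTE beads: terminal coil2 bead (highest residue number) of each chain
  c2 <- b[b$domain == "coil2_2A2B", ]
  cte_z <- tapply(c2$z[c2$resno == max(c2$resno)],
                  c2$chain_uid[c2$resno == max(c2$resno)], mean)
  cte_extent <- diff(range(cte_z))
  tet_mass <- sum(b$mass[b$tetramer == 0L])
  mpl <- mass_per_length(tet_mass, model$params$rise / 10)
  zc <- mean(zr)
  cc <- cross_section_chain_count(model, zc)
  interlock <- a_cn <- NA_real_
  per_pf <- table(b$protofibril[!duplicated(b$tetramer)])
  if (min(per_pf) >= 2L) {
    sites <- interlock_sites(model)
    # the interlocks form on both sides of the assembly; the ~21 nm spacing
    # is the axial period within each side's family of sites
    sp <- unlist(lapply(split(sites$z, interaction(sites$pf, sites$side)),
                        function(z)
                          if (length(z) >= 2L) diff(sort(z)) else numeric(0)))
    if (length(sp)) interlock <- mean(sp)
    a_cn <- a_cn_overlap(model)
  }
  rep <- list(n_tetramers = model$n_tetramers,
              n_protofibrils = model$n_protofibrils,
              axial_extent_A = diff(zr), axial_extent_nm = diff(zr) / 10,
              cte_extent_A = cte_extent, cte_extent_nm = cte_extent / 10,
              outer_diameter_A = outer_d,
              chains_cross_section = cc$count,
              chains_per_protofibril = unname(cc$by_protofibril),
              interlock_spacing_A = interlock,
              interlock_spacing_nm = interlock / 10,
              a_cn_overlap_A = a_cn,
              mass_per_length_kda_nm = mpl,
              tetramer_mass_kda = tet_mass)
  class(rep) <- c("geometry_report", "list")
  rep
}

# Axial positions where a conserved-1A interval of one tetramer coincides
# with a conserved-2B interval of another tetramer of the same protofibril.
interlock_sites <- function(model, min_overlap = 5) {
  b <- model$beads
  d <- model$domains
  c1 <- b$domain == "coil1_1A1B" & b$resno >= d$conserved_1A[1] &
    b$resno <= d$conserved_1A[2]
  c2 <- b$domain == "coil2_2A2B" & b$resno >= d$conserved_2B[1] &
    b$resno <= d$conserved_2B[2]
  iv <- function(sel) {
    s <- b[sel, ]
    key <- interaction(s$tetramer, s$chain, drop = TRUE)
    data.frame(zmin = as.numeric(tapply(s$z, key, min)),
               zmax = as.numeric(tapply(s$z, key, max)),
               tet = as.integer(tapply(s$tetramer, key, "[", 1L)),
               pf = as.integer(tapply(s$protofibril, key, "[", 1L)))
  }
  i1 <- iv(c1); i2 <- iv(c2)
  sites <- data.frame(z = numeric(0), side = integer(0))
  for (p in unique(i1$pf)) {
    a <- i1[i1$pf == p, ]; bb <- i2[i2$pf == p, ]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(bb))) {
      if (a$tet[i] == bb$tet[j]) next
      lo <- max(a$zmin[i], bb$zmin[j]); hi <- min(a$zmax[i], bb$zmax[j])
      if (hi - lo >= min_overlap)
        sites <- rbind(sites, data.frame(z = (lo + hi) / 2, pf = p,
                                         side = sign(a$tet[i] - bb$tet[j])))
    }
  }
  sites <- sites[order(sites$pf, sites$side, sites$z), ]
  keep <- c(TRUE, diff(sites$z) > 2 | diff(sites$side) != 0 |
              diff(sites$pf) != 0)
  sites[keep, , drop = FALSE]
}

# Mean axial distance by which the NTE pair of a tetramer extends past the
# CTE of its predecessor along the protofibril.
a_cn_overlap <- function(model) {
  b <- model$beads
  res <- numeric(0)
  for (p in 0:(model$n_protofibrils - 1L)) {
    tets <- sort(unique(b$tetramer[b$protofibril == p]))
    if (length(tets) < 2L) next
    for (i in seq_len(length(tets) - 1L)) {
      t0 <- tets[i]; t1 <- tets[i + 1L]
      nte_hi <- max(b$z[b$tetramer == t1 & b$domain == "coil1_nte"])
      cte_hi <- max(b$z[b$tetramer == t0 & b$domain == "coil2_2A2B"])
      res <- c(res, nte_hi - cte_hi)
    }
  }
  mean(res)
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("Lattice model report (%d tetramers, %d protofibrils)\n",
              x$n_tetramers, x$n_protofibrils))
  cat(sprintf("  axial extent        %8.1f A (%.0f nm)\n", x$axial_extent_A,
              x$axial_extent_nm))
  cat(sprintf("  CTE-to-CTE extent   %8.1f A (%.0f nm)\n", x$cte_extent_A,
              x$cte_extent_nm))
  cat(sprintf("  outer diameter      %8.1f A\n", x$outer_diameter_A))
  cat(sprintf("  chains in section   %8d\n", x$chains_cross_section))
  cat(sprintf("  interlock spacing   %8.1f A (%.0f nm)\n",
              x$interlock_spacing_A, x$interlock_spacing_nm))
  cat(sprintf("  A_CN overlap        %8.1f A\n", x$a_cn_overlap_A))
  cat(sprintf("  mass per length     %8.2f kDa/nm\n",
              x$mass_per_length_kda_nm))
  invisible(x)
}

#' Export a lattice model as pseudo-atoms (PDB) or density (MRC)
#'
#' PDB export writes one CA pseudo-atom per bead with the residue number of
#' the residues the bead represents and a chain identifier per rod chain;
#' models with more than 62 chains are split across several numbered files
#' with a CSV manifest. MRC export renders the bead cloud through
#' [render_density_map()].
#'
#' @param model a `lattice_model`.
#' @param file output path (`.pdb` or `.mrc`).
#' @param format `"pdb"` or `"mrc"`.
#' @param voxel_size MRC voxel size, Angstrom (default 3.44).
#' @return Character vector of files written, invisibly.
#' @export
export_model <- function(model, file, format = c("pdb", "mrc"),
                         voxel_size = 3.44) {
  stopifnot(inherits(model, "lattice_model"), nrow(model$beads) > 0L)
  format <- match.arg(format)
  if (format == "mrc") {
    map <- render_density_map(model, voxel_size = voxel_size)
    write_mrc(map$grid, file, voxel_size = map$voxel_size,
              origin = map$origin)
    return(invisible(file))
  }
  chain_chars <- c(LETTERS, letters, as.character(0:9))
  b <- model$beads
  uids <- sort(unique(b$chain_uid))
  n_parts <- ceiling(length(uids) / length(chain_chars))
  files <- character(0)
  resid_of <- c(head = "HED", coil1_nte = "NTE", coil1_1A1B = "CO1",
                linker_L12 = "L12", coil2_2A2B = "CO2", tail = "TAL")
  for (part in seq_len(n_parts)) {
    sel_uid <- uids[((part - 1L) * 62L + 1L):min(part * 62L, length(uids))]
    s <- b[b$chain_uid %in% sel_uid, ]
    ch <- chain_chars[match(s$chain_uid, sel_uid)]
    out <- if (n_parts == 1L) file else
      sub("(\\.pdb)?$", sprintf("_%d.pdb", part), file)
    xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
    bio3d::write.pdb(file = out, xyz = xyz, resno = s$resno,
                     resid = resid_of[s$domain], chain = ch,
                     elety = rep("CA", nrow(s)), o = rep(1, nrow(s)),
                     b = rep(0, nrow(s)))
    files <- c(files, out)
  }
  if (n_parts > 1L) {
    man <- sub("(\\.pdb)?$", "_manifest.csv", file)
    utils::write.csv(data.frame(part = seq_len(n_parts), file = files),
                     man, row.names = FALSE)
    files <- c(files, man)
  }
  invisible(files)
}
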