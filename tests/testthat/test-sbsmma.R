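test_that("perturbation constructors validate their positions", {
  expect_s3_class(perturbation("up", 3), "perturbation")
  expect_equal(perturbation("probe", 4)$positions, 4:6)
  expect_error(perturbation("probe", c(2, 4, 5)),
               class = "allokit_validation_error")
  expect_error(perturbation("up", 0), class = "allokit_validation_error")
})

test_that("up scaling with alpha 1 is the identity on the network", {
  net <- build_network(make_helix(8))
  same <- apply_perturbation(net, perturbation("up", 4, alpha_up = 1))
  expect_equal(same$edges, net$edges)
})

test_that("up stiffens exactly the incident contacts", {
  net <- build_network(collinear3(), cutoff = 10)
  up <- apply_perturbation(net, perturbation("up", 2, alpha_up = 2))
  hit <- up$edges$i == 2 | up$edges$j == 2
  expect_equal(up$edges$k[hit], c(2, 2))
  expect_equal(up$edges$k[!hit], 1)
  expect_equal(net$edges$k, rep(1, 3))  # native untouched
})

test_that("down removes non-sequential contacts and keeps the backbone", {
  net <- build_network(collinear3(), cutoff = 10)  # edges (1,2),(1,3),(2,3)
  down <- apply_perturbation(net, perturbation("down", 1))
  expect_equal(down$edges[, c("i", "j")],
               tibble::tibble(i = c(1L, 2L), j = c(2L, 3L)))
})

test_that("a down mutation that isolates a residue errors with its name", {
  # bead 4 hangs off bead 2 only; down at 2 cuts its single non-backbone tie
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(3.8, 5, 0))
  net <- build_network(coords_structure(coords), cutoff = 6)
  err <- tryCatch(apply_perturbation(net, perturbation("down", 2)),
                  error = identity)
  expect_s3_class(err, "allokit_disconnected_error")
  expect_match(conditionMessage(err), "4")
})

test_that("probe stiffens the segment's contacts and completes the triple", {
  # 5 beads zig-zagged so (1,3) is beyond the cutoff before probing
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 4.2, 0),
                  c(7.0, 4.2, 0), c(7.0, 0.4, 0))
  net <- build_network(coords_structure(coords), cutoff = 4.5)
  expect_false(any(net$edges$i == 1 & net$edges$j == 3))
  probed <- apply_perturbation(net, perturbation("probe", 1, alpha_bind = 2))
  new_edge <- dplyr::filter(probed$edges, i == 1, j == 3)
  expect_equal(nrow(new_edge), 1L)
  expect_true(new_edge$added)
  expect_equal(new_edge$k, 2)  # k0 * alpha_bind
  seg_hit <- probed$edges$i %in% 1:3 | probed$edges$j %in% 1:3
  expect_true(all(probed$edges$k[seg_hit & !probed$edges$added] == 2))
})

test_that("identity perturbations give exactly zero free energy", {
  net <- build_network(make_helix(20))
  prof <- free_energy_profile(net, perturbation("up", 10, alpha_up = 1))
  expect_identical(prof$dg, rep(0, 20))
  expect_identical(prof$dh, rep(0, 20))
})

test_that("uniform spring scaling leaves the profile at numerical zero", {
  net <- build_network(make_helix(20))
  scaled <- net
  scaled$edges$k <- scaled$edges$k * 3
  prof <- free_energy_from_networks(net, scaled)
  expect_lt(max(abs(prof$dg)), 1e-8)
})

test_that("the full up-mutation pipeline matches the brute-force oracle", {
  s <- make_helix(20)
  cfg <- allokit_config()
  net <- build_network(s, cutoff = cfg$cutoff)
  prof <- free_energy_profile(net, perturbation("up", 10, alpha_up = 2),
                              config = cfg)
  up_net <- apply_perturbation(net, perturbation("up", 10, alpha_up = 2))
  ref <- oracle_dg(structure_coords(s),
                   net$edges$i, net$edges$j, net$edges$k,
                   up_net$edges$i, up_net$edges$j, up_net$edges$k,
                   kBT = cfg$kBT)
  expect_lt(max(abs(prof$dg - ref)), 1e-10)
})

test_that("the probe pipeline matches the brute-force oracle", {
  s <- make_random_coil(12, seed = 21)
  cfg <- allokit_config()
  net <- build_network(s, cutoff = cfg$cutoff)
  pert <- perturbation("probe", 5, alpha_bind = cfg$alpha_bind)
  prof <- quiet(free_energy_profile(net, pert, config = cfg))
  p_net <- apply_perturbation(net, pert)
  ref <- oracle_dg(structure_coords(s),
                   net$edges$i, net$edges$j, net$edges$k,
                   p_net$edges$i, p_net$edges$j, p_net$edges$k,
                   kBT = cfg$kBT)
  expect_lt(max(abs(prof$dg - ref)), 1e-10)
})

test_that("down profiles survive the floppy-residue mode bookkeeping", {
  s <- make_helix(20)
  net <- build_network(s)
  expect_message(
    prof <- free_energy_profile(net, perturbation("down", 10)),
    "mode counts differ")
  expect_true(all(is.finite(prof$dg)))
  expect_lt(abs(mean(prof$dh)), 1e-12)
  down_net <- apply_perturbation(net, perturbation("down", 10))
  ref <- oracle_dg(structure_coords(s),
                   net$edges$i, net$edges$j, net$edges$k,
                   down_net$edges$i, down_net$edges$j, down_net$edges$k)
  expect_lt(max(abs(prof$dg - ref)), 1e-10)
})

test_that("every profile is mean-centred", {
  s <- make_two_domain(10, 10, 4, seed = 7)
  net <- build_network(s)
  perts <- list(perturbation("up", 3), perturbation("probe", 11),
                perturbation("down", 15))
  for (p in perts) {
    prof <- quiet(free_energy_profile(net, p))
    expect_lt(abs(mean(prof$dh)), 1e-12)
  }
})

test_that("modulation range is up minus down and antisymmetric exactly", {
  s <- make_helix(25)
  net <- build_network(s)
  eps0 <- allokit:::network_stiffness(net, allokit_config())
  for (m in c(1L, 12L, 25L)) {
    mr <- quiet(modulation_range(net, m, eps0 = eps0))
    up <- quiet(free_energy_profile(net, perturbation("up", m), eps0 = eps0))
    dn <- quiet(free_energy_profile(net, perturbation("down", m), eps0 = eps0))
    expect_equal(mr$dh_range, up$dh - dn$dh, tolerance = 0)
    rev <- quiet(modulation_range(net, m, eps0 = eps0, direction = "up_down"))
    expect_identical(mr$dh_range + rev$dh_range, rep(0, 25))
  }
})

test_that("the response profile is invariant under rigid motion", {
  s <- make_random_coil(20, seed = 13)
  prof1 <- quiet(mutation_profile(s, 10, direction = "up"))
  sR <- transform_structure(s, random_rotation(41), c(7, -3, 11))
  prof2 <- quiet(mutation_profile(sR, 10, direction = "up"))
  expect_lt(max(abs(prof1$dg - prof2$dg)), 1e-8)
})
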