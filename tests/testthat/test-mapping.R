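cfg <- allokit_config()

test_that("ASM and APM obey their shape contracts and row-wise centring", {
  s <- make_helix(15)
  asm <- quiet(compute_asm(s))
  apm <- quiet(compute_apm(s))
  expect_equal(dim(asm), c(15L, 15L))
  expect_equal(dim(apm), c(13L, 15L))
  expect_true(all(abs(rowMeans(asm$values)) < 1e-12))
  expect_true(all(abs(rowMeans(apm$values)) < 1e-12))
  expect_equal(asm$row_kind, "mutation_range")
  expect_equal(apm$row_kind, "probe")
})

test_that("structures below the minimum size are rejected", {
  expect_error(compute_asm(make_helix(8)), class = "allokit_validation_error")
})

test_that("ASM rows are bit-identical to standalone modulation-range calls", {
  s <- make_helix(14)
  asm <- quiet(compute_asm(s, config = cfg))
  net <- build_network(s, cutoff = cfg$cutoff, k0 = cfg$k0)
  for (m in c(1L, 7L, 14L)) {
    standalone <- quiet(modulation_range(net, m, config = cfg))
    expect_identical(asm$values[m, ], stats::setNames(standalone$dh_range,
                                                      standalone$residue))
  }
})

test_that("the first APM row equals the standalone probe profile", {
  s <- make_helix(14)
  apm <- quiet(compute_apm(s, config = cfg))
  prof <- quiet(probe_profile(s, 1, config = cfg))
  expect_identical(unname(apm$values[1, ]), prof$dh)
})

test_that("an identity probe (alpha 1, complete triple) yields a zero row", {
  s <- make_helix(12)  # consecutive triples are within 10 A: triple complete
  apm <- quiet(compute_apm(s, config = allokit_config(alpha_bind = 1)))
  expect_equal(max(abs(apm$values)), 0)
})

test_that("up and down ASMs carry the requested row kind", {
  s <- make_helix(12)
  up_map <- quiet(compute_asm(s, row_kind = "up"))
  expect_equal(up_map$row_kind, "up")
  net <- build_network(s)
  prof <- quiet(free_energy_profile(net, perturbation("up", 3)))
  expect_identical(unname(up_map$values[3, ]), prof$dh)
})

test_that("fingerprint masking follows the distance/threshold definition", {
  s <- collinear3()
  vals <- matrix(c(0, 0.5, -2,
                   1.5, 0, 0.05,
                   -0.2, 3, 0), 3, byrow = TRUE)
  map <- allokit:::new_allosteric_map(vals, "mutation_range", 1:3,
                                      allokit:::residue_labels(s))
  # distances: d(1,2)=d(2,3)=3.8, d(1,3)=7.6, d(i,i)=0
  fp <- make_fingerprint(map, s, d_min = 4, h_min = 0.1)
  prox_truth <- matrix(c(TRUE, TRUE, FALSE,
                         TRUE, TRUE, TRUE,
                         FALSE, TRUE, TRUE), 3, byrow = TRUE)
  weak_truth <- abs(vals) <= 0.1
  expect_equal(unname(fp$mask), prox_truth | weak_truth)

  zero <- make_fingerprint(map, s, d_min = 0, h_min = 0)
  expect_equal(unname(zero$mask), unname(vals == 0))  # only exact zeros masked
  all_masked <- make_fingerprint(map, s, d_min = Inf, h_min = 0)
  expect_true(all(all_masked$mask))
  expect_error(make_fingerprint(map, s, d_min = -1, h_min = 0.1),
               class = "allokit_validation_error")
})

test_that("fingerprint masking is monotone in both thresholds", {
  s <- make_helix(12)
  map <- quiet(compute_asm(s))
  prev <- make_fingerprint(map, s, d_min = 0, h_min = 0)$mask
  for (d in c(4, 8, 12, 20)) {
    cur <- make_fingerprint(map, s, d_min = d, h_min = 0)$mask
    expect_true(all(cur[prev]))  # nothing unmasked
    prev <- cur
  }
  prev <- make_fingerprint(map, s, d_min = 0, h_min = 0)$mask
  for (h in c(0.05, 0.2, 1, 5)) {
    cur <- make_fingerprint(map, s, d_min = 0, h_min = h)$mask
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("probe rows mask proximity to the whole three-residue segment", {
  s <- make_helix(12)
  apm <- quiet(compute_apm(s))
  fp <- make_fingerprint(apm, s, d_min = 1e-6, h_min = 0)
  # each probe row touches exactly its three segment residues at distance 0
  for (r in seq_len(nrow(fp$mask))) {
    at_zero <- which(fp$mask[r, ] &
                       abs(apm$values[r, ]) > 0)
    expect_true(all(at_zero %in% (r + 0:2)))
  }
})

test_that("zoom extracts contiguous blocks with labels and rejects bad ranges", {
  s <- make_helix(30)
  map <- quiet(compute_asm(s))
  full <- zoom_map(map)
  expect_equal(full$values, map$values)
  sub <- zoom_map(map, rows = 5:10, cols = 1:30)
  expect_equal(nrow(sub$values), 6L)
  expect_equal(sub$row_positions, 5:10)
  expect_equal(rownames(sub$values), as.character(5:10))
  expect_error(zoom_map(map, rows = 25:35), class = "allokit_range_error")
  expect_error(zoom_map(map, rows = c(3, 5, 7)), class = "allokit_range_error")
})

test_that("map TSV round trips to serialized precision, sentinel included", {
  vals <- withr::with_seed(99, matrix(rnorm(120) / 10, 10, 12))
  vals[4, ] <- NA_real_
  map <- allokit:::new_allosteric_map(vals, "mutation_range", 1:10,
                                      sprintf("A%d", 1:12))
  path <- tempfile(fileext = ".tsv")
  write_map(map, path)
  back <- read_map(path)
  expect_lte(max(abs(back$values - map$values), na.rm = TRUE), 5e-7)
  expect_true(all(is.na(back$values[4, ])))
  expect_equal(back$residue_ids, map$residue_ids)
  expect_equal(back$row_kind, "mutation_range")
})

test_that("label disagreement with the sidecar is a format error", {
  map <- allokit:::new_allosteric_map(matrix(1:12 / 7, 3, 4), "up", 1:3,
                                      sprintf("A%d", 1:4))
  path <- tempfile(fileext = ".tsv")
  write_map(map, path)
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  lines[1] <- paste(header[c(1, 3, 2, 4, 5)], collapse = "\t")
  writeLines(lines, path)
  expect_error(read_map(path), class = "allokit_format_error")
})

test_that("malformed map TSVs report a parse error", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("pos\tA1\tA2", "1\t0.5\tnot_a_number"), path)
  expect_error(suppressWarnings(read_map(path)), class = "allokit_format_error")
})
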