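test_that("synthetic morphology reproduces the reconstruction summary statistics", {
  m <- generate_synthetic_morphology(seed = 1)
  expect_s3_class(m, "pir_morphology")
  tl <- total_dendritic_length(m)
  expect_gte(tl, 2238)
  expect_lte(tl, 2516)
  expect_equal(m$soma_area, 829)
  tips <- piriform:::section_tip_distances(m)
  expect_gte(max(tips$tip_dist), 350)
  # at least two primaries so sister/different relations are realizable
  expect_gte(length(unique(m$sections$root_id[!m$sections$is_soma])), 2)
})

test_that("generation is deterministic under a fixed seed", {
  m1 <- generate_synthetic_morphology(seed = 7)
  m2 <- generate_synthetic_morphology(seed = 7)
  expect_identical(m1$sections, m2$sections)
  m3 <- generate_synthetic_morphology(seed = 8)
  expect_false(isTRUE(all.equal(m1$sections$length, m3$sections$length)))
})

test_that("soma area parameter propagates to the reported membrane area", {
  p <- morph_params(soma_area = 829)
  m <- generate_synthetic_morphology(p, seed = 2)
  expect_equal(m$soma_area, 829)
  g <- discretize(m)
  expect_equal(g$comps$area[1], 829)
  # cylinder with length = diameter: pi * L * d = 829 -> L = 16.24
  expect_equal(m$sections$length[1], sqrt(829 / pi), tolerance = 1e-10)
})

test_that("morphology invariants hold across many seeds", {
  for (seed in 1:100) {
    m <- generate_synthetic_morphology(seed = seed)
    expect_silent(validate_morphology(m, total_length_range = c(2238, 2516)))
    tips <- piriform:::section_tip_distances(m)
    expect_gte(max(tips$tip_dist), 350)
  }
})

test_that("unsatisfiable generator constraints raise constraint errors", {
  expect_error(
    generate_synthetic_morphology(morph_params(min_tip_distance = 3000), seed = 1),
    class = "pir_constraint_error")
  expect_error(
    generate_synthetic_morphology(morph_params(diam_by_order = c(2, 1)), seed = 1),
    class = "pir_constraint_error")
  expect_error(
    generate_synthetic_morphology(morph_params(total_length_range = c(100, 50)),
                                  seed = 1),
    class = "pir_constraint_error")
})

test_that("discretize splits sections into ceiling(length / max_seg_len) pieces", {
  m <- toy_morphology(parent = 1, length = 19, diam = 2)
  g <- discretize(m, max_seg_len = 19)
  expect_equal(sum(g$comps$section == 2), 1)

  m2 <- toy_morphology(parent = 1, length = 40, diam = 2)
  g2 <- discretize(m2, max_seg_len = 19)
  expect_equal(sum(g2$comps$section == 2), 3)
  # compartment lengths per section sum to the section length
  expect_equal(sum(g2$comps$length[g2$comps$section == 2]), 40)
})

test_that("default discretization lands in the reconstruction compartment band", {
  g <- default_cell()$g
  expect_gte(nrow(g$comps), 400)
  expect_lte(nrow(g$comps), 650)
  # hard cap on compartment length
  expect_true(all(g$comps$length <= 19))
  expect_error(discretize(default_cell()$m, max_seg_len = 25),
               class = "pir_constraint_error")
  # re-discretizing the same geometry gives identical compartment counts
  g2 <- discretize(default_cell()$m)
  expect_identical(table(g2$comps$section), table(g$comps$section))
})

test_that("coupling topology mirrors the section tree", {
  g <- default_cell()$g
  cc <- g$comps
  sec <- default_cell()$m$sections
  for (i in which(!is.na(cc$parent_comp))) {
    p <- cc$parent_comp[i]
    same_section <- cc$section[p] == cc$section[i]
    parent_section <- sec$parent[match(cc$section[i], sec$section)] == cc$section[p]
    expect_true(same_section || parent_section)
  }
  expect_true(all(cc$g_axial[-1] > 0))
})

test_that("path distance accumulates arc lengths along the unique path to the soma", {
  m <- toy_morphology(parent = c(1, 2), length = c(200, 60), diam = c(2, 1))
  g <- discretize(m)
  expect_equal(path_distance(g, dendritic_location(1, 0)), 0)
  expect_equal(path_distance(g, dendritic_location(2, 1)), 200, tolerance = 1e-9)
  # midpoint of a 60 um child whose parent ends 200 um out -> 230 um
  expect_equal(path_distance(g, dendritic_location(3, 0.5)), 230, tolerance = 1e-9)
  expect_error(path_distance(g, dendritic_location(99, 0.5)),
               class = "pir_lookup_error")
  # monotone along a root-to-tip path
  d <- sapply(seq(0, 1, 0.1), function(a) path_distance(g, dendritic_location(3, a)))
  expect_true(all(diff(d) > 0))
})

test_that("zone classification partitions the tree into three contiguous bands", {
  m <- toy_morphology(parent = c(1, 2), length = c(200, 200), diam = c(2, 1))
  g <- discretize(m)
  at <- function(dist) {
    if (dist <= 200) dendritic_location(2, dist / 200)
    else dendritic_location(3, (dist - 200) / 200)
  }
  expect_equal(classify_zone(g, at(80)), "perisomatic")
  expect_equal(classify_zone(g, at(160)), "IC")
  expect_equal(classify_zone(g, at(280)), "LOT")
  # boundaries: <=100 perisomatic, >=250 LOT, contiguous IC in between
  zones <- sapply(seq(5, 395, by = 5), function(d) classify_zone(g, at(d)))
  r <- rle(zones)
  expect_equal(r$values, c("perisomatic", "IC", "LOT"))
})

test_that("branch relations follow the root-dendrite definition and are symmetric", {
  # two primaries; primary 1 branches into sections 3 and 4
  m <- toy_morphology(parent = c(1, 2, 2, 1), length = c(100, 80, 80, 120),
                      diam = c(2, 1, 1, 2), order = c(1, 2, 2, 1),
                      root = c(1, 1, 1, 2))
  a <- dendritic_location(3, 0.5)
  expect_equal(branch_relation(m, dendritic_location(3, 0.2), a), "same")
  # ancestor line counts as the same branch
  expect_equal(branch_relation(m, dendritic_location(2, 0.5), a), "same")
  expect_equal(branch_relation(m, a, dendritic_location(4, 0.5)), "sister")
  expect_equal(branch_relation(m, a, dendritic_location(5, 0.5)), "different")
  # symmetry
  for (b in list(dendritic_location(2, 0.1), dendritic_location(4, 0.9),
                 dendritic_location(5, 0.5))) {
    expect_equal(branch_relation(m, a, b), branch_relation(m, b, a))
  }
  expect_error(branch_relation(m, a, dendritic_location(42, 0.5)),
               class = "pir_lookup_error")
})

test_that("morphology summary reports totals and per-zone lengths", {
  cell <- default_cell()
  s <- morphology_summary(cell$m, cell$g)
  expect_equal(s$total_dendritic_length_um, total_dendritic_length(cell$m))
  expect_equal(s$n_compartments, nrow(cell$g$comps))
  expect_setequal(names(s$zone_length_um), c("perisomatic", "IC", "LOT"))
  expect_equal(sum(unlist(s$zone_length_um)), s$total_dendritic_length_um,
               tolerance = 1e-6)
  expect_no_error(jsonlite::toJSON(s, auto_unbox = TRUE))
})
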