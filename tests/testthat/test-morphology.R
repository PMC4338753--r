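test_that("axon construction matches the reference geometry exactly", {
  ax <- pc_build_axon()
  # 11 axonal sections: AIS, paraAIS, 4 myelinated internodes, 3 nodes,
  # 2 collateral sections
  expect_equal(nrow(ax), 11)
  ais <- ax[ax$tag == "AIS", ]
  expect_equal(ais$diam, 0.97)
  expect_equal(ais$length, 17)
  # lateral area of the AIS cylinder
  expect_equal(pi * ais$diam * ais$length, 51.81, tolerance = 1e-3)
  expect_equal(sum(ax$tag == "myelin"), 4)
  expect_equal(sum(ax$tag == "node"), 3)
  expect_equal(sum(ax$tag == "collateral"), 2)
  expect_true(all(ax$diam[ax$tag == "myelin"] == 0.73))
  expect_true(all(ax$length[ax$tag == "myelin"] == 100))
  expect_true(all(ax$length[ax$tag == "node"] == 4))
  # collateral branches from the 2nd node
  node_ids <- ax$id[ax$tag == "node"]
  col <- ax[ax$tag == "collateral", ]
  expect_equal(col$parent[1], node_ids[2])
  expect_equal(col$parent[2], col$id[1])
  # deterministic: two calls identical
  expect_identical(ax, pc_build_axon())
})

test_that("AIS-to-3rd-node midpoint path length sums to 322.5 um", {
  expect_equal(axon_path_length(), 8.5 + 4 + 100 + 4 + 100 + 4 + 100 + 2)
  expect_equal(axon_path_length(), 322.5)
})

test_that("total area is additive and the unit cylinder checks out", {
  one <- data.frame(id = 1, parent = 0, tag = "soma", diam = 1, length = 1)
  expect_equal(total_area(one), pi)
  ax <- pc_build_axon()
  expect_equal(total_area(ax), sum(pi * ax$diam * ax$length))
  m <- pc_morphology(60, seed = 4)
  drop <- m[-nrow(m), ]
  expect_equal(total_area(m) - total_area(drop),
               pi * m$diam[nrow(m)] * m$length[nrow(m)])
})

test_that("surrogate tree hits the area target and respects ranges", {
  for (n in c(60, 400)) {
    m <- pc_morphology(n, seed = 1)
    expect_equal(nrow(m), n + 12) # soma + 11 axonal sections
    expect_lt(abs(total_area(m) - 70000) / 70000, 0.02)
    dend <- m[m$tag %in% c("trunk_dendrite", "principal_dendrite",
                           "terminal_dendrite"), ]
    expect_equal(nrow(dend), n)
    expect_true(all(dend$diam >= 0.67 & dend$diam <= 9.22))
    expect_true(all(dend$length > 0))
    # tagging by diameter: terminal < 3.5, trunk/principal above
    expect_true(all(dend$diam[dend$tag == "terminal_dendrite"] < 3.5))
    expect_true(all(dend$diam[dend$tag != "terminal_dendrite"] >= 3.5))
    # three branch orders, connected and acyclic
    expect_true(all(dend$parent %in% c(1L, m$id)))
    depth <- pc_path_length(m)
    expect_true(all(is.finite(depth)))
  }
})

test_that("full-scale 1599-section tree keeps lengths in the printed range", {
  d <- generate_surrogate_dendrites(70000, 1599, seed = 2)
  term <- d$length[d$tag == "terminal_dendrite"]
  expect_true(all(term >= 0.4 & term <= 25)) # near the 1-10 um band
  expect_lt(abs(sum(pi * d$diam * d$length) -
                (70000 - pc_soma_area() -
                 total_area(pc_build_axon()))) / 70000, 0.02)
})

test_that("surrogate generator is deterministic per seed", {
  expect_identical(generate_surrogate_dendrites(70000, 80, seed = 7),
                   generate_surrogate_dendrites(70000, 80, seed = 7))
  a <- generate_surrogate_dendrites(70000, 80, seed = 7)
  b <- generate_surrogate_dendrites(70000, 80, seed = 8)
  expect_false(identical(a$length, b$length))
})

test_that("infeasible area targets raise an error", {
  expect_error(generate_surrogate_dendrites(70000, 3, seed = 1),
               "infeasible")
  expect_error(generate_surrogate_dendrites(3000, 50, seed = 1),
               "exceed")
})

test_that("SWC round trip preserves topology, diameters and lengths", {
  m <- pc_morphology(40, seed = 3)
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$tag, m$tag)
  expect_equal(m2$diam, m$diam, tolerance = 1e-6)
  expect_equal(m2$length, m$length, tolerance = 1e-6)
  expect_equal(m2$parent, m$parent)
  unlink(f)
})

test_that("malformed SWC records are rejected", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 0.5 -1", "2 3 1 0 0 0.5 2"), f) # self-parent
  expect_error(read_swc(f), "cyclic")
  writeLines(c("1 1 0 0 0 0.5"), f) # six columns
  expect_error(read_swc(f), "malformed")
  unlink(f)
})

test_that("a 3-point toy SWC with radius 0.5 yields one 1-um section", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 0.5 -1",
               "2 1 2 0 0 0.5 1",
               "3 3 7 0 0 0.5 2"), f)
  m <- read_swc(f)
  dend <- m[m$tag != "soma", ]
  expect_equal(nrow(dend), 1)
  expect_equal(dend$diam, 1.0)
  expect_equal(dend$length, 5)
  unlink(f)
})
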