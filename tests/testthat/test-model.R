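test_that("channel densities are distributed to compartments exactly", {
  mod <- canonical_model()
  area_of <- function(tag) sum(mod$comp$area_cm2[mod$comp$tag == tag])
  gbar_total <- function(ch) {
    e <- Filter(function(x) x$channel == ch, mod$sys$chan)[[1]]
    sum(e$gbar)
  }
  # conductances are density x area x 1e6 (uS) summed over placements
  expect_equal(gbar_total("Kv3.3"),
               0.01 * (area_of("trunk_dendrite") +
                       area_of("principal_dendrite") +
                       area_of("terminal_dendrite")) * 1e6,
               tolerance = 1e-9)
  expect_equal(gbar_total("Nav1.6"),
               (0.016 * area_of("trunk_dendrite") +
                0.214 * area_of("soma") + 0.5 * area_of("AIS") +
                0.03 * area_of("node") + 0.03 * area_of("collateral")) * 1e6,
               tolerance = 1e-9)
  # myelin has no channels at all
  myel <- which(mod$comp$tag == "myelin") - 1L
  for (e in mod$sys$chan) expect_false(any(e$comp %in% myel))
})

test_that("model edits are pure: the original model is untouched", {
  mod <- canonical_model()
  h0 <- digest_tab <- paste(capture.output(str(mod$channels)), collapse = "")
  ko <- pc_edit(mod, "Nav1.6", "AIS", 0)
  expect_equal(pc_gmax("Nav1.6", "AIS", ko$channels), 0)
  expect_equal(pc_gmax("Nav1.6", "AIS", mod$channels), 0.5)
  h1 <- paste(capture.output(str(mod$channels)), collapse = "")
  expect_identical(h0, h1)
  # scaling composes multiplicatively
  half <- pc_edit(mod, "Kv3.4", "all", 0.5)
  expect_equal(pc_gmax("Kv3.4", "soma", half$channels), 0.025)
})

test_that("an empty configuration yields the canonical model", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- pc_load_config(f)
  expect_equal(cfg$channels, pc_channelome())
  expect_equal(cfg$passive, pc_passive())
  expect_equal(cfg$sim$dt, 0.025)
  expect_equal(total_area(cfg$morphology), 70000, tolerance = 0.02 * 70000)
  unlink(f)
})

test_that("config overrides mirror programmatic edits and are validated", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("channels:",
               "  - channel: Nav1.6",
               "    region: AIS",
               "    gmax: 0"), f)
  cfg <- pc_load_config(f)
  mod_cfg <- pc_model_from_config(cfg)
  mod_edit <- pc_edit(canonical_model(), "Nav1.6", "AIS", 0)
  expect_equal(mod_cfg$channels, mod_edit$channels)
  writeLines(c("channels:",
               "  - channel: Nav1.6",
               "    region: AIS",
               "    gmax: -1"), f)
  expect_error(pc_load_config(f), "non-negative")
  writeLines("unknown_block: 1", f)
  expect_error(pc_load_config(f), "unknown config key")
  unlink(f)
})

test_that("the run manifest captures what a re-run needs", {
  mod <- canonical_model()
  man <- pc_manifest(mod, list(note = "x"))
  expect_equal(man$morphology$seed, 1)
  expect_equal(man$morphology$target_area, 70000)
  expect_equal(man$celsius, 37)
  expect_true(is.numeric(man$channel_table_checksum))
  expect_equal(man$note, "x")
  # same model, same checksum; edited model, different checksum
  man2 <- pc_manifest(pc_edit(mod, "Kv1.1", "soma", 0.5))
  expect_false(identical(man$channel_table_checksum,
                         man2$channel_table_checksum))
})

test_that("trace CSV export round-trips through read.csv", {
  mod <- pc_model(pc_morphology(40, seed = 6))
  tr <- pc_run(mod, 20, settle = 10, record = c("soma", "AIS"))
  f <- tempfile(fileext = ".csv")
  pc_write_traces(tr, f, decimate = 2)
  d <- utils::read.csv(f)
  expect_equal(names(d), c("time", "soma", "AIS"))
  expect_equal(nrow(d), ceiling(length(tr$time) / 2))
  expect_equal(d$soma[1], unname(tr$v[1, "soma"]), tolerance = 1e-9)
  unlink(f)
})

test_that("named recording sites resolve to the expected regions", {
  mod <- canonical_model()
  for (s in c("soma", "AIS", "node1", "node3", "trunk", "terminal",
              "collateral")) {
    k <- pc_site(mod, s)
    expect_true(k >= 1 && k <= nrow(mod$comp))
  }
  expect_equal(mod$comp$tag[pc_site(mod, "soma")], "soma")
  expect_equal(mod$comp$tag[pc_site(mod, "node3")], "node")
  expect_equal(mod$comp$tag[pc_site(mod, "terminal")], "terminal_dendrite")
  expect_error(pc_site(mod, "nowhere"), "unknown site")
})
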