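test_that("node and network validation enforces the declared invariants", {
  expect_error(fz_node("X", "no-such-module"),
               class = "fuzzynet_validation_error")
  expect_error(fz_node("X", "activation-core", rule = "Y", alpha = 0),
               class = "fuzzynet_validation_error")
  expect_error(fz_node("X", "cytokine-input", rule = "Y"),
               class = "fuzzynet_validation_error")
  expect_error(fz_node("X", "activation-core"),
               class = "fuzzynet_validation_error")
  expect_error(fz_network(list(fz_node("A", "activation-core", rule = "A"),
                               fz_node("A", "activation-core", rule = "A"))),
               class = "fuzzynet_validation_error")
  err <- tryCatch(
    fz_network(list(fz_node("A", "activation-core", rule = "A & FOO"))),
    error = identity)
  expect_s3_class(err, "fuzzynet_validation_error")
  expect_match(conditionMessage(err), "FOO")
})

test_that("model files round-trip through write_network/read_network", {
  net <- biased_toggle()
  f <- withr::local_tempfile(fileext = ".net")
  write_network(net, f)
  net2 <- read_network(f)
  expect_identical(network_nodes(net2), network_nodes(net))
  expect_identical(net2$name, net$name)
  expect_identical(net2$version, net$version)
})

test_that("malformed model files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".net")
  writeLines(c("NETWORK t VERSION 1", "NODE A MODULE activation-core ALPHA 1 RULE B"), f)
  expect_error(read_network(f), class = "fuzzynet_validation_error")
  writeLines(c("NODE A MODULE activation-core ALPHA 1 RULE A"), f)
  expect_error(read_network(f), class = "fuzzynet_io_error")
  expect_error(read_network(file.path(tempdir(), "absent.net")),
               class = "fuzzynet_io_error")
})

test_that("step stimulus follows the logistic depletion schedule", {
  s <- step_stimulus()  # A = D = 1, T = 15, beta_s = 1
  expect_equal(stimulus_level(s, 15), 0.5)
  expect_equal(stimulus_level(s, 0), 1 - 1 / (1 + exp(15)), tolerance = 1e-12)
  expect_equal(stimulus_level(s, 30), 1 - 1 / (1 + exp(-15)), tolerance = 1e-12)
  expect_equal(stimulus_level(s, 30), 3.06e-7, tolerance = 1e-2)
  # midpoint identity A - D/2 for arbitrary parameters
  s2 <- step_stimulus(A = 0.8, D = 0.5, T = 7, beta_s = 3)
  expect_equal(stimulus_level(s2, 7), 0.8 - 0.25)
  # D = 0: constant stimulus
  s3 <- step_stimulus(A = 0.6, D = 0)
  expect_equal(stimulus_level(s3, c(0, 10, 100)), rep(0.6, 3))
  # monotone non-increasing for D > 0
  expect_true(all(diff(stimulus_level(s, seq(0, 40, 0.5))) <= 0))
})

test_that("fixture networks have the advertised structure", {
  tg <- make_fixture("toggle")
  expect_identical(names(tg$nodes), c("A", "B"))
  expect_identical(fz_deparse(tg$nodes$A$rule), "!B")
  expect_identical(fz_deparse(tg$nodes$B$rule), "!A")
  expect_equal(vapply(tg$nodes, `[[`, 1, "alpha"), c(A = 1, B = 1))
  sa <- make_fixture("self-activator")
  expect_identical(fz_deparse(sa$nodes$A$rule), "A")
  nf <- make_fixture("negative-feedback-loop")
  expect_identical(fz_deparse(nf$nodes$B$rule), "A")   # A activates B
  expect_identical(fz_deparse(nf$nodes$A$rule), "!B")  # B represses A
  expect_error(make_fixture("nope"))
})

test_that("the bundled CD4 model has the documented topology", {
  net <- cd4_net_cached()
  expect_length(net$nodes, 68)
  info <- network_nodes(net)
  expect_length(unique(info$module), 8)
  expect_setequal(unique(info$module), module_tags())
  # referential integrity: every rule symbol is a declared node
  for (nd in net$nodes) {
    if (!is.null(nd$rule)) {
      expect_true(all(fz_vars(nd$rule) %in% info$name))
    }
  }
  # inputs carry no rules; internal nodes exactly one
  expect_true(all(is.na(info$rule[info$is_input])))
  expect_true(all(!is.na(info$rule[!info$is_input])))
  # hypoxia wiring: HIF-1a activates RORgt and represses Foxp3
  ror <- info$rule[info$name == "RORGT"]
  expect_match(ror, "HIF1A")
  expect_match(info$rule[info$name == "FOXP3"], "!HIF1A", fixed = TRUE)
  # Bcl-6 is mTORC1/STAT3-driven, antagonized by the other lineage TFs,
  # and represses glycolysis
  bcl6 <- info$rule[info$name == "BCL6"]
  for (s in c("MTORC1", "STAT3", "TBET", "RORGT", "GATA3")) {
    expect_match(bcl6, s)
  }
  expect_match(info$rule[info$name == "GLYC"], "!BCL6", fixed = TRUE)
  # glutamine -> AKG -> mTORC1 axis
  expect_match(info$rule[info$name == "AKG"], "GLN")
  expect_match(info$rule[info$name == "MTORC1"], "AKG")
})

test_that("microenvironment construction validates its inputs", {
  expect_error(fz_env(levels = c(IL4_e = 1.4)),
               class = "fuzzynet_validation_error")
  expect_error(cd4_env(levels = c(NOPE = 1), manifest = cd4_man_cached()),
               class = "fuzzynet_config_error")
  expect_error(cd4_env(t_ctla4 = 0, manifest = cd4_man_cached()),
               class = "fuzzynet_config_error")
  env <- cd4_env(manifest = cd4_man_cached())
  # naive defaults: cytokines absent, nutrients optimal, normoxia
  expect_equal(unname(env$levels[c("IL4_e", "IL6_e")]), c(0, 0))
  expect_equal(unname(env$levels[c("GLN", "TRP", "GLC", "FA")]), rep(1, 4))
  expect_equal(unname(env$levels["HYP"]), 0)
  expect_setequal(names(env$schedules), c("MHC", "CD8086"))
})
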