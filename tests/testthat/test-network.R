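test_that("network assembly has the right populations and projections", {
  set.seed(20)
  net <- build_network(network_config("EI2/1", n_exc = 144))
  expect_equal(net$config$n_lgn, 288L)
  expect_equal(net$config$n_exc, 144L)
  expect_equal(net$config$n_inh, 36L)
  expect_named(net$proj, c("lgn_e", "lgn_i", "e_i", "i_e", "i_i"))
  expect_equal(dim(net$proj$lgn_e$W), c(288L, 144L))
  expect_true(all(diag(net$proj$i_i$W) == 0))  # no inhibitory self-connection
  expect_error(network_config("EI2/1", n_exc = 10, n_inh = 3), "4:1")
  # noInh: inhibitory projections absent, reduced learning rates
  no <- build_network(network_config("noInh", n_exc = 36))
  expect_null(no$proj$i_e)
  expect_equal(no$proj$lgn_e$params$A_ltp, 7.2e-5)
  # EI3/1 differs only in the feedback target constant
  e3 <- build_network(network_config("EI3/1", n_exc = 36))
  expect_equal(e3$proj$i_e$params$rho, 0.7)
  expect_error(build_network(network_config("fix_fb_inh", n_exc = 36)),
               "reference")
})

test_that("silent input produces no spikes and identical seeds identical records", {
  set.seed(21)
  net <- build_network(network_config("EI2/1", n_exc = 8))
  r <- present_stimulus(net, rep(0, 288))
  expect_equal(nrow(r$spikes), 0L)
  expect_equal(sum(r$counts_e), 0)
  rates <- runif(288, 0, 100)
  set.seed(99); r1 <- present_stimulus(net, rates, plastic = TRUE)
  set.seed(99); r2 <- present_stimulus(net, rates, plastic = TRUE)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$net$proj$lgn_e$W, r2$net$proj$lgn_e$W)
})

test_that("the compiled core reproduces the R-composed step-function loop exactly", {
  set.seed(22)
  net <- build_network(network_config("EI2/1", n_exc = 8))
  rates <- matrix(runif(288 * 3, 0, 120), 288, 3)
  set.seed(7); ref <- r_network_loop(net, rates, 125)
  set.seed(7); r <- present_batch(net, rates, plastic = TRUE)
  expect_gt(sum(ref$counts_e), 0)  # the comparison must exercise spikes
  expect_identical(r$counts_e, ref$counts_e)
  for (nm in names(ref$W))
    expect_equal(r$net$proj[[nm]]$W, ref$W[[nm]], tolerance = 1e-13,
                 label = paste("projection", nm))
})

test_that("training is a no-op for zero stimuli and detects runaway weights", {
  set.seed(23)
  scenes <- list(generate_whitened_scene(32))
  net <- build_network(network_config("EI2/1", n_exc = 8))
  r0 <- train(net, scenes, n_stimuli = 0)
  expect_identical(r0$net$proj$lgn_e$W, net$proj$lgn_e$W)
  expect_equal(nrow(r0$log), 0L)
  # force divergence: start at the ceiling with an enormous LTP rate
  hot <- net
  hot$proj$lgn_e$W[] <- hot$proj$lgn_e$params$w_max - 1e-4
  hot$proj$lgn_e$params$A_ltp <- 10
  hot$proj$lgn_e$params$A_ltd <- 0
  bright <- whitened_scene(matrix(runif(32 * 32, -1, 1), 32, 32))
  expect_error(train(hot, list(bright), n_stimuli = 100, block_size = 50),
               "runaway")
})

test_that("variant constructions preserve and freeze what they must", {
  set.seed(24)
  scenes <- list(generate_whitened_scene(48))
  ref <- build_network(network_config("EI2/1", n_exc = 8))
  ref <- train(ref, scenes, n_stimuli = 100, block_size = 50)$net
  # blockInh shares the feed-forward weights by construction
  bl <- block_inhibition(ref)
  expect_identical(bl$proj$lgn_e$W, ref$proj$lgn_e$W)
  expect_false(bl$transmit_inh)
  r <- present_batch(bl, matrix(runif(288, 0, 80), ncol = 1))
  expect_true(all(r$mean_ii == 0))
  # shuffled reference: weight-value multiset preserved
  fx <- build_network(network_config("fix_fb_inh", n_exc = 8), reference = ref)
  expect_equal(sort(as.vector(fx$proj$e_i$W)),
               sort(as.vector(ref$proj$e_i$W)))
  # frozen projection is bit-identical after training
  ie_before <- fx$proj$i_e$W
  fx2 <- train(fx, scenes, n_stimuli = 150, block_size = 50)$net
  expect_identical(fx2$proj$i_e$W, ie_before)
  # plastic projections did change
  expect_false(identical(fx2$proj$lgn_e$W, fx$proj$lgn_e$W))
})

test_that("checkpoint, restore and continue is bit-identical to an uninterrupted run", {
  set.seed(25)
  scenes <- list(generate_whitened_scene(48))
  net0 <- build_network(network_config("EI2/1", n_exc = 8))
  f <- tempfile(fileext = ".rds")

  set.seed(26)
  straight <- train(net0, scenes, n_stimuli = 60, block_size = 20)$net

  set.seed(26)
  part1 <- train(net0, scenes, n_stimuli = 20, block_size = 20)$net
  save_checkpoint(part1, f)
  set.seed(31415); runif(100)  # scramble the RNG as a fresh session would
  restored <- load_checkpoint(f)
  resumed <- train(restored, scenes, n_stimuli = 40, block_size = 20)$net

  expect_identical(resumed$proj$lgn_e$W, straight$proj$lgn_e$W)
  expect_identical(resumed$proj$i_e$W, straight$proj$i_e$W)
  expect_identical(resumed$state$u_e, straight$state$u_e)
  expect_identical(resumed$stim_count, straight$stim_count)
  unlink(f)
})
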