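# Desk-scale trained models shared across test files: 36 E / 9 I
# networks trained on 50,000 synthetic-scene stimuli with a matched
# stimulus seed across variants. Built lazily, once per test run.

.desk_cache <- new.env(parent = emptyenv())

desk_models <- function(seed = 1L, n_stimuli = 50000L) {
  key <- paste0("m", seed, "_", n_stimuli)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  set.seed(seed)
  scenes <- generate_scene_set(8, size = 96)
  cfg <- desk_config("EI2/1", n_stimuli = n_stimuli)
  probe <- v1plastic:::.sample_block(scenes, 150, cfg)

  train_variant <- function(variant, reference = NULL) {
    set.seed(seed)
    net <- build_network(desk_config(variant, n_stimuli = n_stimuli),
                         reference = reference)
    train(net, scenes, n_stimuli = n_stimuli, probe_rates = probe,
          probe_every = 10L)
  }

  ei <- train_variant("EI2/1")
  no <- train_variant("noInh")
  fixfb_init <- {
    set.seed(seed)
    build_network(desk_config("fix_fb_inh", n_stimuli = n_stimuli),
                  reference = ei$net)
  }
  fixfb_ie_before <- fixfb_init$proj$i_e$W
  fixfb <- train(fixfb_init, scenes, n_stimuli = n_stimuli,
                 probe_rates = probe, probe_every = 10L)
  block <- block_inhibition(ei$net)

  out <- list(scenes = scenes, probe = probe, seed = seed,
              ei = ei, no = no, fixfb = fixfb,
              fixfb_ie_before = fixfb_ie_before, block = block)
  .desk_cache[[key]] <- out
  out
}

# mean ON-minus-OFF structure index of the feed-forward weights
rf_structure_index <- function(W) {
  rf <- rf_from_weights(W)
  mean(vapply(seq_len(dim(rf)[3]), function(j)
    sqrt(sum(rf[, , j]^2)) / sqrt(sum(W[, j]^2)), numeric(1)))
}
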