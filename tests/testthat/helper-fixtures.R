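# Shared small fixtures, built in code at test time.

tiny_dataset <- function(n = 8, size = 32, pf = 0.75, seed = 42) {
  generate_dataset(generator_params(n_samples = n, positive_fraction = pf,
                                    image_size = size, seed = seed))
}

tiny_model <- function(depth = 2, base = 4, kind = "conventional",
                       placement = "both", rate = 0.5, seed = 7) {
  build_model(model_config(depth = depth, base_channels = base,
                           conv_kind = kind, dropout_placement = placement,
                           dropout_rate = rate),
              seed = seed)
}
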