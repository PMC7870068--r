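# End-to-end pipeline on a small synthetic scenario written to disk.
make_demo_run <- function(dir, n = 60, p = c(8, 8), B = 5, seed = 11,
                          fine = FALSE) {
  sc <- make_confounded_scenario(n = n, p = p, effect = 2, seed = seed)
  data_dir <- file.path(dir, "data")
  write_synthetic(sc$sim, data_dir)
  config <- list(
    blocks = list(
      list(name = "rna", file = file.path(data_dir, "block1.tsv"), tau = 1),
      list(name = "otu", file = file.path(data_dir, "block2.tsv"), tau = 1)
    ),
    metadata = list(file = file.path(data_dir, "metadata.tsv"),
                    covariate_blocks = list(group = list("group"))),
    template = list(grid = c(0, 0.5, 1)),
    scheme = "centroid",
    bootstrap = list(B = B),
    evaluate = list(labels = "group", block = "rna"),
    fine_stage = fine,
    seed = seed
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}

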