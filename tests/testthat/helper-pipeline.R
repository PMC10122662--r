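# one small simulated study shared by the pipeline, io and roster tests,
# plus memoized model reports so the end-to-end fits run once per suite
.pipeline_sim_cache <- new.env(parent = emptyenv())

get_pipeline_sim <- function() {
  if (is.null(.pipeline_sim_cache$value)) {
    cfg <- synthetic_config(n_species = 120, n_watersheds = 40,
                            missing_rate = 0.1, seed = 31)
    sim <- simulate_invasion_study(cfg)
    config <- pipeline_config(
      synthetic = cfg,
      brt = brt_params(learning_rate = 0.1, max_trees = 60, n_folds = 4,
                       step_size = 15, patience = 3),
      n_reruns = 2, compute_interactions = FALSE,
      imputation = list(num_trees = 30L, max_iter = 3L), seed = 31)
    .pipeline_sim_cache$value <- list(sim = sim, config = config)
  }
  .pipeline_sim_cache$value
}

get_pipeline_reports <- function() {
  if (is.null(.pipeline_sim_cache$reports)) {
    ps <- get_pipeline_sim()
    rep1 <- suppressWarnings(suppressMessages(
      run_invasiveness(ps$sim, ps$config)))
    rep2 <- suppressWarnings(suppressMessages(
      run_invasibility(ps$sim, ps$config)))
    .pipeline_sim_cache$reports <- list(invasiveness = rep1,
                                        invasibility = rep2)
  }
  .pipeline_sim_cache$reports
}
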