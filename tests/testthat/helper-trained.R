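# The study-scale training run (9 + 9 patients, default generator) is
# expensive, so tests that need a fitted model on the default cohort share
# one cached fit.
.trained_cache <- new.env(parent = emptyenv())

default_trained <- function() {
  if (is.null(.trained_cache$fit)) {
    cfg <- synthetic_config(seed = 1)
    sim <- simulate_cohort(cfg)
    tr <- train_cohort(sim$datasets, sim$rois, sim$truth$specimen_class,
                       seed = 1)
    .trained_cache$fit <- list(config = cfg, sim = sim, trained = tr)
  }
  .trained_cache$fit
}
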