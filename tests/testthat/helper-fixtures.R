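# shared fixtures, generated once per test run and cached
.fx <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fx[[name]])) .fx[[name]] <- maker()
  .fx[[name]]
}

# small strong-effect cohort + prepared matrix + quick 5-member fit
small_cohort <- function() fixture("small_cohort", function()
  generate_cohort(generator_config(n = 300, seed = 42)))

small_prep <- function() fixture("small_prep", function()
  prepare_matrix(small_cohort(), impute_seed = 1))

small_fit <- function() fixture("small_fit", function() {
  prep <- small_prep()
  tr <- prep$y %in% 1:4
  etio_ensemble(prep$x[tr, ], prep$y[tr], params = fast_params(),
                fit_seed = 7)
})

# well-separated two-blob data for separability checks
separable_xy <- function(n_per = 40, seed = 5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(1:4, function(cc)
    matrix(stats::rnorm(n_per * 6, mean = 4 * cc), n_per)))
  colnames(x) <- paste0("f", 1:6)
  list(x = x, y = rep(1:4, each = n_per))
}

# the expensive study-scale runs used by the acceptance suite (computed once)
acceptance_strong <- function() fixture("acceptance_strong", function() {
  coh <- generate_cohort(generator_config(n = 2000, seed = 11))
  prep <- prepare_matrix(coh, impute_seed = 1)
  tr <- prep$y %in% 1:4
  res <- rmfcv_evaluate(prep$x[tr, ], prep$y[tr], fast_params(),
                        rmfcv_plan(folds = c(2, 5), reps = c(1, 1),
                                   base_seed = 1701))
  fit <- etio_ensemble(prep$x[tr, ], prep$y[tr], params = fast_params(),
                       fit_seed = 1701)
  list(coh = coh, prep = prep, train = tr, rmfcv = res, fit = fit)
})

acceptance_null <- function() fixture("acceptance_null", function() {
  coh <- generate_cohort(generator_config(n = 2000, seed = 13,
                                          effects = zero_effect_spec()))
  prep <- prepare_matrix(coh, impute_seed = 2)
  tr <- prep$y %in% 1:4
  res <- rmfcv_evaluate(prep$x[tr, ], prep$y[tr], fast_params(),
                        rmfcv_plan(folds = 5, reps = 1, base_seed = 5))
  list(prep = prep, train = tr, rmfcv = res)
})
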