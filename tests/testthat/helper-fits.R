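# Shared fixtures: posterior fits are expensive, so fits used by several
# test files are built once per run and cached in this environment.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache, inherits = FALSE)
}

table2 <- function(model) flexlinks:::estimates_for(model)

# Reduced-size MCMC used where the test is about behaviour, not about the
# paper's default sampler settings.
fit_quick <- function(data, model, seed = 1, chains = 2, iter = 800) {
  fit_bayes(data, model, chains = chains, iter = iter, seed = seed)
}

# One synthetic flexible-links dataset shaped like the empirical
# compilation, and its full-size fit.
shared_fl_webs <- function() cached("fl_webs", mangal_like_webs(255, seed = 101))

shared_fl_fit <- function() cached("fl_fit", {
  fit_bayes(shared_fl_webs(), "flexible_links", seed = 201)
})

shared_pl_fit <- function() cached("pl_fit", {
  fit_bayes(shared_fl_webs(), "power_law", seed = 202)
})
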