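# Small parameter helpers shared across the suite. The named fixtures are the
# package's reference sets; tests that need variants modify copies.

pfli <- function() fixture_params("pfli_default")
li <- function() fixture_params("li_default")

with_fields <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  if (params$model_form == "MODEL3") params$alpha_n <- params$alpha_N
  params
}

# independent pure-LI right-hand side, coded directly from the printed
# three-species equations with the positive-feedback arm removed
li_rhs_independent <- function(state, params, meanD, meanN) {
  N <- state[1]; D <- state[2]; R <- state[3]
  x <- N * meanD
  delta <- params$k_d^params$h / (params$k_d^params$h + x^params$h)
  c(params$beta_N - params$alpha_N * N - x,
    params$beta_D * ((1 - params$S_LI) + params$S_LI * delta) -
      params$alpha_D * D - meanN * D,
    x - params$alpha_R * R)
}

stable_states <- function(census)
  Filter(function(s) s$stability == "STABLE", census)

n_stable <- function(census) length(stable_states(census))
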