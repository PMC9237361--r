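# Fitted log-logistic laws of the default configuration: per-arm OS/PFS
# (shape gamma, scale lambda), time in months.
default_curves <- function() {
  list(
    os_pembro  = surv_model("loglogistic", 1.59, 0.015),
    os_chemo   = surv_model("loglogistic", 1.70, 0.022),
    pfs_pembro = surv_model("loglogistic", 1.75, 0.029),
    pfs_chemo  = surv_model("loglogistic", 2.27, 0.028)
  )
}

# One representative model per supported family, all with ~10-month scale.
one_per_family <- function() {
  list(
    surv_model("loglogistic", 1.59, 0.015),
    surv_model("weibull", 1.3, 12),
    surv_model("lognormal", 0.8, 10),
    surv_model("gompertz", 0.08, 0.04),
    surv_model("exponential", scale = 0.08),
    surv_model("gamma", 1.6, 8)
  )
}

# Bare surv_fit stub for selection tests.
fake_fit <- function(family, aic, bic, loglik = NA_real_) {
  structure(list(model = surv_model(family, 1, 1), loglik = loglik,
                 aic = aic, bic = bic, n_obs = 10L, n_events = 10L,
                 family = family),
            class = "surv_fit")
}
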