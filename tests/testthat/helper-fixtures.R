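# Small fixtures built in code.

tiny_library <- function() {
  tibble::tibble(
    compound_id = c("T1", "T2", "P1", "H1", "O1"),
    name = c("tire-A", "tire-B", "biocide-A", "pharma-A", "other-A"),
    category = c("traffic", "traffic", "pesticide_biocide", "human_consumption", "other"),
    uses = list("tire wear", c("rubber additive", "herbicide"), "biocide",
                "pharmaceutical", "industrial"),
    log_kow = c(3.5, 5.2, 2.1, 0.8, 6.5),
    log10_solubility_mg_L = c(1.2, -0.5, 2.0, 3.1, -2.0)
  )
}

tiny_conc_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    compound_id = c("T1", "T2", "H1", "T1"),
    concentration_ng_L = c(10, 20, 5, 40),
    mdl_ng_L = 1,
    censored = FALSE
  )
}

# A flat model so predicted EC50s are easy to reason about in tests.
flat_model <- function(value_mg_L = 1) {
  b <- log10(value_mg_L)
  meltrisk::baseline_model(
    slopes = c(algae = 0, crustacean = 0, fish = 0),
    intercepts = c(algae = b, crustacean = b, fish = b)
  )
}

linear_model <- function(a = -1, b = 2) {
  meltrisk::baseline_model(
    slopes = c(algae = a, crustacean = a, fish = a),
    intercepts = c(algae = b, crustacean = b, fish = b)
  )
}

# Minimal six-day influent series for one compound with a given concentration
# pattern and rise-then-fall flow.
tiny_series <- function(conc, flow = c(9, 12, 15, 18, 14, 10) * 1e4,
                        stream = "influent", mdl = NULL) {
  n <- length(conc)
  out <- tibble::tibble(
    date = as.Date("2021-02-17") + seq_len(n) - 1,
    stream = stream,
    flow_m3_day = flow[seq_len(n)],
    compound_id = "X1",
    concentration_ng_L = conc
  )
  if (!is.null(mdl)) {
    out$mdl_ng_L <- mdl
    out <- meltrisk::censor_below_mdl(out)
  }
  out
}
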