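# Shared fixtures, built in code.

default_lt <- synthetic_life_table()

# parameter set with all cardiovascular risk removed
zero_risk_params <- function() {
  p <- base_case()
  for (nm in c("p_ref_intermediate_65_74", "p_ref_intermediate_75",
               "p_ref_high_65_74", "p_ref_high_75"))
    p$common[[nm]] <- dist_spec("fixed", base = 0)
  p
}

# collapse every distribution to a fixed point at its base case
all_fixed_params <- function(p = base_case()) {
  for (blk in c("usual", "programme", "common"))
    for (nm in names(p[[blk]]))
      p[[blk]][[nm]] <- dist_spec("fixed", base = p[[blk]][[nm]]$base)
  p
}

# life table with no background mortality until the absorbing horizon
immortal_lt <- function(max_age = 100L) {
  ages <- 65:max_age
  qx <- c(rep(0, length(ages) - 1L), 1)
  structure(data.frame(age = ages, qx = qx),
            class = c("life_table", "data.frame"))
}

base_aem <- lapply(base_case()$common, function(s) s$base)
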