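# Published parameter table, frozen: every printed cost/outcome variable maps
# to exactly one field of the parameter set.
published_params <- read.csv(text = '
block,name,kind,p1,p2,base
usual,drug_cost_year,lognormal,4.36,1.39,206.43
usual,test_cost_year,uniform,20.37,37.83,29.10
usual,n_visits_year,lognormal,1.68,0.89,7.68
usual,hr,normal,0.6150,0.0089,0.6150
programme,drug_cost_year,lognormal,4.59,1.26,216.55
programme,test_cost_year,uniform,25.33,47.04,36.19
programme,programme_fee_year,uniform,10.26,19.06,14.66
programme,n_visits_year,lognormal,1.16,0.85,4.72
programme,hr,normal,0.5124,0.0131,0.5124
programme,hr_scenario,uniform,0.4500,0.5700,0.5100
common,overhead_per_visit,uniform,1.39,2.57,1.98
common,visit_cost,uniform,6.74,12.52,9.63
common,ambulance_cost_year,uniform,12.21,22.67,17.44
common,drug_coverage,uniform,0.40,1.00,0.70
common,event_hospital_cost,lognormal,8.24,1.39,10041.65
common,first_year_test_cost,uniform,82.44,153.11,117.78
common,p_ref_intermediate_65_74,uniform,0.0223,0.0285,0.0255
common,p_ref_intermediate_75,uniform,0.0300,0.0500,0.0400
common,p_ref_high_65_74,uniform,0.0300,0.0350,0.0325
common,p_ref_high_75,uniform,0.1500,0.2500,0.2000
common,p_start_intermediate,uniform,0.0000,1.0000,0.7000
common,start_age,uniform,65,80,65
common,p_unrecognized,uniform,0.2500,0.4000,0.3670
common,p_sudden_death,uniform,0.0600,0.1400,0.1000
common,cfr_assisted_65_74,uniform,0.1000,0.2000,0.1500
common,cfr_assisted_75,uniform,0.2500,0.3500,0.3000
common,cfr_unassisted_65_74,uniform,0.2000,0.4000,0.3000
common,cfr_unassisted_75,uniform,0.5500,0.6500,0.6000
', stringsAsFactors = FALSE, strip.white = TRUE)

test_that("base_case holds every published variable with its printed law", {
  p <- base_case()
  for (i in seq_len(nrow(published_params))) {
    row <- published_params[i, ]
    spec <- p[[row$block]][[row$name]]
    expect_false(is.null(spec), info = paste(row$block, row$name))
    expect_identical(spec$kind, row$kind, info = row$name)
    expect_equal(spec$p1, row$p1, tolerance = 1e-12, info = row$name)
    expect_equal(spec$p2, row$p2, tolerance = 1e-12, info = row$name)
    expect_equal(spec$base, row$base, tolerance = 1e-12, info = row$name)
  }
  # the one field with no published row: usual care pays no programme fee
  expect_identical(p$usual$programme_fee_year$kind, "fixed")
  expect_identical(p$usual$programme_fee_year$base, 0)
  # nothing beyond the published rows + the fee
  n_fields <- length(p$usual) + length(p$programme) + length(p$common)
  expect_identical(n_fields, nrow(published_params) + 1L)
})

test_that("published uniform cost/outcome bases sit at their midpoints", {
  # the two cohort entry conditions are scenario ranges, printed with bases
  # away from the midpoint (entry age 65 in U(65,80); intermediate-risk
  # share 0.70 in U(0,1)); every uncertainty parameter is midpoint-centred
  entry <- c("start_age", "p_start_intermediate", "p_unrecognized")
  uni <- published_params[published_params$kind == "uniform" &
                            !published_params$name %in% entry, ]
  expect_true(all(abs(uni$base - (uni$p1 + uni$p2) / 2) <= 0.0101))
  ent <- published_params[published_params$name %in% entry, ]
  expect_true(all(abs(ent$base - (ent$p1 + ent$p2) / 2) > 0.0101))
})

test_that("parameter files round-trip and validate on load", {
  p <- base_case()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(p, path)
  expect_equal(load_parameters(path), p)

  # schema error: a required key removed from the file is named in the error
  doc <- yaml::read_yaml(path)
  doc$usual$hr <- NULL
  yaml::write_yaml(doc, path)
  expect_error(load_parameters(path), "usual\\$hr")

  # missing schema marker
  doc2 <- yaml::read_yaml(path)
  save_parameters(p, path)
  doc2 <- yaml::read_yaml(path)
  doc2$schema <- NULL
  yaml::write_yaml(doc2, path)
  expect_error(load_parameters(path), "schema")

  # out-of-range value: coverage is a proportion
  bad <- base_case()
  bad$common$drug_coverage <- dist_spec("fixed", base = 1.3)
  expect_error(save_parameters(bad, path), "drug_coverage")
})

test_that("distribution consistency report matches closed forms", {
  rep <- validate_distributions(base_case())
  fee <- rep[rep$parameter == "programme_fee_year" & rep$block == "programme", ]
  expect_equal(fee$deviation, 0, tolerance = 1e-9)

  drugs <- rep[rep$parameter == "drug_cost_year" & rep$block == "usual", ]
  expect_equal(drugs$implied, exp(4.36 + 1.39^2 / 2), tolerance = 1e-9)
  expect_lt(drugs$deviation, 0.01)

  fixed <- rep[rep$parameter == "programme_fee_year" & rep$block == "usual", ]
  expect_identical(fixed$kind, "fixed")
  expect_equal(fixed$deviation, 0)
  # only the strongly off-centre entry-condition ranges trip the 5% flag;
  # the unrecognized-event range (base 0.367, midpoint 0.325) stays under it
  expect_setequal(rep$parameter[rep$flag],
                  c("start_age", "p_start_intermediate"))
})

test_that("dist_spec enforces its invariants", {
  expect_error(dist_spec("uniform", 5, 1), "p1 <= p2")
  expect_error(dist_spec("uniform", 0, 1, base = 2), "outside")
  expect_error(dist_spec("lognormal", 1, -1), "sigma")
  expect_error(dist_spec("fixed"), "base")
  expect_equal(dist_spec("uniform", 10.26, 19.06)$base, 14.66)
})
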