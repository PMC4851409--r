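# Stage 5: distance-based redundancy analysis of the community matrix on the
# environmental table (Jaccard dissimilarities), with permutation tests per
# variable and per constrained axis, plus stepwise variable selection.

source("analysis/00_config.R")

M <- read_community_matrix(res_path("community_matrix.csv"))
E <- read_environment_table(res_path("environment.csv"))
aligned <- align_inputs(M, E)

D <- jaccard_dissimilarity(aligned$M)
fit <- dbrda_fit(D, aligned$E)
print(fit)

set.seed(config$seed + 6)
by_margin <- dbrda_permutation_tests(fit, by = "margin",
                                     n_perm = config$n_perm)
by_axis <- dbrda_permutation_tests(fit, by = "axis", n_perm = config$n_perm)
selected <- stepwise_select_dbrda(D, aligned$E)

write.csv(by_margin, res_path("dbrda_variable_tests.csv"), row.names = FALSE)
write.csv(by_axis, res_path("dbrda_axis_tests.csv"), row.names = FALSE)
write.csv(data.frame(
  constrained_inertia = fit$constrained_inertia,
  unconstrained_inertia = fit$unconstrained_inertia,
  total_inertia = fit$total_inertia,
  constrained_fraction = fit$constrained_fraction,
  selected_variables = paste(selected, collapse = "+")),
  res_path("dbrda_summary.csv"), row.names = FALSE)

message(sprintf("dbRDA: %.1f%% of inertia constrained; selected: %s",
                100 * fit$constrained_fraction,
                paste(selected, collapse = ", ")))
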