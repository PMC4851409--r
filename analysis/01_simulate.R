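# Stage 1: generate the synthetic metacommunity used by every later stage.
# Writes the community matrix, environment table, group map, and the true
# niche coefficients to results/.

source("analysis/00_config.R")

E <- generate_environment(config$n_sites, n_gradients = config$n_gradients,
                          n_vars = config$n_env_vars,
                          collinear_r2 = config$collinear_r2,
                          seed = config$seed)
truth <- synthetic_truth(config$n_species, paste0("env_", 1:config$n_env_vars),
                         mass_effect = config$mass_effect,
                         seed = config$seed + 1)
world <- generate_metacommunity(E, truth, seed = config$seed + 2)
M <- suppressWarnings(filter_rare_species(world$M, config$min_occurrences))
G <- make_group_map(truth, "niche-similarity", n_groups = config$n_groups,
                    seed = config$seed + 3)[colnames(M)]

write_community_matrix(M, res_path("community_matrix.csv"))
write.csv(cbind(site = rownames(E), E), res_path("environment.csv"),
          row.names = FALSE)
write.csv(data.frame(species = names(G), label = unname(G)),
          res_path("group_map.csv"), row.names = FALSE)
write.csv(data.frame(species = names(truth$intercepts),
                     intercept = unname(truth$intercepts),
                     truth$slopes, check.names = FALSE),
          res_path("true_niche_coefficients.csv"), row.names = FALSE)

message(sprintf("world: %d x %d after filtering, fill %d (m = %.2f)",
                nrow(M), ncol(M), matrix_fill(M), config$mass_effect))
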