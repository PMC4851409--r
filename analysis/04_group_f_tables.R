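# Stage 4: group-partitioned F-index tables (mean CU_model / CU_real per
# group pair) and the NODF-to-C-score regression across the pooled
# pseudo-communities.

source("analysis/00_config.R")

M <- read_community_matrix(res_path("community_matrix.csv"))
G <- read_group_map(res_path("group_map.csv"))
ens <- read.csv(res_path("ensemble_replicates.csv"), check.names = FALSE)

ft <- run_f_tables(ens, M, G[colnames(M)])
write.csv(ft, res_path("f_tables.csv"), row.names = FALSE)

reg <- run_nodf_cscore_regression(ens, M)
write.csv(data.frame(slope = reg$slope,
                     r_squared = reg$r_squared,
                     observed_nodf = reg$observed_nodf,
                     observed_cscore = reg$observed_cscore,
                     predicted_cscore = reg$predicted_cscore,
                     prediction_lower = reg$prediction_interval[1],
                     prediction_upper = reg$prediction_interval[2],
                     observed_inside = reg$observed_inside),
          res_path("nodf_cscore_regression.csv"), row.names = FALSE)

message(sprintf("NODF~C-score: slope %.3f, R^2 %.3f, observed inside PI: %s",
                reg$slope, reg$r_squared, reg$observed_inside))
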