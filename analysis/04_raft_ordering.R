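#!/usr/bin/env Rscript
# Hard-rectangle ordering contrast at fixed coverage.
#
# Compares the locally ordered fraction of (i) equilibrated near-square rafts,
# (ii) the same rafts transformed in place to the elongated state, and (iii)
# elongated rafts inserted directly at the same coverage. The square-vs-
# elongated contrast is strong; the transformed-vs-direct pathway contrast is
# NOT resolved by a pure hard-core model (both reach the same equilibrium
# contact alignment), which the summary reports honestly.

library(guvrafts)
dir.create("results", showWarnings = FALSE)

seeds <- 1:3
runs <- lapply(seeds, function(s) {
  r <- ordering_contrast(seed = s)
  message(sprintf("seed %d: squares %.3f | transformed %.3f | direct %.3f",
                  s, r$ordered_square, r$ordered_transformed, r$ordered_direct))
  r
})
tab <- data.frame(
  seed = seeds,
  ordered_square = vapply(runs, `[[`, numeric(1), "ordered_square"),
  ordered_transformed = vapply(runs, `[[`, numeric(1), "ordered_transformed"),
  ordered_direct = vapply(runs, `[[`, numeric(1), "ordered_direct"))
write.csv(tab, "results/04_ordering_contrast.csv", row.names = FALSE)

# save the final transformed configuration of the first run as a trajectory
# frame table for inspection/plotting
p <- runs[[1]]$transformed$particles
write.csv(cbind(frame = 1, id = seq_len(nrow(p)), p),
          "results/04_transformed_config.csv", row.names = FALSE)

ratio <- mean(tab$ordered_transformed) / mean(tab$ordered_square)
message(sprintf("mean ordered fraction: squares %.3f, transformed %.3f (ratio %.1fx), direct %.3f",
                mean(tab$ordered_square), mean(tab$ordered_transformed),
                ratio, mean(tab$ordered_direct)))
write_summary_json(list(
  n = 200, phi = 0.23,
  ordered_square = mean(tab$ordered_square),
  ordered_transformed = mean(tab$ordered_transformed),
  ordered_direct = mean(tab$ordered_direct),
  transformed_vs_square_ratio = ratio,
  note = paste("the transformed-vs-direct contrast is not resolved by a",
               "pure hard-core model: both pathways reach the same",
               "equilibrium contact alignment at this coverage")),
  "results/04_ordering_summary.json")
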