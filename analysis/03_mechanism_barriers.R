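#!/usr/bin/env Rscript
# Compares a direct proton-transfer channel against a relay-assisted channel
# with the chain-of-states pipeline (band relaxation + climbing-image saddle
# refinement), after benchmarking the optimizer on the Mueller-Brown surface
# against a dense-grid minimax oracle. Writes results/mechanism_barriers.csv.

suppressPackageStartupMessages(library(protonpath))
dir.create("results", showWarnings = FALSE)

## Benchmark: Mueller-Brown saddle vs brute force.
mb <- muller_brown()
descend <- function(x) {
  for (i in 1:20000) {
    g <- mb$gradient(x)
    if (sqrt(sum(g^2)) < 1e-11) break
    x <- x - 1e-4 * g
  }
  x
}
A <- descend(c(-0.56, 1.44)); B <- descend(c(0.62, 0.03))
p <- optimize_path(mb, init_path(A, B, 20))
ci <- climbing_image_refine(mb, p, tol = 1e-6)
oracle <- grid_minimax_saddle(mb, A, B, xlim = c(-1.6, 1.2),
                              ylim = c(-0.3, 2.1), n = 2000)
cat(sprintf("Mueller-Brown: CI saddle %.5f vs 2000x2000 grid oracle %.5f (%.4f%% apart)\n",
            ci$energy, oracle, 100 * abs(ci$energy - oracle) / abs(oracle)))

## Mechanism comparison on the paired proton-transfer surfaces.
ps <- proton_transfer_surfaces()
run <- function(surface, label) {
  pp <- optimize_path(surface, init_path(ps$endpoints$reactant,
                                         ps$endpoints$product, 20))
  cc <- climbing_image_refine(surface, pp, tol = 1e-6)
  b <- path_barrier(pp)
  data.frame(channel = label,
             activation = cc$energy - surface$energy(ps$endpoints$reactant),
             reaction = b$reaction, saddle_grad_norm = cc$grad_norm,
             band_converged = attr(pp, "converged"))
}
tab <- rbind(run(ps$direct, "direct"), run(ps$relay, "relay"))
tab$mb_saddle <- ci$energy
tab$mb_oracle <- oracle
print(tab[, 1:5])
write.csv(tab, "results/mechanism_barriers.csv", row.names = FALSE)
cat(sprintf("\nThe relay channel crosses at %.2f vs %.2f for the direct channel\n",
            tab$activation[2], tab$activation[1]))
cat(sprintf("(ratio %.1f): engaging the relay coordinate avoids most of the\n",
            tab$activation[1] / tab$activation[2]))
cat("direct barrier while both channels share reactant and product states.\n")
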