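#!/usr/bin/env Rscript

# Validation of the ordinal-complexity pipeline on surrogate interval
# series with known structure: cyclic firing patterns with jitter versus
# structureless i.i.d. intervals. Demonstrates the discrimination property
# the resonance analysis relies on, and the worked six-element example.
# Writes results/surrogate_summary.csv.

suppressPackageStartupMessages(library(fhnsmr))

dir.create("results", showWarnings = FALSE)

## worked example
series <- c(1.1, 3.5, 2.3, 4.7, 1.8, 5.6)
pd <- pattern_distribution(series, d = 3, warn = FALSE)
cat("worked six-element series, d = 3:\n")
print(pd)
cs <- scm(pd)
print(cs)

## discrimination across seeds
L <- 10000
pattern <- c(4, 10)
m <- mean(pattern)
res <- t(sapply(1:20, function(seed) {
  per <- generate_periodic_isi(pattern, 0.05 * m, L = L, seed = seed)
  iid <- generate_iid_isi(m, 0.05 * m, L = L, seed = seed + 1000)
  c(C_periodic = complexity_of_isi(per)$C, C_iid = complexity_of_isi(iid)$C)
}))
cat(sprintf("\nC(periodic) = %.4f +/- %.4f, C(iid) = %.5f +/- %.5f over 20 seeds\n",
            mean(res[, 1]), sd(res[, 1]), mean(res[, 2]), sd(res[, 2])))
cat(sprintf("discrimination holds in %d/20 seeds\n", sum(res[, 1] > res[, 2])))

## degradation with jitter
jit_frac <- c(0.01, 0.1, 0.5, 1, 2)
deg <- sapply(jit_frac, function(f) {
  mean(sapply(1:5, function(seed)
    complexity_of_isi(generate_periodic_isi(c(6, 8), f * m, L = 5000,
                                            seed = seed))$C))
})
cat("\nSCM vs jitter (fraction of mean interval):\n")
print(data.frame(jitter = jit_frac, C = round(deg, 5)))

utils::write.csv(
  rbind(data.frame(quantity = "C_periodic_mean", value = mean(res[, 1])),
        data.frame(quantity = "C_iid_mean", value = mean(res[, 2])),
        data.frame(quantity = sprintf("C_jitter_%g", jit_frac), value = deg)),
  "results/surrogate_summary.csv", row.names = FALSE)
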